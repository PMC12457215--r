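#' Relative difference in mean target dose
#'
#' \eqn{\Delta D = 100 (\bar{D}_{eval} - \bar{D}_{ref}) / \bar{D}_{ref}}
#' over the target mask, in percent. Positive values mean the evaluated
#' (ISDC) dose is higher than the reference (TPS) dose. If the evaluated
#' grid lives on a different geometry it is resampled onto the reference
#' geometry first; voxels outside its support are dropped from the mean.
#'
#' @param ref reference [dose_grid()].
#' @param eval evaluated [dose_grid()].
#' @param target a [structure_mask()] on the reference geometry with at least
#'   one voxel set.
#' @return Signed percentage.
#' @examples
#' g <- dose_grid(array(60, c(4, 4, 4)))
#' m <- structure_mask(array(TRUE, c(4, 4, 4)), g)
#' e <- dose_grid(g$values * 1.02, g$origin, g$spacing)
#' mean_target_dose_diff(g, e, m)  # +2
#' @export
mean_target_dose_diff <- function(ref, eval, target) {
  stopifnot(inherits(ref, "dose_grid"), inherits(eval, "dose_grid"),
            inherits(target, "structure_mask"))
  if (!identical(dim(target$values), dim(ref$values)))
    stop("mean_target_dose_diff: geometry error, mask not on reference geometry",
         call. = FALSE)
  sel <- target$values
  if (!any(sel))
    stop("mean_target_dose_diff: degenerate-target error, empty target mask",
         call. = FALSE)
  if (!same_geometry(ref, eval)) {
    rs <- resample_onto(eval, target = ref)
    eval <- rs$grid
    sel <- sel & !rs$out_of_support$values
    if (!any(sel))
      stop("mean_target_dose_diff: degenerate-target error, target outside evaluated grid",
           call. = FALSE)
  }
  m_ref <- mean(ref$values[sel])
  if (m_ref <= 0)
    stop("mean_target_dose_diff: degenerate-target error, zero reference mean",
         call. = FALSE)
  100 * (mean(eval$values[sel]) - m_ref) / m_ref
}

#' Evaluate one plan: gamma pass rates and mean target dose difference
#'
#' Bundles [gamma_pass_rate()] at each criterion with
#' [mean_target_dose_diff()] into a one-row data frame — the atom of the
#' cohort tables consumed by the action-level and TG-218 layers. The
#' evaluated grid is resampled onto the reference geometry once;
#' out-of-support voxels are excluded from the gamma statistics.
#'
#' @inheritParams mean_target_dose_diff
#' @param criteria list of [gamma_criterion()], default [default_criteria()].
#' @param plan_id,case_class,technique labels stored with the result.
#' @param interp,step,cap forwarded to [gamma_map()].
#' @return One-row `data.frame` with columns `plan_id`, `case_class`,
#'   `technique`, `delta_d`, and one `gpr_<dd>_<dta>` column per criterion.
#' @export
evaluate_plan <- function(ref, eval, target, criteria = default_criteria(),
                          plan_id = "plan", case_class = NA_character_,
                          technique = NA_character_,
                          interp = TRUE, step = NULL, cap = 2) {
  # gamma interrogates the native evaluated grid; the resampled copy only
  # provides delta-D and the out-of-support exclusion mask
  include <- NULL
  eval_dd <- eval
  if (!same_geometry(ref, eval)) {
    rs <- resample_onto(eval, target = ref)
    include <- structure_mask(!rs$out_of_support$values, grid = ref,
                              role = "in_support")
    eval_dd <- rs$grid
  }
  dd <- mean_target_dose_diff(ref, eval_dd, target)
  res <- data.frame(plan_id = plan_id, case_class = case_class,
                    technique = technique, delta_d = dd,
                    stringsAsFactors = FALSE)
  for (crit in criteria) {
    gm <- gamma_map(ref, eval, crit, interp = interp, step = step, cap = cap,
                    include = include)
    res[[criterion_label(crit)]] <- gamma_pass_rate(gm)
  }
  res
}

gpr_columns <- function(cohort) {
  grep("^gpr_", names(cohort), value = TRUE)
}

check_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("empty-statistics error: cohort must be a non-empty data frame",
         call. = FALSE)
  if (!"delta_d" %in% names(cohort))
    stop("data error: cohort lacks a `delta_d` column", call. = FALSE)
  gc <- gpr_columns(cohort)
  for (cl in gc) {
    v <- cohort[[cl]]
    if (any(!is.finite(v)) || any(v < 0 | v > 100))
      stop("data error: GPR column ", cl, " outside [0, 100]", call. = FALSE)
  }
  if (any(!is.finite(cohort$delta_d)))
    stop("data error: non-finite delta_d", call. = FALSE)
  invisible(cohort)
}

#' Write / read the plan-results cohort CSV
#'
#' The interchange format between the evaluation and statistics layers:
#' columns `plan_id, case_class, technique, delta_d, gpr_5_3, gpr_3_3,
#' gpr_2_2, gpr_2_1` (GPR columns follow the configured criterion set).
#'
#' @param cohort data frame of per-plan results, e.g. rows from
#'   [evaluate_plan()] or [sample_result_cohort()].
#' @param path CSV path.
#' @return `write_plan_results()`: `path` invisibly; `read_plan_results()`:
#'   the validated cohort data frame.
#' @export
write_plan_results <- function(cohort, path) {
  check_cohort(cohort)
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plan_results
#' @export
read_plan_results <- function(path) {
  check_cohort(read.csv(path, stringsAsFactors = FALSE))
}
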