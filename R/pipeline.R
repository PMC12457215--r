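#' Run the full action-level study on a cohort
#'
#' Orchestrates the end-to-end chain: obtain a cohort (a result-level
#' simulation, a voxel-level simulation, or a pre-computed plan-results
#' table), derive percentile action levels at each failure rate, evaluate
#' the combined gamma-and-\eqn{|\Delta D|} criteria at the derived (and any
#' user-fixed) levels, and compute TG-218 expected failure rates from the
#' cohort mean/SD. Deterministic given `(config, seed)`.
#'
#' @param config a list with one of:
#'   * `cohort` — a [cohort_sim_config()] (result-level simulation),
#'   * `plan` plus `n_plans` — a [plan_sim_config()] (voxel-level simulation;
#'     gamma is computed per plan, so this tier is slow),
#'   * `results` — a plan-results data frame or CSV path;
#'   and optionally `q` (failure rates, default `c(0.02, 0.05, 0.1, 0.2)`),
#'   `convention` (rounding, default `"nearest"`), `fixed_als` (a list of
#'   `list(gamma = <action_level>, dd = <action_level>)` pairs to tabulate),
#'   `criteria` (for the voxel tier).
#' @param seed RNG seed for any simulation.
#' @param out_dir if non-`NULL`, CSVs and a run log are written there.
#' @return Object of class `study_report`: list with `cohort`,
#'   `action_levels`, `combined`, `tg218`, `provenance`.
#' @export
run_study <- function(config = list(), seed = 1L, out_dir = NULL) {
  q <- config$q %||% c(0.02, 0.05, 0.1, 0.2)
  convention <- config$convention %||% "nearest"

  cohort <- if (!is.null(config$results)) {
    if (is.character(config$results)) read_plan_results(config$results)
    else check_cohort(config$results)
  } else if (!is.null(config$plan)) {
    if (is.null(config$n_plans))
      stop("run_study: configuration error, voxel tier needs `n_plans`",
           call. = FALSE)
    simulate_voxel_cohort(config$n_plans, config$plan, seed = seed,
                          criteria = config$criteria %||% default_criteria())
  } else if (!is.null(config$cohort)) {
    sample_result_cohort(config$cohort, seed = seed)
  } else {
    stop("run_study: configuration error, supply `cohort`, `plan` or `results`",
         call. = FALSE)
  }

  als <- action_level_table(cohort, q = q, convention = convention)
  tg <- tg218_table(cohort, q = q, convention = convention)

  # combined tables at each derived (q, gpr-criterion) pair ...
  combined <- list()
  for (qi in q) {
    al_dd <- dd_action_level(cohort$delta_d, qi, convention = convention)
    for (col in gpr_columns(cohort)) {
      al_g <- gpr_action_level(cohort[[col]], qi, convention = convention,
                               criterion = col)
      key <- sprintf("q%s_%s", format(qi), col)
      combined[[key]] <- combined_table(cohort, al_g, al_dd)
    }
  }
  # ... and at any user-fixed action levels
  for (nm in names(config$fixed_als %||% list())) {
    fa <- config$fixed_als[[nm]]
    combined[[nm]] <- combined_table(cohort, fa$gamma, fa$dd)
  }

  prov <- list(seed = seed, config_hash = config_hash(config),
               n = nrow(cohort),
               package_version = as.character(utils::packageVersion("doseqa")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  report <- structure(list(cohort = cohort, action_levels = als,
                           combined = combined, tg218 = tg,
                           provenance = prov),
                      class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  # deparse gives a stable text form; hash that (objects in the config print
  # via their list structure)
  writeLines(deparse(config, control = "all"), f)
  unname(tools::md5sum(f))
}

combined_to_df <- function(combined) {
  do.call(rbind, lapply(names(combined), function(nm) {
    x <- combined[[nm]]
    data.frame(table = nm, passed_both = x$passed_both,
               failed_both = x$failed_both, failed_gamma = x$failed_gamma,
               failed_dd = x$failed_dd, n = x$n)
  }))
}

#' Write a study report's tables to a directory
#'
#' Emits `cohort.csv`, `action_levels.csv`, `combined.csv`, `tg218.csv` and
#' `run_log.txt`.
#'
#' @param report a `study_report` from [run_study()].
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_plan_results(report$cohort, file.path(out_dir, "cohort.csv"))
  write.csv(report$action_levels, file.path(out_dir, "action_levels.csv"),
            row.names = FALSE)
  write.csv(combined_to_df(report$combined), file.path(out_dir, "combined.csv"),
            row.names = FALSE)
  write.csv(report$tg218, file.path(out_dir, "tg218.csv"), row.names = FALSE)
  log <- c(sprintf("doseqa study report"),
           sprintf("seed: %d", report$provenance$seed),
           sprintf("config_hash: %s", report$provenance$config_hash),
           sprintf("n_plans: %d", report$provenance$n),
           sprintf("package_version: %s", report$provenance$package_version),
           vapply(seq_len(nrow(report$cohort)), function(i) {
             r <- report$cohort[i, ]
             gc <- grep("^gpr_", names(r), value = TRUE)
             sprintf("plan %s: delta_d=%.3f %s", r$plan_id, r$delta_d,
                     paste(sprintf("%s=%.2f", gc, as.numeric(r[gc])),
                           collapse = " "))
           }, ""))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d plans, %d action levels, %d combined tables\n",
              nrow(x$cohort), nrow(x$action_levels), length(x$combined)))
  invisible(x)
}

parse_criteria_flag <- function(s) {
  # "5,3;3,3;2,2;2,1" -> list of gamma_criterion
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  cr <- lapply(parts, function(p) {
    v <- as.numeric(strsplit(p, ",", fixed = TRUE)[[1]])
    gamma_criterion(v[1], v[2])
  })
  names(cr) <- vapply(cr, criterion_label, "")
  cr
}

parse_fixed_al_flag <- function(s, criteria) {
  # "gpr:3,3:90;dd:4.5" -> list(gamma = ..., dd = ...)
  out <- list(gamma = NULL, dd = NULL)
  for (p in strsplit(s, ";", fixed = TRUE)[[1]]) {
    f <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (f[1] == "gpr") {
      v <- as.numeric(strsplit(f[2], ",", fixed = TRUE)[[1]])
      out$gamma <- fixed_action_level("gpr", as.numeric(f[3]),
                                      criterion = criterion_label(gamma_criterion(v[1], v[2])))
    } else if (f[1] == "dd") {
      out$dd <- fixed_action_level("dd", as.numeric(f[2]))
    } else stop("qa_cli: cannot parse fixed action level '", p, "'", call. = FALSE)
  }
  out
}

#' Command-line interface
#'
#' Subcommands, each reading/writing the CSV interchange formats so stages
#' compose: `simulate` (result-level cohort to CSV), `simulate-voxel`
#' (voxel-level cohort, gamma + \eqn{\Delta D}), `evaluate` (paired NRRD
#' grids in a directory to a results CSV), `action-levels`, `tg218`, and
#' `report` / `all` (the full study). Typical use:
#' `Rscript -e 'doseqa::qa_cli()' all --flavor M3D --seed 7 --out outdir`.
#'
#' @param args character vector of arguments; defaults to the command line.
#' @return The main result of the subcommand, invisibly.
#' @export
qa_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: qa_cli <simulate|simulate-voxel|evaluate|action-levels|tg218|report|all> [options]",
         call. = FALSE)
  cmd <- args[1]
  rest <- args[-1]
  opts <- list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "doseqa_out"),
    optparse::make_option("--results", type = "character", default = NULL),
    optparse::make_option("--flavor", type = "character", default = "M3D"),
    optparse::make_option("--n-plans", type = "integer", default = 100L,
                          dest = "n_plans"),
    optparse::make_option("--criteria", type = "character",
                          default = "5,3;3,3;2,2;2,1"),
    optparse::make_option("--q", type = "character", default = "0.02,0.05,0.1,0.2"),
    optparse::make_option("--fixed-al", type = "character", default = NULL,
                          dest = "fixed_al"),
    optparse::make_option("--in", type = "character", default = NULL,
                          dest = "input")
  )
  po <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                             args = rest)
  criteria <- parse_criteria_flag(po$criteria)
  qv <- as.numeric(strsplit(po$q, ",", fixed = TRUE)[[1]])
  dir.create(po$out, showWarnings = FALSE, recursive = TRUE)

  result <- switch(cmd,
    "simulate" = {
      cohort <- sample_result_cohort(
        cohort_sim_config(flavor = po$flavor, criteria = criteria),
        seed = po$seed)
      write_plan_results(cohort, file.path(po$out, "cohort.csv"))
      message("wrote ", file.path(po$out, "cohort.csv"))
      cohort
    },
    "simulate-voxel" = {
      cohort <- simulate_voxel_cohort(po$n_plans, plan_sim_config(),
                                      seed = po$seed, criteria = criteria)
      write_plan_results(cohort, file.path(po$out, "cohort.csv"))
      cohort
    },
    "evaluate" = {
      if (is.null(po$input))
        stop("qa_cli evaluate: configuration error, --in DIR required", call. = FALSE)
      cohort <- evaluate_directory(po$input, criteria = criteria)
      write_plan_results(cohort, file.path(po$out, "cohort.csv"))
      cohort
    },
    "action-levels" = {
      if (is.null(po$results))
        stop("qa_cli action-levels: configuration error, --results CSV required",
             call. = FALSE)
      tab <- action_level_table(read_plan_results(po$results), q = qv)
      write.csv(tab, file.path(po$out, "action_levels.csv"), row.names = FALSE)
      tab
    },
    "tg218" = {
      if (is.null(po$results))
        stop("qa_cli tg218: configuration error, --results CSV required",
             call. = FALSE)
      tab <- tg218_table(read_plan_results(po$results), q = qv)
      write.csv(tab, file.path(po$out, "tg218.csv"), row.names = FALSE)
      tab
    },
    "report" = ,
    "all" = {
      config <- list(q = qv, criteria = criteria)
      if (!is.null(po$results)) config$results <- po$results
      else config$cohort <- cohort_sim_config(flavor = po$flavor,
                                              criteria = criteria)
      if (!is.null(po$fixed_al))
        config$fixed_als <- list(fixed = parse_fixed_al_flag(po$fixed_al, criteria))
      run_study(config, seed = po$seed, out_dir = po$out)
    },
    stop("qa_cli: unknown subcommand '", cmd, "'", call. = FALSE)
  )
  invisible(result)
}

#' Evaluate a directory of paired NRRD dose grids
#'
#' Expects triples `<plan>_ref.nrrd`, `<plan>_eval.nrrd`, `<plan>_mask.nrrd`.
#'
#' @param dir directory path.
#' @param criteria list of [gamma_criterion()].
#' @return Plan-results data frame.
#' @export
evaluate_directory <- function(dir, criteria = default_criteria()) {
  refs <- sort(list.files(dir, "_ref\\.nrrd$", full.names = TRUE))
  if (length(refs) == 0)
    stop("evaluate_directory: configuration error, no *_ref.nrrd files in ", dir,
         call. = FALSE)
  rows <- lapply(refs, function(rf) {
    stem <- sub("_ref\\.nrrd$", "", rf)
    ef <- paste0(stem, "_eval.nrrd"); mf <- paste0(stem, "_mask.nrrd")
    if (!file.exists(ef) || !file.exists(mf))
      stop("evaluate_directory: configuration error, missing pair for ",
           basename(stem), call. = FALSE)
    ref <- read_nrrd(rf)
    evaluate_plan(ref, read_nrrd(ef), read_nrrd(mf, as_mask = TRUE),
                  criteria = criteria, plan_id = basename(stem))
  })
  do.call(rbind, rows)
}
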