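#' Gamma evaluation criterion
#'
#' A (DD, DTA) tolerance pair for the global gamma index: `dd` is the dose
#' difference tolerance as a percentage of the global reference maximum, and
#' `dta` the distance-to-agreement tolerance in mm. Voxels whose reference
#' dose falls below `low_dose_threshold` times the reference maximum are
#' excluded from the statistics (numerator and denominator).
#'
#' @param dd dose-difference tolerance, % of global reference maximum (> 0).
#' @param dta distance-to-agreement tolerance in mm (> 0).
#' @param low_dose_threshold proportion of reference maximum in \[0, 1).
#' @return Object of class `gamma_criterion`.
#' @examples
#' gamma_criterion(3, 3)   # the classic 3%/3mm criterion
#' @export
gamma_criterion <- function(dd, dta, low_dose_threshold = 0.05) {
  dd <- as.double(dd); dta <- as.double(dta)
  if (!is.finite(dd) || dd <= 0 || !is.finite(dta) || dta <= 0)
    stop("gamma_criterion: `dd` and `dta` must be positive", call. = FALSE)
  if (low_dose_threshold < 0 || low_dose_threshold >= 1)
    stop("gamma_criterion: `low_dose_threshold` must be in [0, 1)", call. = FALSE)
  structure(list(dd = dd, dta = dta, low_dose_threshold = low_dose_threshold),
            class = "gamma_criterion")
}

#' @export
print.gamma_criterion <- function(x, ...) {
  cat(sprintf("<gamma_criterion> %g%% / %g mm (low-dose cut %g%% of max)\n",
              x$dd, x$dta, 100 * x$low_dose_threshold))
  invisible(x)
}

#' Column label used for a criterion in cohort tables, e.g. `"gpr_3_3"`.
#' @param crit a [gamma_criterion()].
#' @return A string.
#' @export
criterion_label <- function(crit) {
  fmt <- function(x) gsub("\\.", "p", sub("\\.0+$", "", format(x)))
  sprintf("gpr_%s_%s", fmt(crit$dd), fmt(crit$dta))
}

#' The four DD/DTA criteria of the study
#'
#' (5%, 3 mm), (3%, 3 mm), (2%, 2 mm), (2%, 1 mm), ordered lenient to strict.
#' @param low_dose_threshold passed to each [gamma_criterion()].
#' @return Named list of `gamma_criterion` objects.
#' @export
default_criteria <- function(low_dose_threshold = 0.05) {
  cr <- list(gamma_criterion(5, 3, low_dose_threshold),
             gamma_criterion(3, 3, low_dose_threshold),
             gamma_criterion(2, 2, low_dose_threshold),
             gamma_criterion(2, 1, low_dose_threshold))
  names(cr) <- vapply(cr, criterion_label, "")
  cr
}

new_gamma_map <- function(values, evaluated, criterion, grid, cap) {
  structure(list(values = values, evaluated_mask = evaluated,
                 criterion = criterion, origin = grid$origin,
                 spacing = grid$spacing, cap = cap),
            class = "gamma_map")
}

#' @export
print.gamma_map <- function(x, ...) {
  g <- x$values[x$evaluated_mask]
  cat(sprintf("<gamma_map> %s, %d voxels evaluated, pass rate %.1f%%, cap %g\n",
              sub("^<|>\\n$", "", format(x$criterion$dd)),
              length(g), 100 * mean(g < 1), x$cap))
  invisible(x)
}

included_indices <- function(ref, crit, include = NULL) {
  rmax <- max_dose(ref)
  if (rmax <= 0)
    stop("gamma: empty-grid error, reference maximum is not positive", call. = FALSE)
  inc <- ref$values >= crit$low_dose_threshold * rmax
  if (crit$low_dose_threshold == 0) inc[] <- TRUE
  if (!is.null(include)) inc <- inc & include$values
  if (!any(inc))
    stop("gamma: empty-statistics error, no voxels above the low-dose threshold",
         call. = FALSE)
  inc
}

#' Global 3D gamma map
#'
#' For each reference voxel above the low-dose threshold, the gamma index
#' \deqn{\gamma = \min_r \sqrt{ |r - r_{ref}|^2 / DTA^2 +
#'   (D_{eval}(r) - D_{ref}(r_{ref}))^2 / (DD \cdot D_{ref,max})^2 }}
#' is minimized over positions of the evaluated grid. The search always
#' includes the evaluated voxel centers within the capped radius; with
#' `interp = TRUE` (default) it additionally walks a sub-voxel lattice of
#' step `step` (default DTA/10) with trilinear interpolation. Gamma values
#' are capped at `cap` (default 2); voxels outside the evaluated mask carry
#' `NA`. Normalization is *global*: the dose denominator is
#' `dd/100 * max(ref)` everywhere (`norm_dose` overrides, e.g. for
#' prescription-dose normalization).
#'
#' @param ref reference [dose_grid()] (the TPS dose); gamma is evaluated at
#'   its voxel centers and its maximum sets the global normalization.
#' @param eval evaluated [dose_grid()] (the ISDC dose); may live on a
#'   different axis-aligned geometry.
#' @param crit a [gamma_criterion()].
#' @param interp search between voxel centers by trilinear interpolation?
#' @param step sub-voxel search step in mm; default `crit$dta / 10`.
#' @param cap gamma cap; larger values are reported as `cap`.
#' @param include optional [structure_mask()] further restricting the
#'   evaluated voxels (e.g. the complement of a resampling out-of-support
#'   mask).
#' @param norm_dose optional normalization dose in Gy replacing `max(ref)`.
#' @return Object of class `gamma_map`: `values` (3D array, `NA` outside the
#'   mask), `evaluated_mask`, `criterion`, plus the geometry.
#' @export
gamma_map <- function(ref, eval, crit, interp = TRUE, step = NULL, cap = 2,
                      include = NULL, norm_dose = NULL) {
  stopifnot(inherits(ref, "dose_grid"), inherits(eval, "dose_grid"),
            inherits(crit, "gamma_criterion"))
  inc <- included_indices(ref, crit, include)
  norm <- if (is.null(norm_dose)) max_dose(ref) else as.double(norm_dose)
  dd_abs <- crit$dd / 100 * norm
  if (is.null(step)) step <- crit$dta / 10
  # the search must be able to reach the evaluated grid at all
  ax_r <- grid_axes(ref); ax_e <- grid_axes(eval)
  overlap <- all(vapply(1:3, function(a)
    min(ax_r[[a]]) <= max(ax_e[[a]]) + crit$dta * cap &&
    max(ax_r[[a]]) >= min(ax_e[[a]]) - crit$dta * cap, TRUE))
  if (!overlap)
    stop("gamma_map: geometry error, grids share no overlap", call. = FALSE)
  idx <- which(inc) - 1L
  g <- cpp_gamma_search(as.double(ref$values), dim(ref$values),
                        ref$origin, ref$spacing,
                        as.double(eval$values), dim(eval$values),
                        eval$origin, eval$spacing,
                        as.integer(idx), dd_abs, crit$dta,
                        as.double(step), as.double(cap), isTRUE(interp))
  vals <- array(NA_real_, dim(ref$values))
  vals[inc] <- g
  new_gamma_map(vals, inc, crit, ref, cap)
}

#' Brute-force gamma oracle
#'
#' Independent reference implementation: exhaustive minimization over *all*
#' evaluated voxel centers, no interpolation, no radius bound, pure R. Same
#' normalization, low-dose-threshold and cap rules as [gamma_map()]. Only
#' small grids are accepted — this exists as a test oracle, not a production
#' path.
#'
#' @inheritParams gamma_map
#' @param max_voxels refuse grids larger than this many voxels per side cubed
#'   (default 25^3).
#' @return A `gamma_map` object.
#' @export
brute_force_gamma <- function(ref, eval, crit, cap = 2, include = NULL,
                              norm_dose = NULL, max_voxels = 25^3) {
  stopifnot(inherits(ref, "dose_grid"), inherits(eval, "dose_grid"))
  if (length(ref$values) > max_voxels || length(eval$values) > max_voxels)
    stop("brute_force_gamma: size error, grid too large for the oracle", call. = FALSE)
  inc <- included_indices(ref, crit, include)
  norm <- if (is.null(norm_dose)) max_dose(ref) else as.double(norm_dose)
  dd_abs <- crit$dd / 100 * norm
  p_ref <- grid_positions(ref)[inc, , drop = FALSE]
  d_ref <- ref$values[inc]
  p_ev <- grid_positions(eval)
  d_ev <- as.vector(eval$values)
  dta2 <- crit$dta^2; dd2 <- dd_abs^2
  g2 <- rep(Inf, length(d_ref))
  for (j in seq_along(d_ev)) {
    d2 <- (p_ref[, 1] - p_ev[j, 1])^2 + (p_ref[, 2] - p_ev[j, 2])^2 +
          (p_ref[, 3] - p_ev[j, 3])^2
    g2 <- pmin(g2, d2 / dta2 + (d_ref - d_ev[j])^2 / dd2)
  }
  vals <- array(NA_real_, dim(ref$values))
  vals[inc] <- pmin(sqrt(g2), cap)
  new_gamma_map(vals, inc, crit, ref, cap)
}

#' Gamma pass rate
#'
#' Percentage of evaluated voxels with gamma strictly below 1.
#'
#' @param gmap a `gamma_map` from [gamma_map()] or [brute_force_gamma()].
#' @return Pass rate in percent, in \[0, 100\].
#' @export
gamma_pass_rate <- function(gmap) {
  stopifnot(inherits(gmap, "gamma_map"))
  g <- gmap$values[gmap$evaluated_mask]
  if (length(g) == 0)
    stop("gamma_pass_rate: empty-statistics error, no evaluated voxels", call. = FALSE)
  100 * mean(g < 1)
}

#' Write a gamma map as NRRD
#'
#' Non-evaluated voxels are stored as the sentinel `-1`.
#' @param gmap a `gamma_map`.
#' @param path output path.
#' @inheritParams write_nrrd
#' @return `path`, invisibly.
#' @export
write_gamma_nrrd <- function(gmap, path, encoding = "raw") {
  vals <- gmap$values
  vals[!gmap$evaluated_mask] <- -1   # sentinel for non-evaluated voxels
  d <- dim(vals)
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- c("NRRD0004", "type: double", "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("encoding: %s", encoding), "endian: little",
           "space dimension: 3",
           sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
                   gmap$spacing[1], gmap$spacing[2], gmap$spacing[3]),
           sprintf("space origin: (%.10g,%.10g,%.10g)",
                   gmap$origin[1], gmap$origin[2], gmap$origin[3]), "")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  if (encoding == "raw") writeBin(as.double(vals), con, size = 8, endian = "little")
  else writeBin(charToRaw(paste(format(as.double(vals), digits = 17, trim = TRUE),
                                collapse = "\n")), con)
  invisible(path)
}
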