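#' Axis-aligned 3D dose grid
#'
#' The unit of comparison throughout the package: a 3D scalar dose field in Gy
#' on an axis-aligned grid. Positions are carried by voxel *centers*, all
#' lengths are millimetres, and the axis order is (x, y, z) in patient
#' coordinates. Tilted orientations are rejected at the I/O layer.
#'
#' @param values numeric 3D array of doses in Gy; all finite and `>= 0`.
#' @param origin numeric length-3, position (mm) of the center of voxel
#'   `[1, 1, 1]`.
#' @param spacing numeric length-3, strictly positive voxel spacing (mm).
#' @return An object of class `dose_grid`: a list with elements `values`,
#'   `origin`, `spacing`.
#' @examples
#' g <- dose_grid(array(1, c(4, 4, 4)), origin = c(0, 0, 0), spacing = c(2.5, 2.5, 2.5))
#' max_dose(g)
#' @export
dose_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("dose_grid: `values` must be a 3D array", call. = FALSE)
  storage.mode(values) <- "double"
  origin <- as.double(origin); spacing <- as.double(spacing)
  if (length(origin) != 3L || length(spacing) != 3L)
    stop("dose_grid: `origin` and `spacing` must have length 3", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose_grid: dose values must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("dose_grid: geometry error, spacing must be strictly positive", call. = FALSE)
  structure(list(values = values, origin = origin, spacing = spacing),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  dose range [%.4g, %.4g] Gy\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Maximum dose of a grid
#' @param grid a [dose_grid()].
#' @return The maximum dose (Gy).
#' @export
max_dose <- function(grid) max(grid$values)

#' Voxel-center coordinates along each axis
#' @param grid a [dose_grid()] or [structure_mask()].
#' @return List of three numeric vectors (x, y, z positions in mm).
#' @export
grid_axes <- function(grid) {
  d <- dim(grid$values)
  lapply(1:3, function(a) grid$origin[a] + (seq_len(d[a]) - 1) * grid$spacing[a])
}

#' Voxel-center coordinates of every voxel
#' @param grid a [dose_grid()] or [structure_mask()].
#' @return n-by-3 matrix of positions (mm), rows in array order (x fastest).
#' @export
grid_positions <- function(grid) {
  ax <- grid_axes(grid)
  d <- dim(grid$values)
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' 3D structure mask on a dose grid's geometry
#'
#' A boolean field labelling voxels (e.g. the planning target volume). The
#' geometry must be identical to the grid the mask is used with.
#'
#' @param values logical 3D array.
#' @param grid a [dose_grid()] providing the geometry, or `NULL` if `origin`
#'   and `spacing` are given directly.
#' @param role free-text label, e.g. `"target"`.
#' @param origin,spacing geometry, used when `grid` is `NULL`.
#' @return Object of class `structure_mask` with elements `values`, `origin`,
#'   `spacing`, `role`.
#' @export
structure_mask <- function(values, grid = NULL, role = "target",
                           origin = NULL, spacing = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("structure_mask: `values` must be a 3D array", call. = FALSE)
  storage.mode(values) <- "logical"
  if (!is.null(grid)) {
    if (!identical(dim(values), dim(grid$values)))
      stop("structure_mask: geometry error, mask shape differs from grid", call. = FALSE)
    origin <- grid$origin; spacing <- grid$spacing
  }
  if (is.null(origin) || is.null(spacing))
    stop("structure_mask: supply `grid` or both `origin` and `spacing`", call. = FALSE)
  structure(list(values = values, origin = as.double(origin),
                 spacing = as.double(spacing), role = as.character(role)),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> role '%s', %d / %d voxels set\n",
              x$role, sum(x$values), length(x$values)))
  invisible(x)
}

#' Threshold mask at a fraction of the maximum dose
#'
#' Marks all voxels receiving at least `fraction` times the grid maximum.
#' Used both for the 5%-of-maximum low-dose exclusion of the global gamma
#' evaluation and for the 70%-of-maximum region in which Monte-Carlo noise
#' levels are specified.
#'
#' @param ref a [dose_grid()] with positive maximum.
#' @param fraction proportion of the maximum in (0, 1).
#' @param role label for the resulting mask.
#' @return A [structure_mask()] true where `dose >= fraction * max(ref)`.
#' @examples
#' g <- dose_grid(array(c(1, 3, 100, 1), c(4, 1, 1)))
#' sum(fractional_mask(g, 0.05)$values)  # only the 100 Gy voxel passes the 5 Gy cut
#' @export
fractional_mask <- function(ref, fraction = 0.05, role = "threshold") {
  stopifnot(inherits(ref, "dose_grid"))
  if (fraction <= 0 || fraction >= 1)
    stop("fractional_mask: `fraction` must be in (0, 1)", call. = FALSE)
  m <- max_dose(ref)
  if (m <= 0)
    stop("fractional_mask: empty-grid error, reference maximum is not positive",
         call. = FALSE)
  structure_mask(ref$values >= fraction * m, grid = ref, role = role)
}

#' Resample a dose grid onto a target geometry
#'
#' Trilinear interpolation of `moving` at the voxel centers of the target
#' geometry. Points outside the support of `moving` (beyond the outermost
#' voxel centers) are filled with 0 and flagged; downstream statistics exclude
#' them.
#'
#' @param moving a [dose_grid()].
#' @param origin,spacing,dim target geometry (voxel-center origin, spacing in
#'   mm, integer shape). Alternatively pass a `dose_grid`/`structure_mask` as
#'   `target` to copy its geometry.
#' @param target optional grid or mask whose geometry is used.
#' @return List with `grid` (the resampled [dose_grid()]) and
#'   `out_of_support` (a [structure_mask()] true where zero-fill occurred).
#' @export
resample_onto <- function(moving, origin = NULL, spacing = NULL, dim = NULL,
                          target = NULL) {
  stopifnot(inherits(moving, "dose_grid"))
  if (!is.null(target)) {
    origin <- target$origin; spacing <- target$spacing; dim <- base::dim(target$values)
  }
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L))
    stop("resample_onto: geometry error, invalid target shape", call. = FALSE)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("resample_onto: geometry error, degenerate target spacing", call. = FALSE)
  tgt <- structure(list(values = array(0, dim), origin = as.double(origin),
                        spacing = as.double(spacing)), class = "dose_grid")
  pts <- grid_positions(tgt)
  ti <- trilinear_at(moving, pts)
  vals <- ti$values
  vals[!ti$in_support] <- 0
  out <- dose_grid(array(vals, dim), origin = origin, spacing = spacing)
  oos <- structure_mask(array(!ti$in_support, dim), grid = out, role = "out_of_support")
  list(grid = out, out_of_support = oos)
}

# Vectorized trilinear interpolation at arbitrary points (n x 3 matrix, mm).
# Returns values and an in-support flag; out-of-support values are NA.
trilinear_at <- function(grid, pts) {
  d <- dim(grid$values)
  f <- sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")
  eps <- 1e-9
  inside <- f[, 1] >= -eps & f[, 1] <= d[1] - 1 + eps &
            f[, 2] >= -eps & f[, 2] <= d[2] - 1 + eps &
            f[, 3] >= -eps & f[, 3] <= d[3] - 1 + eps
  f <- pmax(f, 0)
  f <- sweep(f, 2, d - 1, pmin)
  i0 <- pmin(floor(f[, 1]), max(d[1] - 2, 0)); wx <- f[, 1] - i0
  j0 <- pmin(floor(f[, 2]), max(d[2] - 2, 0)); wy <- f[, 2] - j0
  k0 <- pmin(floor(f[, 3]), max(d[3] - 2, 0)); wz <- f[, 3] - k0
  # degenerate (single-voxel) axes interpolate trivially
  if (d[1] == 1L) wx <- 0
  if (d[2] == 1L) wy <- 0
  if (d[3] == 1L) wz <- 0
  v <- grid$values
  at <- function(di, dj, dk) {
    ii <- pmin(i0 + di, d[1] - 1); jj <- pmin(j0 + dj, d[2] - 1)
    kk <- pmin(k0 + dk, d[3] - 1)
    v[1 + ii + d[1] * (jj + d[2] * kk)]
  }
  val <- (1 - wx) * (1 - wy) * (1 - wz) * at(0, 0, 0) +
         wx       * (1 - wy) * (1 - wz) * at(1, 0, 0) +
         (1 - wx) * wy       * (1 - wz) * at(0, 1, 0) +
         wx       * wy       * (1 - wz) * at(1, 1, 0) +
         (1 - wx) * (1 - wy) * wz       * at(0, 0, 1) +
         wx       * (1 - wy) * wz       * at(1, 0, 1) +
         (1 - wx) * wy       * wz       * at(0, 1, 1) +
         wx       * wy       * wz       * at(1, 1, 1)
  val[!inside] <- NA_real_
  list(values = val, in_support = inside)
}
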