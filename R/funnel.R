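#' Funnel restraint geometry
#'
#' Cone-plus-cylinder boundary used to confine an unbound peptide: a cone
#' with its wide end at the membrane (z = 0) narrowing with half-angle
#' `alpha` up to the switch height `zcc`, continued by a cylinder of radius
#' `rcyl` directed toward the solvent. A harmonic one-sided wall of
#' stiffness `k_wall` acts outside the boundary; an optional top wall caps
#' the funnel at `zmax`. Defaults follow the funnel-restrained sampling
#' setup for a peptide-bilayer system: alpha 0.8 rad, rcyl 1 A, zcc 35 A.
#'
#' @param alpha cone half-angle, rad, in (0, pi/2).
#' @param rcyl cylinder radius, Angstrom, > 0.
#' @param zcc cone-to-cylinder switch height above the membrane centre, A.
#' @param origin axis origin (membrane centre of mass), length-3, A.
#' @param axis axis direction (bilayer normal); normalised internally.
#' @param zmax optional top-wall height, A (`NULL` disables the top wall).
#' @param k_wall wall stiffness, kcal mol^-1 A^-2.
#' @return object of class `mg_funnel`.
#' @export
funnel_geometry <- function(alpha = 0.8, rcyl = 1, zcc = 35,
                            origin = c(0, 0, 0), axis = c(0, 0, 1),
                            zmax = 45, k_wall = 10) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= pi / 2)
    stop("alpha must lie in (0, pi/2)")
  if (!is.finite(rcyl) || rcyl <= 0) stop("rcyl must be positive")
  if (!is.finite(zcc) || zcc <= 0) stop("zcc must be positive")
  if (!is.null(zmax) && (!is.finite(zmax) || zmax <= zcc))
    stop("zmax must exceed zcc")
  if (!is.finite(k_wall) || k_wall <= 0) stop("k_wall must be positive")
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("axis direction must be non-zero")
  axis <- axis / nrm
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-12)
    stop("axis normalisation failed")
  structure(list(alpha = alpha, rcyl = rcyl, zcc = zcc,
                 origin = as.numeric(origin), axis = as.numeric(axis),
                 zmax = zmax, k_wall = k_wall),
            class = "mg_funnel")
}

#' @export
print.mg_funnel <- function(x, ...) {
  cat(sprintf(
    "mg_funnel: alpha %.3f rad, rcyl %.2f A, zcc %.1f A, k_wall %.1f%s\n",
    x$alpha, x$rcyl, x$zcc, x$k_wall,
    if (is.null(x$zmax)) ", no top wall"
    else sprintf(", zmax %.1f A", x$zmax)))
  invisible(x)
}

#' Funnel boundary radius
#'
#' r(z) = rcyl + max(0, zcc - z) * tan(alpha): linearly widening toward the
#' membrane below the switch height, constant rcyl above it. Continuous and
#' non-increasing in z; a total function of finite z.
#'
#' @param z axial coordinate(s), Angstrom (0 at the membrane centre).
#' @param geometry an `mg_funnel`.
#' @return boundary radius (Angstrom), vectorised over `z`.
#' @export
boundary_radius <- function(z, geometry) {
  geometry$rcyl + pmax(0, geometry$zcc - z) * tan(geometry$alpha)
}

## Decompose points (n x 3) into axial coordinate and radial distance.
.funnel_frame <- function(points, geometry) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  rel <- sweep(points, 2L, geometry$origin)
  zax <- as.numeric(rel %*% geometry$axis)
  rad2 <- pmax(rowSums(rel^2) - zax^2, 0)
  list(z = zax, rho = sqrt(rad2), rel = rel)
}

#' Funnel wall bias energy
#'
#' Zero strictly inside the boundary (points exactly on the boundary are
#' unbiased); outside, a harmonic penalty `0.5 * k_wall * (rho - r(z))^2`,
#' plus `0.5 * k_wall * (z - zmax)^2` above an enabled top wall.
#'
#' @param point a length-3 vector or an `n x 3` matrix of positions, A.
#' @param geometry an `mg_funnel`.
#' @return energy (kcal mol^-1), one value per point; always >= 0.
#' @export
bias_energy <- function(point, geometry) {
  f <- .funnel_frame(point, geometry)
  over <- pmax(0, f$rho - boundary_radius(f$z, geometry))
  e <- 0.5 * geometry$k_wall * over^2
  if (!is.null(geometry$zmax))
    e <- e + 0.5 * geometry$k_wall * pmax(0, f$z - geometry$zmax)^2
  e
}

#' Funnel wall bias force
#'
#' Analytic negative gradient of [bias_energy()]: zero strictly inside,
#' continuous across the wall. For a point outside the boundary that sits
#' exactly on the axis the radial push direction is undefined and an error
#' is raised.
#'
#' @param point length-3 position, Angstrom.
#' @param geometry an `mg_funnel`.
#' @return length-3 force vector, kcal mol^-1 A^-1.
#' @export
bias_force <- function(point, geometry) {
  f <- .funnel_frame(matrix(point, ncol = 3L), geometry)
  z <- f$z[1L]; rho <- f$rho[1L]
  r <- boundary_radius(z, geometry)
  force <- c(0, 0, 0)
  if (rho > r) {
    if (rho < 1e-12)
      stop("degenerate direction: exterior point lies exactly on the axis")
    u <- (f$rel[1L, ] - z * geometry$axis) / rho
    dU_drho <- geometry$k_wall * (rho - r)
    drdz <- if (z < geometry$zcc) -tan(geometry$alpha) else 0
    dU_dz <- -geometry$k_wall * (rho - r) * drdz
    force <- -dU_drho * u - dU_dz * geometry$axis
  }
  if (!is.null(geometry$zmax) && z > geometry$zmax)
    force <- force - geometry$k_wall * (z - geometry$zmax) * geometry$axis
  force
}

#' Flag frames that feel the funnel wall
#'
#' Frames whose tracked-selection geometric centre experiences a non-zero
#' wall energy are flagged; downstream statistics drop flagged frames, so
#' only unbiased configurations enter averages. The tracked point is the
#' unweighted geometric centre of the selection.
#'
#' @param trajectory an `mg_trajectory`.
#' @param geometry an `mg_funnel`.
#' @param tracked_selection an `mg_selection` (non-empty).
#' @return logical vector, one flag per frame (`TRUE` = biased).
#' @export
frame_bias_flags <- function(trajectory, geometry, tracked_selection) {
  idx <- tracked_selection$indices
  if (length(idx) == 0L) stop("tracked selection is empty")
  nf <- n_frames(trajectory)
  centers <- t(vapply(seq_len(nf), function(i) {
    colMeans(trajectory$coords[idx, , i, drop = FALSE])
  }, numeric(3L)))
  bias_energy(centers, geometry) > 0
}
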