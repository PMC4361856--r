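#' Switching-function parameters
#'
#' Parameters of the rational switching function
#' `s(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)` used to count smooth
#' peptide-membrane contacts. Defaults r0 = 5 A, n = 8, m = 16.
#'
#' @param r0 contact distance scale, Angstrom, > 0.
#' @param n numerator exponent, positive even integer, < m.
#' @param m denominator exponent, positive even integer.
#' @return object of class `mg_switch`.
#' @export
switching_params <- function(r0 = 5, n = 8L, m = 16L) {
  if (!is.finite(r0) || r0 <= 0) stop("r0 must be positive")
  if (n <= 0 || m <= 0 || n != round(n) || m != round(m))
    stop("n and m must be positive integers")
  if (n %% 2 != 0 || m %% 2 != 0) stop("n and m must be even")
  if (n >= m) stop("n must be smaller than m")
  structure(list(r0 = r0, n = as.integer(n), m = as.integer(m)),
            class = "mg_switch")
}

#' Evaluate the switching function
#'
#' Smoothly decays from 1 at r = 0 toward 0 at large r, strictly decreasing.
#' The removable singularity at r = r0 is handled analytically and returns
#' the limit n/m. For the common case m = 2n the algebraically equivalent
#' stable form `1 / (1 + (r/r0)^n)` is used everywhere.
#'
#' @param r distances, Angstrom, >= 0 (vectorised).
#' @param params an `mg_switch`.
#' @return values in (0, 1].
#' @export
switch_value <- function(r, params) {
  if (any(r < 0)) stop("distances must be non-negative")
  x <- r / params$r0
  if (params$m == 2L * params$n) return(1 / (1 + x^params$n))
  out <- numeric(length(x))
  at_r0 <- abs(x - 1) < 1e-12
  out[at_r0] <- params$n / params$m
  out[!at_r0] <- (1 - x[!at_r0]^params$n) / (1 - x[!at_r0]^params$m)
  out
}

## Pairwise distances between two coordinate blocks, minimum-image when an
## orthorhombic box is given.
.pair_dists <- function(a, b, box = NULL) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

#' Contact collective variable for one frame
#'
#' Sum of the switching function over all pairs between two disjoint atom
#' groups. Under `"per_group_atom"` normalisation (the default) the raw sum
#' is divided by the size of `group_a` (the peptide-side selection), so one
#' ideal contact per tracked atom gives s of order 1 and the absolute bound
#' threshold 0.5 is meaningful; `"raw_sum"` keeps the plain pair sum.
#'
#' @param frame `n_atoms x 3` coordinate matrix, Angstrom.
#' @param group_a,group_b `mg_selection`s, non-empty and disjoint.
#' @param params an `mg_switch`.
#' @param normalization `"per_group_atom"` or `"raw_sum"`.
#' @param box optional orthorhombic box lengths (minimum-image convention).
#' @return scalar contact value s (dimensionless, >= 0).
#' @export
contact_value <- function(frame, group_a, group_b, params,
                          normalization = c("per_group_atom", "raw_sum"),
                          box = NULL) {
  normalization <- match.arg(normalization)
  ia <- group_a$indices; ib <- group_b$indices
  if (length(ia) == 0L || length(ib) == 0L)
    stop("contact groups must be non-empty")
  if (length(intersect(ia, ib)) > 0L)
    stop("contact groups must be disjoint")
  d <- .pair_dists(frame[ia, , drop = FALSE], frame[ib, , drop = FALSE], box)
  s <- sum(switch_value(d, params))
  if (normalization == "per_group_atom") s <- s / length(ia)
  s
}

#' Per-side contact time series
#'
#' Computes the contact collective variable between each helix-side Calpha
#' selection and the membrane phosphate atoms for every frame, carrying the
#' funnel-biased frame mask so that excluded frames never enter summary
#' statistics.
#'
#' @param trajectory an `mg_trajectory`.
#' @param side1,side2 `mg_selection`s of the two helix faces (disjoint).
#' @param phosphate `mg_selection` of membrane phosphate atoms.
#' @param params an `mg_switch`.
#' @param excluded optional logical mask of biased frames (length =
#'   frame count); `NULL` means no frame is excluded.
#' @param normalization passed to [contact_value()].
#' @return list with elements `side1` and `side2`, each an
#'   `mg_contact_series`: data.frame `frame`, `time_ps`, `s`, `excluded`
#'   with the side label, parameters and normalisation as attributes.
#' @export
per_side_series <- function(trajectory, side1, side2, phosphate, params,
                            excluded = NULL,
                            normalization = c("per_group_atom", "raw_sum")) {
  normalization <- match.arg(normalization)
  if (length(intersect(side1$indices, side2$indices)) > 0L)
    stop("side selections must not overlap")
  nf <- n_frames(trajectory)
  if (is.null(excluded)) excluded <- rep(FALSE, nf)
  if (length(excluded) != nf)
    stop("excluded mask length must equal the frame count")
  time <- trajectory$time %||% rep(NA_real_, nf)
  one_side <- function(sel, label) {
    s <- vapply(seq_len(nf), function(i) {
      contact_value(trajectory$coords[, , i, drop = TRUE], sel, phosphate,
                    params, normalization,
                    box = if (!is.null(trajectory$box)) trajectory$box[i, ])
    }, numeric(1L))
    structure(
      data.frame(frame = seq_len(nf), time_ps = time, s = s,
                 excluded = excluded),
      side = label, params = params, normalization = normalization,
      class = c("mg_contact_series", "data.frame"))
  }
  list(side1 = one_side(side1, "Side1"), side2 = one_side(side2, "Side2"))
}

#' Summary statistics of a contact series
#'
#' @param object an `mg_contact_series`.
#' @param ... unused.
#' @return list with mean s, retained and excluded frame counts.
#' @export
summary.mg_contact_series <- function(object, ...) {
  keep <- !object$excluded
  list(side = attr(object, "side"),
       mean_s = if (any(keep)) mean(object$s[keep]) else NA_real_,
       n_retained = sum(keep), n_excluded = sum(!keep))
}

#' Classify bound frames
#'
#' A frame is a bound pose when its contact value strictly exceeds the
#' threshold (default 0.5); funnel-excluded frames are never bound. The
#' bound fraction is reported over retained frames.
#'
#' @param series an `mg_contact_series`.
#' @param threshold dimensionless contact threshold.
#' @return logical per-frame mask with attributes `bound_fraction` and
#'   `n_retained`.
#' @export
classify_bound <- function(series, threshold = 0.5) {
  keep <- !series$excluded
  mask <- keep & series$s > threshold
  frac <- if (any(keep)) sum(mask) / sum(keep) else 0
  structure(mask, bound_fraction = frac, n_retained = sum(keep))
}
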