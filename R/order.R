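#' C-H bond vectors of one acyl carbon
#'
#' Unit vectors from a chain carbon to its hydrogens. In `"explicit"` mode
#' the hydrogens must be present in the topology; in `"reconstructed"` mode
#' the two methylene hydrogen directions are rebuilt from the carbon and its
#' two chain-neighbour carbons with ideal tetrahedral geometry (H-C-H angle
#' 109.47 deg), which requires both neighbours and therefore excludes the
#' terminal methyl carbon.
#'
#' @param frame `n_atoms x 3` coordinate matrix.
#' @param topology an `mg_topology`.
#' @param lipid lipid id.
#' @param chain acyl chain, `"c1"` or `"c2"`.
#' @param carbon carbon index (2..14 for a myristoyl chain).
#' @param h_mode `"explicit"` or `"reconstructed"`.
#' @return matrix of unit row vectors (one per hydrogen).
#' @export
ch_vectors <- function(frame, topology, lipid, chain, carbon,
                       h_mode = c("explicit", "reconstructed")) {
  h_mode <- match.arg(h_mode)
  at <- topology$atoms
  sel_c <- which(at$role == "carbon" & at$lipid_id == lipid &
                 at$acyl == chain & at$carbon == carbon)
  if (length(sel_c) != 1L)
    stop("carbon ", carbon, " of chain ", chain, " not found for lipid ",
         lipid)
  c_pos <- frame[sel_c, ]
  if (h_mode == "explicit") {
    sel_h <- which(at$role == "hydrogen" & at$lipid_id == lipid &
                   at$acyl == chain & at$carbon == carbon)
    if (length(sel_h) == 0L)
      stop("no explicit hydrogens on carbon ", carbon, " of chain ", chain)
    v <- frame[sel_h, , drop = FALSE] - matrix(c_pos, length(sel_h), 3L,
                                               byrow = TRUE)
    v / sqrt(rowSums(v^2))
  } else {
    prev_i <- which(at$role == "carbon" & at$lipid_id == lipid &
                    at$acyl == chain & at$carbon == carbon - 1L)
    next_i <- which(at$role == "carbon" & at$lipid_id == lipid &
                    at$acyl == chain & at$carbon == carbon + 1L)
    if (length(prev_i) != 1L || length(next_i) != 1L)
      stop("terminal carbon: reconstruction needs both chain neighbours ",
           "of carbon ", carbon)
    a <- frame[prev_i, ] - c_pos; a <- a / sqrt(sum(a^2))
    b <- frame[next_i, ] - c_pos; b <- b / sqrt(sum(b^2))
    u <- -(a + b); u <- u / sqrt(sum(u^2))
    v <- c(a[2L] * b[3L] - a[3L] * b[2L],
           a[3L] * b[1L] - a[1L] * b[3L],
           a[1L] * b[2L] - a[2L] * b[1L])
    v <- v / sqrt(sum(v^2))
    half <- 0.5 * acos(-1 / 3)   # half the tetrahedral H-C-H angle
    rbind(cos(half) * u + sin(half) * v,
          cos(half) * u - sin(half) * v)
  }
}

#' Acyl-chain deuterium order parameter profile
#'
#' Per-carbon S_CD = <(3 cos^2 theta - 1) / 2> with theta the angle between
#' each C-H bond vector and the bilayer normal, averaged over hydrogens,
#' lipids and retained frames. S_CD is +1 for bonds along the normal, -0.5
#' perpendicular, 0 for isotropic orientations. Uncertainties come from
#' block averaging over contiguous frame blocks. Both leaflets are pooled;
#' the normal is the fixed frame +z by default (the bilayer is built
#' pre-oriented).
#'
#' @param trajectory an `mg_trajectory` of the bilayer.
#' @param topology defaults to the trajectory's topology.
#' @param chain `"c1"` or `"c2"`.
#' @param normal unit bilayer normal.
#' @param h_mode `"explicit"` (default) or `"reconstructed"`.
#' @param excluded optional logical per-frame exclusion mask.
#' @param n_blocks number of blocks for the standard error.
#' @return `mg_order_profile`: data.frame with columns `chain`, `carbon`,
#'   `scd`, `abs_scd`, `se`, `n_samples`.
#' @export
scd_profile <- function(trajectory, topology = NULL, chain = "c1",
                        normal = c(0, 0, 1),
                        h_mode = c("explicit", "reconstructed"),
                        excluded = NULL, n_blocks = 5L) {
  h_mode <- match.arg(h_mode)
  topology <- topology %||% trajectory$topology
  if (!chain %in% c("c1", "c2")) stop("chain must be 'c1' or 'c2'")
  at <- topology$atoms
  if (!any(at$role == "carbon" & at$acyl == chain, na.rm = TRUE))
    stop("chain ", chain, " absent from topology")
  nf <- n_frames(trajectory)
  if (is.null(excluded)) excluded <- rep(FALSE, nf)
  frames <- which(!excluded)
  if (length(frames) == 0L) stop("no retained frames")
  normal <- normal / sqrt(sum(normal^2))
  if (h_mode == "explicit") {
    hy <- which(at$role == "hydrogen" & at$acyl == chain)
    if (length(hy) == 0L)
      stop("no explicit hydrogens on chain ", chain,
           "; use h_mode = 'reconstructed'")
    key <- paste(at$lipid_id[hy], at$carbon[hy])
    cidx <- match(key, paste(at$lipid_id, at$carbon)[
      at$role == "carbon" & at$acyl == chain])
    carb_atoms <- which(at$role == "carbon" & at$acyl == chain)
    cat_of_h <- carb_atoms[cidx]
    carbon_of_h <- at$carbon[hy]
    per_frame <- function(f) {
      xyz <- trajectory$coords[, , f, drop = TRUE]
      v <- xyz[hy, , drop = FALSE] - xyz[cat_of_h, , drop = FALSE]
      ct <- as.numeric(v %*% normal) / sqrt(rowSums(v^2))
      p2 <- 0.5 * (3 * ct^2 - 1)
      rowsum(cbind(p2, 1), group = carbon_of_h)
    }
  } else {
    carbons_all <- sort(unique(at$carbon[at$role == "carbon" &
                                         at$acyl == chain]))
    inner <- carbons_all[carbons_all > min(carbons_all) &
                         carbons_all < max(carbons_all)]
    lipids <- unique(at$lipid_id[at$role == "carbon" & at$acyl == chain])
    per_frame <- function(f) {
      xyz <- trajectory$coords[, , f, drop = TRUE]
      acc <- matrix(0, length(inner), 2L,
                    dimnames = list(inner, NULL))
      for (lp in lipids) {
        for (ci in seq_along(inner)) {
          vv <- ch_vectors(xyz, topology, lp, chain, inner[ci],
                           h_mode = "reconstructed")
          ct <- as.numeric(vv %*% normal)
          acc[ci, 1L] <- acc[ci, 1L] + sum(0.5 * (3 * ct^2 - 1))
          acc[ci, 2L] <- acc[ci, 2L] + nrow(vv)
        }
      }
      acc
    }
  }
  sums <- lapply(frames, per_frame)
  carbons <- as.integer(rownames(sums[[1L]]))
  tot <- Reduce(`+`, sums)
  scd <- tot[, 1L] / tot[, 2L]
  nb <- min(n_blocks, length(frames))
  if (nb >= 2L) {
    blocks <- split(seq_along(frames),
                    cut(seq_along(frames), breaks = nb, labels = FALSE))
    block_means <- vapply(blocks, function(bi) {
      bt <- Reduce(`+`, sums[bi])
      bt[, 1L] / bt[, 2L]
    }, numeric(length(carbons)))
    if (is.null(dim(block_means)))
      block_means <- matrix(block_means, nrow = length(carbons))
    se <- apply(block_means, 1L, sd) / sqrt(ncol(block_means))
    se[is.na(se)] <- 0
  } else {
    se <- rep(0, length(carbons))   # a single frame carries no block error
  }
  structure(
    data.frame(chain = chain, carbon = carbons, scd = unname(scd),
               abs_scd = abs(unname(scd)), se = unname(se),
               n_samples = as.integer(tot[, 2L])),
    class = c("mg_order_profile", "data.frame"))
}

#' Compare two order-parameter profiles
#'
#' Per-carbon difference (a - b) with combined standard error
#' `sqrt(se_a^2 + se_b^2)`; carbons where |delta| exceeds `z` combined
#' standard errors (plus a tiny absolute guard against float noise) are
#' flagged as perturbed, and the deepest flagged carbon per chain is
#' reported.
#'
#' @param profile_a,profile_b `mg_order_profile`s over matching chains and
#'   carbon ranges.
#' @param z flagging multiple of the combined standard error.
#' @param tol absolute guard added to the flag threshold.
#' @return data.frame `chain`, `carbon`, `delta`, `se`, `flagged` with
#'   attribute `deepest_carbon` (named by chain; `NA` when nothing is
#'   flagged).
#' @export
profile_compare <- function(profile_a, profile_b, z = 2, tol = 1e-9) {
  if (!identical(profile_a$chain, profile_b$chain) ||
      !identical(profile_a$carbon, profile_b$carbon))
    stop("profile chain/carbon ranges do not match")
  delta <- profile_a$scd - profile_b$scd
  se <- sqrt(profile_a$se^2 + profile_b$se^2)
  flagged <- abs(delta) > z * se + tol
  out <- data.frame(chain = profile_a$chain, carbon = profile_a$carbon,
                    delta = delta, se = se, flagged = flagged)
  deepest <- vapply(split(out, out$chain), function(d) {
    if (any(d$flagged)) max(d$carbon[d$flagged]) else NA_integer_
  }, integer(1L))
  structure(out, deepest_carbon = deepest)
}
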