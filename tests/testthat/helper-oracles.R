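## Independent oracles used to cross-check the package implementations.
## Each oracle deliberately avoids the package's own code path.

## Central finite-difference gradient of a scalar function of a 3-vector.
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(1:3, function(k) {
    e <- numeric(3L); e[k] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1L))
}

## Rational switching function evaluated from the closed form (independent
## of switch_value); r exactly at r0 has measure zero for random inputs.
oracle_switch <- function(r, r0, n, m) {
  x <- r / r0
  (1 - x^n) / (1 - x^m)
}

## Brute-force O(N^2) contact sum with an explicit double loop.
oracle_contact <- function(frame, ia, ib, r0, n, m, box = NULL,
                           normalize = TRUE) {
  s <- 0
  for (i in ia) {
    for (j in ib) {
      d <- frame[i, ] - frame[j, ]
      if (!is.null(box)) d <- d - box * round(d / box)
      s <- s + oracle_switch(sqrt(sum(d^2)), r0, n, m)
    }
  }
  if (normalize) s / length(ia) else s
}

## Exhaustive unweighted average-linkage agglomeration on a full distance
## matrix: recomputes every inter-cluster average at every step. Returns
## the merge heights and the flat partition at every cluster count.
oracle_upgma <- function(D) {
  k <- nrow(D)
  clusters <- as.list(seq_len(k))
  partitions <- list()
  partitions[[k]] <- seq_len(k)
  heights <- numeric(0L)
  labels <- seq_len(k)
  while (length(clusters) > 1L) {
    nc <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d - 1e-15) {  # strict improvement; first pair wins ties
          best_d <- d; best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- c(clusters[-best], list(merged))
    lab <- integer(k)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[length(clusters)]] <- lab
  }
  list(heights = sort(heights), partitions = partitions)
}

## Label-invariant signature of a flat partition.
partition_signature <- function(labels) {
  paste(match(labels, unique(labels)), collapse = ",")
}

## Numeric RMSD minimisation over proper rotations (Euler angles) after
## centroid removal; multi-start Nelder-Mead. Independent of the SVD route.
oracle_min_rmsd <- function(moving, reference) {
  P <- sweep(moving, 2L, colMeans(moving))
  Q <- sweep(reference, 2L, colMeans(reference))
  rot <- function(ang) {
    cx <- cos(ang[1L]); sx <- sin(ang[1L])
    cy <- cos(ang[2L]); sy <- sin(ang[2L])
    cz <- cos(ang[3L]); sz <- sin(ang[3L])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((P %*% rot(ang) - Q)^2)))
  best <- Inf
  for (start in list(c(0, 0, 0), c(1, 1, 1), c(-1, 2, 0.5), c(2, -1, -2),
                     c(3, 0.2, 1.5), c(-2.5, -0.7, 2.8))) {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

## Equilibrium bound probability of the simulator's potential by direct
## Boltzmann quadrature over (z, phi), with the funnel wall entering as a
## lateral configurational weight A(z). Mirrors the integrator's energy
## terms exactly (including the k_core * d^2 repulsion convention).
oracle_bound_fraction <- function(helix, config) {
  kT <- 0.0019872041 * config$temperature
  depth <- unname(config$depths[helix$class])
  center <- config$z_surface + unname(config$offsets[helix$class])
  fz <- config$funnel
  w <- config$well_width
  u_mem <- function(z, phi) {
    zb <- z + helix$radial * cos(phi + helix$phase)
    u <- sum(-depth * exp(-(zb - center)^2 / (2 * w^2)))
    d <- pmax(0, config$z_core - zb)
    u + config$k_core * sum(d^2)
  }
  lateral_weight <- function(z) {
    r <- fz$rcyl + max(0, fz$zcc - z) * tan(fz$alpha)
    sigma <- sqrt(kT / fz$k_wall)
    rho <- seq(0, r + 8 * sigma, length.out = 400L)
    wall <- 0.5 * fz$k_wall * pmax(0, rho - r)^2
    a <- sum(rho * exp(-wall / kT)) * (rho[2L] - rho[1L]) * 2 * pi
    if (!is.null(fz$zmax))
      a <- a * exp(-0.5 * fz$k_wall * max(0, z - fz$zmax)^2 / kT)
    a
  }
  zs <- seq(config$z_core - 3, (fz$zmax %||% 60) + 3, by = 0.05)
  phis <- seq(0, 2 * pi, length.out = 181L)[-181L]
  az <- vapply(zs, lateral_weight, numeric(1L))
  ## mean peptide-bead height at (z, phi); all beads counted, as in the
  ## ground-truth rule
  mean_offset <- vapply(phis, function(phi)
    mean(helix$radial * cos(phi + helix$phase)), numeric(1L))
  num <- 0; den <- 0
  for (pi_ in seq_along(phis)) {
    u <- vapply(zs, u_mem, numeric(1L), phi = phis[pi_])
    wgt <- az * exp(-u / kT + 30)   # fixed offset avoids underflow,
    bound <- (zs + mean_offset[pi_]) < config$bound_cutoff  # cancels in ratio
    num <- num + sum(wgt[bound])
    den <- den + sum(wgt)
  }
  num / den
}

## Block-averaged standard error of the mean of a (possibly correlated)
## series.
block_se <- function(x, n_blocks = 10L) {
  groups <- cut(seq_along(x), breaks = n_blocks, labels = FALSE)
  means <- tapply(x, groups, mean)
  stats::sd(means) / sqrt(length(means))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
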