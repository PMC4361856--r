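#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of `moving` onto `reference` over proper
#' rotations and translations, via SVD of the cross-covariance matrix with
#' the usual sign correction so the rotation determinant is +1.
#'
#' @param moving,reference `n x 3` matrices, n >= 3, equal row counts.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3;
#'   aligned = moving %*% rotation + translation), `rmsd` (Angstrom) and
#'   `aligned` coordinates.
#' @export
kabsch_superpose <- function(moving, reference) {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  if (!all(dim(moving) == dim(reference)))
    stop("point counts of moving and reference differ")
  n <- nrow(moving)
  if (n < 3L) stop("superposition needs at least 3 points")
  cm <- colMeans(moving); cr <- colMeans(reference)
  P <- sweep(moving, 2L, cm); Q <- sweep(reference, 2L, cr)
  C <- crossprod(P, Q)
  sv <- svd(C)
  scale <- sqrt(mean(rowSums(P^2)) * mean(rowSums(Q^2)))
  if (scale > 0 && sv$d[2L] / max(sv$d[1L], .Machine$double.eps) < 1e-10 &&
      sv$d[1L] > 1e-8 * scale)
    stop("degenerate (collinear) configuration: superposition ill-conditioned")
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- P %*% R
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  list(rotation = R, translation = cr - as.numeric(cm %*% R),
       rmsd = rmsd, aligned = sweep(aligned, 2L, cr, "+"))
}

## Core Calpha atom indices for RMSD work.
.core_ca_indices <- function(topology, core = NULL) {
  core <- core %||% topology$helix_core
  at <- topology$atoms
  idx <- which(at$segment == "peptide" & at$role == "ca" &
               at$res_id >= core[1L] & at$res_id <= core[2L])
  if (length(idx) == 0L)
    stop("core residue range ", core[1L], "-", core[2L],
         " selects no Calpha atoms in this topology")
  idx
}

#' Helix-core Calpha RMSD between two frames
#'
#' Superposition-minimised RMSD over the Calpha atoms of the helix core
#' (default: the topology's core range, residues 5-12 for the bundled
#' 21-residue peptide).
#'
#' @param frame_a,frame_b `n_atoms x 3` coordinate matrices sharing
#'   `topology`.
#' @param topology an `mg_topology`.
#' @param core inclusive residue range, default `topology$helix_core`.
#' @return RMSD, Angstrom.
#' @export
core_rmsd <- function(frame_a, frame_b, topology, core = NULL) {
  idx <- .core_ca_indices(topology, core)
  kabsch_superpose(frame_a[idx, , drop = FALSE],
                   frame_b[idx, , drop = FALSE])$rmsd
}

#' Pairwise core-RMSD matrix over bound frames
#'
#' @param trajectory an `mg_trajectory`.
#' @param bound_mask logical per-frame mask of bound poses (>= 2 TRUE).
#' @param topology topology shared by the frames (defaults to the
#'   trajectory's own).
#' @param core inclusive core residue range.
#' @return object of class `mg_distmat`: a `dist` of pairwise RMSD values
#'   plus the map back to trajectory frame indices.
#' @export
rmsd_matrix <- function(trajectory, bound_mask, topology = NULL,
                        core = NULL) {
  topology <- topology %||% trajectory$topology
  frames <- which(bound_mask)
  k <- length(frames)
  if (k < 2L) stop("insufficient data: need at least 2 bound frames")
  idx <- .core_ca_indices(topology, core)
  coords <- lapply(frames, function(f)
    trajectory$coords[idx, , f, drop = TRUE])
  m <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      m[i, j] <- m[j, i] <- kabsch_superpose(coords[[i]], coords[[j]])$rmsd
    }
  }
  structure(list(dist = as.dist(m), frames = frames, core_coords = coords),
            class = "mg_distmat")
}

#' Average-linkage clustering of bound poses
#'
#' Unweighted average-linkage (UPGMA-style) agglomeration of the pose RMSD
#' matrix, with flat labels obtained by cutting the merge tree at the
#' requested family count. Clusters are renumbered by decreasing
#' population (ties by first occurrence) so cluster 1 is the most populated
#' family.
#'
#' @param matrix an `mg_distmat` from [rmsd_matrix()].
#' @param n_clusters number of families to cut to, in `[1, k]`.
#' @return object of class `mg_clusters`: merge tree (`merge`, `height`),
#'   per-pose `labels`, `populations` (count and fraction per cluster) and
#'   the trajectory `frames` clustered.
#' @export
average_linkage <- function(matrix, n_clusters = 10L) {
  k <- length(matrix$frames)
  if (n_clusters < 1L || n_clusters > k)
    stop("n_clusters must lie in [1, ", k, "]")
  hc <- stats::hclust(matrix$dist, method = "average")
  labels <- stats::cutree(hc, k = n_clusters)
  sizes <- table(labels)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  labels <- unname(relabel[as.character(labels)])
  sizes <- table(labels)
  populations <- data.frame(
    cluster = as.integer(names(sizes)),
    population = as.integer(sizes),
    fraction = as.integer(sizes) / k)
  structure(list(merge = hc$merge, height = hc$height, labels = labels,
                 populations = populations, frames = matrix$frames,
                 n_clusters = n_clusters, hclust = hc,
                 core_coords = matrix$core_coords),
            class = "mg_clusters")
}

#' @export
print.mg_clusters <- function(x, ...) {
  cat("mg_clusters:", length(x$frames), "poses in", x$n_clusters,
      "families\n")
  print(x$populations, row.names = FALSE)
  invisible(x)
}

## Iterative mean structure: superpose members onto the running mean until
## the mean moves by less than tol (RMS over atoms).
.average_structure <- function(coords, tol = 1e-6, max_iter = 200L) {
  mean_s <- coords[[1L]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(coords, function(m) kabsch_superpose(m, mean_s)$aligned)
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    shift <- sqrt(mean(rowSums((new_mean - mean_s)^2)))
    mean_s <- new_mean
    if (shift < tol) break
  }
  mean_s
}

#' Representative pose per cluster
#'
#' For each family, the cluster-average core Calpha structure is built by
#' iterative superposition onto the running mean (stopping when the mean
#' shifts by < 1e-6 A) and the member with the lowest core RMSD to that
#' average is returned; ties go to the lowest frame index.
#'
#' @param result an `mg_clusters`.
#' @param trajectory the clustered `mg_trajectory` (used only when the
#'   cluster object does not carry core coordinates).
#' @param topology,core as in [core_rmsd()].
#' @return named integer vector of representative trajectory frame indices
#'   (one per cluster), with the per-cluster average structures and
#'   RMSD-to-average of each representative as attributes.
#' @export
representatives <- function(result, trajectory = NULL, topology = NULL,
                            core = NULL) {
  coords <- result$core_coords
  if (is.null(coords)) {
    topology <- topology %||% trajectory$topology
    idx <- .core_ca_indices(topology, core)
    coords <- lapply(result$frames, function(f)
      trajectory$coords[idx, , f, drop = TRUE])
  }
  clusters <- sort(unique(result$labels))
  reps <- integer(length(clusters))
  rep_rmsd <- numeric(length(clusters))
  averages <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    members <- which(result$labels == clusters[ci])
    avg <- .average_structure(coords[members])
    d <- vapply(members, function(mi)
      kabsch_superpose(coords[[mi]], avg)$rmsd, numeric(1L))
    best <- members[which.min(d)]   # ties: first member = lowest frame index
    reps[ci] <- result$frames[best]
    rep_rmsd[ci] <- min(d)
    averages[[ci]] <- avg
  }
  structure(setNames(reps, paste0("cluster", clusters)),
            averages = averages, rmsd_to_average = rep_rmsd)
}
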