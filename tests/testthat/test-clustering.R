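## pose_clustering: superposition, RMSD matrices, average linkage,
## representatives.

test_that("kabsch superposition handles trivial and rigid cases", {
  set.seed(21)
  ref <- matrix(rnorm(30), 10L, 3L)
  same <- kabsch_superpose(ref, ref)
  expect_lt(same$rmsd, 1e-12)
  expect_equal(det(same$rotation), 1, tolerance = 1e-10)
  R <- memglyco:::.random_rotation()
  moved <- sweep(ref %*% R, 2L, c(4, -2, 9), "+")
  fit <- kabsch_superpose(moved, ref)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  ## returned transform reproduces the aligned coordinates
  expect_equal(sweep(moved %*% fit$rotation, 2L, fit$translation, "+"),
               fit$aligned, tolerance = 1e-10)
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(ref[1:4, ], ref), "differ")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
})

test_that("kabsch rmsd matches a numeric minimisation oracle", {
  set.seed(22)
  for (i in 1:10) {
    ref <- matrix(rnorm(12), 4L, 3L)
    R <- memglyco:::.random_rotation()
    moved <- sweep(ref %*% R, 2L, runif(3, -5, 5), "+")
    moved[1L, ] <- moved[1L, ] + c(1, 0, 0)   # displace one point 1 A
    expect_equal(kabsch_superpose(moved, ref)$rmsd,
                 oracle_min_rmsd(moved, ref), tolerance = 1e-6)
  }
})

test_that("core RMSD uses exactly the helix-core Calphas", {
  hx <- build_ideal_helix()
  f <- hx$frame
  expect_lt(core_rmsd(f, f, hx$topology), 1e-12)
  R <- memglyco:::.random_rotation()
  g <- sweep(f %*% R, 2L, c(1, 2, 3), "+")
  expect_lt(core_rmsd(f, g, hx$topology), 1e-10)
  ## moving a non-core atom leaves the core RMSD at zero
  h <- f; h[1L, ] <- h[1L, ] + 5
  expect_lt(core_rmsd(f, h, hx$topology), 1e-12)
  ## moving a core atom does not
  k <- f; k[8L, ] <- k[8L, ] + 2
  expect_gt(core_rmsd(f, k, hx$topology), 0.1)
  expect_error(core_rmsd(f, f, hx$topology, core = c(30L, 40L)),
               "no Calpha")
  ## symmetry
  expect_equal(core_rmsd(f, k, hx$topology), core_rmsd(k, f, hx$topology),
               tolerance = 1e-10)
})

test_that("rmsd_matrix is consistent with direct core_rmsd calls", {
  set.seed(23)
  hx <- build_ideal_helix()
  nf <- 8L
  frames <- lapply(seq_len(nf), function(i)
    hx$frame + matrix(rnorm(length(hx$frame), 0, 0.5), nrow(hx$frame), 3L))
  traj <- mg_trajectory(hx$topology, frames)
  dm <- rmsd_matrix(traj, rep(TRUE, nf))
  m <- as.matrix(dm$dist)
  expect_identical(length(dm$dist), (nf * (nf - 1L)) %/% 2L)
  for (pair in replicate(20, sample.int(nf, 2L), simplify = FALSE)) {
    i <- pair[1L]; j <- pair[2L]
    expect_equal(m[i, j],
                 core_rmsd(frames[[i]], frames[[j]], hx$topology),
                 tolerance = 1e-10)
  }
  ## identical frames give a zero matrix
  same <- mg_trajectory(hx$topology, rep(list(hx$frame), 3L))
  expect_lt(max(rmsd_matrix(same, rep(TRUE, 3L))$dist), 1e-12)
  expect_error(rmsd_matrix(traj, c(TRUE, rep(FALSE, nf - 1L))),
               "insufficient")
})

test_that("k = 2 clustering is a single merge at the pair distance", {
  hx <- build_ideal_helix()
  f2 <- hx$frame + matrix(rnorm(length(hx$frame), 0, 1), nrow(hx$frame), 3L)
  traj <- mg_trajectory(hx$topology, list(hx$frame, f2))
  dm <- rmsd_matrix(traj, c(TRUE, TRUE))
  cl <- average_linkage(dm, n_clusters = 1L)
  expect_length(cl$height, 1L)
  expect_equal(cl$height, as.numeric(dm$dist), tolerance = 1e-12)
  expect_error(average_linkage(dm, n_clusters = 3L), "n_clusters")
})

test_that("average linkage matches exhaustive agglomeration for k <= 6", {
  set.seed(24)
  n_checked <- 0L
  for (trial in 1:200) {
    k <- sample(3:6, 1L)
    pts <- matrix(runif(k * 4L), k, 4L)
    D <- as.matrix(stats::dist(pts))   # metric-like random matrix
    dm <- structure(list(dist = stats::as.dist(D), frames = seq_len(k),
                         core_coords = NULL), class = "mg_distmat")
    want <- oracle_upgma(D)
    expect_equal(sort(average_linkage(dm, 1L)$height), want$heights,
                 tolerance = 1e-10)
    for (kk in seq_len(k - 1L)) {
      got <- average_linkage(dm, n_clusters = kk)$labels
      expect_identical(partition_signature(got),
                       partition_signature(want$partitions[[kk]]))
    }
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 200L)
})

test_that("two pose families are recovered at 100% label agreement", {
  hx <- build_ideal_helix()
  ref2 <- hx$frame
  core <- 5:12
  ref2[core, 3L] <- ref2[core, 3L] + c(6, -6, 6, -6, 6, -6, 6, -6)
  stopifnot(core_rmsd(hx$frame, ref2, hx$topology) > 5)
  fix <- make_cluster_fixture(100L, list(hx$frame, ref2), 0.2, seed = 31L,
                              topology = hx$topology)
  dm <- rmsd_matrix(fix$trajectory, rep(TRUE, 100L))
  cl <- average_linkage(dm, n_clusters = 2L)
  ## perfect agreement up to label renaming
  tab <- table(cl$labels, fix$labels)
  expect_identical(sum(apply(tab, 1L, max)), 100L)
  expect_identical(sum(cl$populations$population), 100L)
})

test_that("clustering is invariant under frame permutation", {
  set.seed(25)
  hx <- build_ideal_helix()
  fix <- make_cluster_fixture(30L, list(hx$frame, hx$frame + 5), 0.3,
                              seed = 7L, topology = hx$topology)
  dm <- rmsd_matrix(fix$trajectory, rep(TRUE, 30L))
  cl <- average_linkage(dm, n_clusters = 3L)
  perm <- sample.int(30L)
  traj_p <- memglyco:::subset_frames(fix$trajectory, perm)
  dm_p <- rmsd_matrix(traj_p, rep(TRUE, 30L))
  cl_p <- average_linkage(dm_p, n_clusters = 3L)
  ## same partition after mapping back through the permutation
  lab_back <- integer(30L)
  lab_back[perm] <- cl_p$labels
  expect_identical(partition_signature(cl$labels),
                   partition_signature(lab_back))
})

test_that("representatives minimise RMSD to the cluster average", {
  set.seed(26)
  hx <- build_ideal_helix()
  fix <- make_cluster_fixture(40L, list(hx$frame, hx$frame * 1.2), 0.3,
                              seed = 9L, topology = hx$topology)
  dm <- rmsd_matrix(fix$trajectory, rep(TRUE, 40L))
  cl <- average_linkage(dm, n_clusters = 4L)
  reps <- representatives(cl)
  avgs <- attr(reps, "averages")
  for (ci in seq_along(reps)) {
    members <- which(cl$labels == ci)
    d <- vapply(members, function(mi)
      kabsch_superpose(dm$core_coords[[mi]], avgs[[ci]])$rmsd, numeric(1L))
    rep_pos <- match(reps[ci], cl$frames)
    expect_lte(d[match(rep_pos, members)], min(d) + 1e-12)
    expect_true(rep_pos %in% members)
  }
})

test_that("a singleton cluster returns its only frame", {
  hx <- build_ideal_helix()
  far <- hx$frame
  far[5:12, 3L] <- far[5:12, 3L] + c(8, -8, 8, -8, 8, -8, 8, -8)
  traj <- mg_trajectory(hx$topology, list(hx$frame, hx$frame, far))
  dm <- rmsd_matrix(traj, rep(TRUE, 3L))
  cl <- average_linkage(dm, n_clusters = 2L)
  reps <- representatives(cl)
  lone <- cl$labels[3L]
  expect_identical(unname(reps[paste0("cluster", lone)]), 3L)
})

test_that("a member equal to the mean of its cluster is the representative", {
  ## three-frame cluster where member 2 is the exact mean of 1 and 3
  hx <- build_ideal_helix()
  idx <- memglyco:::.core_ca_indices(hx$topology)
  d <- matrix(0, nrow(hx$frame), 3L)
  d[idx, ] <- matrix(rnorm(length(idx) * 3L, 0, 0.5), length(idx), 3L)
  f1 <- hx$frame + d; f3 <- hx$frame - d; f2 <- hx$frame
  traj <- mg_trajectory(hx$topology, list(f1, f2, f3))
  dm <- rmsd_matrix(traj, rep(TRUE, 3L))
  cl <- average_linkage(dm, n_clusters = 1L)
  reps <- representatives(cl)
  expect_identical(unname(reps[1L]), 2L)
})
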