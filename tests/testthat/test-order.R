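## order_parameter: C-H vectors, S_CD profiles, profile comparison.

## Minimal one-lipid topology with chain c1 carbons 2..6 (no hydrogens),
## positioned as an ideal all-trans zig-zag whose axis is -z.
make_trans_chain <- function() {
  ks <- 2:6
  atoms <- data.frame(
    name = paste0("C", ks, "A"), res_name = "DMP", res_id = 1L,
    chain = "U", segment = "lipid", role = "carbon", element = "C",
    lipid_id = 1L, leaflet = "upper", acyl = "c1", carbon = ks)
  half <- 0.5 * acos(-1 / 3)            # half the tetrahedral angle
  b <- 1.53                              # C-C bond length
  x <- b * sin(half) * ifelse(seq_along(ks) %% 2L == 0L, 1, -1)
  z <- 15 - b * cos(half) * seq_along(ks)
  list(top = mg_topology(atoms), frame = cbind(x, 0, z))
}

test_that("explicit C-H vectors are unit vectors toward the hydrogens", {
  atoms <- data.frame(
    name = c("C2A", "F2A", "G2A"), res_name = "DMP", res_id = 1L,
    chain = "U", segment = "lipid", role = c("carbon", "hydrogen",
                                             "hydrogen"),
    element = c("C", "H", "H"), lipid_id = 1L, leaflet = "upper",
    acyl = "c1", carbon = 2L)
  top <- mg_topology(atoms)
  frame <- rbind(c(0, 0, 0), c(0, 0, 1.09), c(1.09, 0, 0))
  v <- ch_vectors(frame, top, 1L, "c1", 2L, h_mode = "explicit")
  expect_equal(v[1L, ], c(0, 0, 1), tolerance = 1e-12)
  expect_equal(v[2L, ], c(1, 0, 0), tolerance = 1e-12)
  expect_error(ch_vectors(frame, top, 1L, "c1", 3L), "not found")
  expect_error(ch_vectors(frame, top, 1L, "c2", 2L), "not found")
})

test_that("reconstructed hydrogens have tetrahedral geometry", {
  tc <- make_trans_chain()
  for (k in 3:5) {
    v <- ch_vectors(tc$frame, tc$top, 1L, "c1", k, h_mode = "reconstructed")
    expect_identical(nrow(v), 2L)
    expect_equal(rowSums(v^2), c(1, 1), tolerance = 1e-12)
    ## H-C-H angle is tetrahedral
    expect_equal(acos(sum(v[1L, ] * v[2L, ])), acos(-1 / 3),
                 tolerance = 1e-10)
    ## ideal all-trans chain aligned with z: C-H perpendicular to z
    expect_lt(max(abs(v[, 3L])), 1e-6)
  }
  expect_error(ch_vectors(tc$frame, tc$top, 1L, "c1", 2L,
                          h_mode = "reconstructed"), "terminal")
  expect_error(ch_vectors(tc$frame, tc$top, 1L, "c1", 6L,
                          h_mode = "reconstructed"), "terminal")
})

test_that("S_CD hits its exact limits for aligned and perpendicular H", {
  ## one carbon, hydrogens along +z in frame A and along +x in frame B
  atoms <- data.frame(
    name = c("C2A", "F2A", "G2A"), res_name = "DMP", res_id = 1L,
    chain = "U", segment = "lipid",
    role = c("carbon", "hydrogen", "hydrogen"),
    element = c("C", "H", "H"), lipid_id = 1L, leaflet = "upper",
    acyl = "c1", carbon = 2L)
  top <- mg_topology(atoms)
  up <- rbind(c(0, 0, 0), c(0, 0, 1.09), c(0, 0, -1.09))
  flat <- rbind(c(0, 0, 0), c(1.09, 0, 0), c(0, 1.09, 0))
  p_up <- scd_profile(mg_trajectory(top, list(up)), chain = "c1",
                      n_blocks = 1L)
  p_flat <- scd_profile(mg_trajectory(top, list(flat)), chain = "c1",
                        n_blocks = 1L)
  expect_equal(p_up$scd, 1, tolerance = 1e-12)
  expect_equal(p_flat$scd, -0.5, tolerance = 1e-12)
  expect_identical(p_up$n_samples, 2L)
})

test_that("fixed-angle generation recovers the target order exactly", {
  for (s_star in c(-0.4, 0, 0.2, 0.9)) {
    traj <- gen_bilayer_frames(
      n_lipids = 8L, n_frames = 5L,
      target_order = list(c1 = setNames(rep(s_star, 13L), 2:14),
                          c2 = setNames(rep(s_star, 13L), 2:14)),
      mode = "fixed-angle", seed = 2L)
    for (ch in c("c1", "c2")) {
      prof <- scd_profile(traj, chain = ch)
      expect_equal(prof$scd, rep(s_star, 13L), tolerance = 1e-6)
      expect_identical(prof$carbon, 2:14)
      expect_identical(prof$n_samples,
                       rep(8L * 2L * 5L, 13L))
    }
  }
})

test_that("S_CD always lies in [-0.5, 1]", {
  traj <- gen_bilayer_frames(n_lipids = 8L, n_frames = 10L,
                             mode = "noisy", noise_sd = 0.8, seed = 5L)
  for (ch in c("c1", "c2")) {
    prof <- scd_profile(traj, chain = ch)
    expect_true(all(prof$scd >= -0.5 & prof$scd <= 1))
    expect_true(all(prof$abs_scd == abs(prof$scd)))
    expect_true(all(diff(prof$carbon) > 0L))
  }
})

test_that("an isotropic sample of 1e5 orientations gives |S_CD| < 0.01", {
  traj <- gen_bilayer_frames(n_lipids = 64L, n_frames = 61L,
                             mode = "isotropic", seed = 6L)
  prof <- scd_profile(traj, chain = "c1")
  n_total <- sum(prof$n_samples)
  expect_gte(n_total, 1e5)
  pooled <- sum(prof$scd * prof$n_samples) / n_total
  expect_lt(abs(pooled), 0.01)
})

test_that("frame exclusion changes sample counts exactly as predicted", {
  traj <- gen_bilayer_frames(n_lipids = 8L, n_frames = 10L, seed = 7L)
  full <- scd_profile(traj, chain = "c1")
  excl <- rep(c(TRUE, FALSE), 5L)
  half <- scd_profile(traj, chain = "c1", excluded = excl)
  expect_identical(half$n_samples, full$n_samples %/% 2L)
  expect_error(scd_profile(traj, chain = "c1",
                           excluded = rep(TRUE, 10L)), "no retained")
  expect_error(scd_profile(traj, chain = "zz"), "chain")
})

test_that("block standard errors shrink noise and vanish for exact data", {
  fixed <- gen_bilayer_frames(n_lipids = 8L, n_frames = 10L,
                              mode = "fixed-angle", seed = 8L)
  prof <- scd_profile(fixed, chain = "c1")
  expect_lt(max(prof$se), 1e-9)   # exact by construction
  noisy <- gen_bilayer_frames(n_lipids = 8L, n_frames = 10L,
                              mode = "noisy", noise_sd = 0.4, seed = 8L)
  prof_n <- scd_profile(noisy, chain = "c1")
  expect_true(all(prof_n$se >= 0))
  expect_gt(max(prof_n$se), 0)
})

## Build an order profile directly (unit-test fixture for comparisons).
make_profile <- function(scd, se = 0.005, chain = "c2") {
  structure(
    data.frame(chain = chain, carbon = 2:14, scd = scd, abs_scd = abs(scd),
               se = se, n_samples = 1000L),
    class = c("mg_order_profile", "data.frame"))
}

test_that("profile comparison flags exactly the perturbed carbons", {
  base <- make_profile(rep(0.2, 13L))
  shifted <- base
  shifted$scd[shifted$carbon <= 7L] <- 0.3   # carbons 2..7 differ by 0.1
  cmp <- profile_compare(shifted, base)
  expect_identical(cmp$carbon[cmp$flagged], 2:7)
  expect_identical(unname(attr(cmp, "deepest_carbon")["c2"]), 7L)
  ## self-comparison: no flags, all deltas zero
  self <- profile_compare(base, base)
  expect_true(all(self$delta == 0))
  expect_false(any(self$flagged))
  expect_true(is.na(attr(self, "deepest_carbon")["c2"]))
})

test_that("profile comparison rejects mismatched ranges", {
  a <- make_profile(rep(0.2, 13L))
  b <- make_profile(rep(0.2, 13L))
  b <- b[b$carbon <= 10L, ]
  expect_error(profile_compare(a, b), "do not match")
  c1 <- make_profile(rep(0.2, 13L), chain = "c1")
  expect_error(profile_compare(a, c1), "do not match")
})

test_that("reported S_CD is unchanged by pooling leaflets symmetrically", {
  ## the generator mirrors leaflets; restricting to one leaflet via a
  ## topology subset must give the same fixed-angle answer
  traj <- gen_bilayer_frames(n_lipids = 8L, n_frames = 5L, seed = 9L)
  full <- scd_profile(traj, chain = "c1")
  at <- traj$topology$atoms
  upper <- which(at$leaflet == "upper")
  top_u <- mg_topology(at[upper, ])
  traj_u <- mg_trajectory(top_u, traj$coords[upper, , , drop = FALSE])
  half <- scd_profile(traj_u, chain = "c1")
  expect_equal(half$scd, full$scd, tolerance = 1e-9)
})
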