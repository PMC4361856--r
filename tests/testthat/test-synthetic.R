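## synthetic_data: helix geometry, simulator physics, generators.

test_that("the ideal helix has canonical, constant geometry", {
  hx <- build_ideal_helix()
  ca <- hx$frame[1:21, ]
  expect_identical(nrow(hx$frame), 22L)   # 21 Calpha + 1 glycan bead
  ## consecutive Calpha-Calpha distance equals the helix chord, constant
  chord <- sqrt(1.5^2 + (2 * 2.3 * sin(100 * pi / 180 / 2))^2)
  d <- sqrt(rowSums((ca[-1L, ] - ca[-21L, ])^2))
  expect_lt(max(abs(d - chord)), 1e-10)
  ## glycan bead sits 3 A radially outside residue 7
  g <- hx$frame[22L, ]
  expect_equal(g[1L], ca[7L, 1L], tolerance = 1e-12)
  expect_equal(sqrt(sum(g[2:3]^2)), 2.3 + 3, tolerance = 1e-10)
  expect_error(build_ideal_helix(rep("ALA", 4L)), "too short")
})

test_that("simulation config validates its inputs", {
  expect_error(sim_config(dt_fs = 0), "time step")
  expect_error(sim_config(temperature = -5), "temperature")
  expect_error(sim_config(depths = c(glycan = 1)), "bead classes")
  expect_error(sim_config(offsets = c(glycan = 1)), "bead classes")
  cfg <- sim_config(seed = 9L)
  expect_identical(cfg$seed, 9L)
})

test_that("identical seeds give bitwise-identical trajectories", {
  hx <- build_ideal_helix()
  cfg <- sim_config(seed = 4L, n_steps = 20000L)
  a <- simulate_funnel_langevin(hx, cfg)
  b <- simulate_funnel_langevin(hx, cfg)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$states, b$states)
  c2 <- simulate_funnel_langevin(hx, sim_config(seed = 5L,
                                                n_steps = 20000L))
  expect_false(identical(a$trajectory$coords, c2$trajectory$coords))
  ## the seed is recorded in the output
  expect_identical(unique(a$states$seed), 4L)
})

test_that("ground-truth labels are recomputable from emitted coordinates", {
  hx <- build_ideal_helix()
  sim <- simulate_funnel_langevin(hx, sim_config(seed = 6L,
                                                 n_steps = 50000L))
  gt <- sim$ground_truth
  again <- ground_truth_labels(sim$trajectory, sim$config$bound_cutoff)
  expect_identical(gt$bound, again$bound)
  expect_identical(gt$side, again$side)
  ## side labels only on bound frames; events alternate bind/unbind
  expect_true(all(gt$side[!gt$bound] == "none"))
  expect_true(all(gt$side[gt$bound] %in% c("Side1", "Side2")))
  ev <- attr(gt, "events")
  if (nrow(ev) > 1L)
    expect_true(all(ev$type[-1L] != ev$type[-nrow(ev)]))
  expect_equal(attr(gt, "bound_fraction"), mean(gt$bound))
})

test_that("unstable integration raises a step-size error", {
  hx <- build_ideal_helix()
  expect_error(
    simulate_funnel_langevin(hx, sim_config(seed = 1L, dt_fs = 8000,
                                            n_steps = 5000L)),
    "unstable integration")
})

test_that("equipartition holds in the harmonic-trap diagnostic", {
  hx <- build_ideal_helix()
  cfg <- sim_config(seed = 2L, friction = 2, dt_fs = 10,
                    n_steps = 2000000L, stride = 20L, membrane = FALSE,
                    funnel = NULL, jitter_sd = 0,
                    trap = list(k = 2, center = c(0, 0, 30)), start_z = 30)
  sim <- simulate_funnel_langevin(hx, cfg, emit_membrane = FALSE)
  kT_over_k <- 0.0019872041 * 300 / 2
  for (v in c("x", "y")) {
    msd <- mean(sim$states[[v]]^2)
    expect_lt(abs(msd - kT_over_k) / kT_over_k, 0.05)
  }
})

test_that("the integrator conserves energy to O(dt^2) without friction", {
  hx <- build_ideal_helix()
  drift <- function(dt) {
    cfg <- sim_config(seed = 5L, friction = 0, dt_fs = dt,
                      n_steps = 20000L, stride = 10L, membrane = FALSE,
                      jitter_sd = 0, start_z = 40)
    sim <- simulate_funnel_langevin(hx, cfg, emit_membrane = FALSE)
    e <- sim$states$potential + sim$states$kinetic
    max(abs(e - e[1L]))
  }
  d1 <- drift(5); d2 <- drift(10)
  expect_lt(d1, 1e-4)                  # tiny absolute drift
  expect_gt(d2 / d1, 2.5)              # ~4x for a second-order method
  expect_lt(d2 / d1, 8)
})

test_that("the bound fraction matches Boltzmann quadrature within 3 SE", {
  ## constructed two-state well: near-cylindrical funnel, weak uniform
  ## wells, so bound and unbound states carry comparable weight
  hx <- build_ideal_helix()
  fz <- funnel_geometry(alpha = 0.05, rcyl = 5, zcc = 25, zmax = 35,
                        k_wall = 10)
  d <- 0.05
  cfg <- sim_config(seed = 3L, n_steps = 2000000L, stride = 200L,
                    depths = c(glycan = d, basic = d, aromatic = d,
                               other = d),
                    offsets = c(glycan = 0, basic = 0, aromatic = 0,
                                other = 0),
                    funnel = fz, jitter_sd = 0, start_z = 28)
  theory <- oracle_bound_fraction(hx, cfg)
  sim <- simulate_funnel_langevin(hx, cfg, emit_membrane = FALSE)
  b <- as.numeric(sim$ground_truth$bound)
  se <- block_se(b, 10L)
  expect_gt(sum(abs(diff(b))), 20)     # genuine two-state exchange
  expect_lt(abs(mean(b) - theory), 3 * se)
})

test_that("bilayer generation is seeded and validates targets", {
  t1 <- gen_bilayer_frames(n_lipids = 8L, n_frames = 3L, seed = 3L)
  t2 <- gen_bilayer_frames(n_lipids = 8L, n_frames = 3L, seed = 3L)
  expect_identical(t1$coords, t2$coords)
  expect_error(gen_bilayer_frames(n_lipids = 7L), "even")
  expect_error(gen_bilayer_frames(
    n_lipids = 8L,
    target_order = list(c1 = setNames(rep(-0.6, 13L), 2:14),
                        c2 = setNames(rep(0.2, 13L), 2:14))),
    "unattainable")
})

test_that("a target order of 1 puts every C-H along the normal", {
  traj <- gen_bilayer_frames(
    n_lipids = 4L, n_frames = 2L,
    target_order = list(c1 = setNames(rep(1, 13L), 2:14),
                        c2 = setNames(rep(1, 13L), 2:14)),
    mode = "fixed-angle", seed = 4L)
  at <- traj$topology$atoms
  h <- which(at$role == "hydrogen")
  key <- paste(at$lipid_id, at$acyl, at$carbon)
  c_of_h <- which(at$role == "carbon")[match(key[h],
    key[at$role == "carbon"])]
  v <- traj$coords[h, , 1L] - traj$coords[c_of_h, , 1L]
  expect_lt(max(abs(v[, 1:2])), 1e-9)   # no lateral component
  expect_equal(unname(abs(v[, 3L])), rep(1.09, length(h)),
               tolerance = 1e-9)
})

test_that("cluster fixtures honour sigma and weights", {
  hx <- build_ideal_helix()
  ## sigma = 0: every frame at core RMSD 0 from its reference
  fix0 <- make_cluster_fixture(10L, list(hx$frame), 0, seed = 12L,
                               topology = hx$topology)
  for (f in 1:10)
    expect_lt(core_rmsd(frame_coords(fix0$trajectory, f), hx$frame,
                        hx$topology), 1e-9)
  ## weights: populations within binomial 3 SE of expectation
  ref2 <- hx$frame + 6
  fix <- make_cluster_fixture(1000L, list(hx$frame, ref2), 0.1,
                              weights = c(0.7, 0.3), seed = 13L,
                              topology = hx$topology)
  n1 <- sum(fix$labels == 1L)
  se <- sqrt(1000 * 0.7 * 0.3)
  expect_lt(abs(n1 - 700), 3 * se)
  expect_error(make_cluster_fixture(5L, list(hx$frame, hx$frame[-1L, ]),
                                    0.1), "same atom count")
  expect_error(make_cluster_fixture(5L, list(hx$frame), 0.1,
                                    weights = c(0.5, 0.2)), "sum to 1")
})
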