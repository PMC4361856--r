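## Synthetic-data generators: every analysis stage in the package is
## exercised against inputs with constructed ground truth.

#' Build an ideal alpha-helix bead model
#'
#' Calpha-only helix laid along +x with canonical alpha-helix geometry
#' (rise 1.5 A per residue, 100 deg twist, 2.3 A radius), so the two helix
#' faces point along +z and -z when the peptide lies on a membrane whose
#' normal is z. When the sequence carries a glycosylated residue, one extra
#' glycan bead is placed 3 A radially outward from that residue's Calpha.
#'
#' @param sequence character vector of 3-letter residue codes (length >= 5);
#'   an optional `glycan_residue` attribute (as set by [csf114_sequence()])
#'   or the `glycan_residue` argument marks the glycosylated position.
#' @param rise helix rise per residue, A.
#' @param twist helix twist per residue, degrees.
#' @param radius helix radius, A.
#' @param glycan_residue residue index carrying the glycan bead, or `NA`.
#' @return list with `topology` (`mg_topology`), `frame` (coordinates,
#'   centred so the Calpha centroid is at the origin), and per-bead
#'   geometry (`axial`, `radial`, `phase`, `class`) used by the simulator.
#' @export
build_ideal_helix <- function(sequence = csf114_sequence(), rise = 1.5,
                              twist = 100, radius = 2.3,
                              glycan_residue = NULL) {
  n <- length(sequence)
  if (n < 5L) stop("sequence too short: need at least 5 residues")
  glycan_residue <- glycan_residue %||%
    attr(sequence, "glycan_residue") %||% NA_integer_
  phi <- (seq_len(n) - 1L) * twist * pi / 180
  axial <- (seq_len(n) - 1L) * rise
  axial <- axial - mean(axial)
  coords <- cbind(axial, radius * sin(phi), radius * cos(phi))
  atoms <- data.frame(
    name = "CA", res_name = as.character(sequence), res_id = seq_len(n),
    chain = "A", segment = "peptide", role = "ca", element = "C",
    lipid_id = NA_integer_, leaflet = NA_character_,
    acyl = NA_character_, carbon = NA_integer_, stringsAsFactors = FALSE)
  radial <- rep(radius, n)
  phase <- phi
  classes <- residue_class(as.character(sequence))
  if (!is.na(glycan_residue)) {
    g <- as.integer(glycan_residue)
    if (g < 1L || g > n) stop("glycan_residue outside the sequence")
    coords <- rbind(coords, c(axial[g], (radius + 3) * sin(phi[g]),
                              (radius + 3) * cos(phi[g])))
    atoms <- rbind(atoms, data.frame(
      name = "C1G", res_name = "GLC", res_id = g, chain = "A",
      segment = "peptide", role = "glycan", element = "C",
      lipid_id = NA_integer_, leaflet = NA_character_,
      acyl = NA_character_, carbon = NA_integer_, stringsAsFactors = FALSE))
    radial <- c(radial, radius + 3)
    phase <- c(phase, phi[g])
    classes <- c(classes, "glycan")
  }
  hc <- if (n >= 12L) c(5L, 12L) else c(1L, n)
  top <- mg_topology(atoms, helix_core = hc,
                     glycan_residue = as.integer(glycan_residue))
  list(topology = top, frame = unname(coords),
       axial = c(axial, if (!is.na(glycan_residue)) axial[glycan_residue]),
       radial = radial, phase = phase, class = classes)
}

#' Simulation configuration for the coarse binding simulator
#'
#' Conditions of the synthetic binding runs: a rigid helical bead model in
#' implicit-membrane wells inside the funnel restraint, thermostatted at
#' 300 K. Per-bead well depths follow the residue classes that drive
#' peptide-membrane binding (glycan > basic > aromatic > other), so the
#' glycosylated face binds more strongly and dominates the bound ensemble.
#'
#' @param temperature K.
#' @param friction Langevin friction, ps^-1.
#' @param dt_fs time step, fs.
#' @param n_steps number of integration steps.
#' @param stride steps between emitted frames.
#' @param seed RNG seed, recorded in every output.
#' @param depths named kcal/mol well depths per bead class
#'   (`glycan`, `basic`, `aromatic`, `other`).
#' @param offsets named per-class well-centre heights above the phosphate
#'   plane, A: the glycan reaches the phosphates (0), basic side chains
#'   salt-bridge just above them, aromatics sit at the choline level and
#'   plain backbone beads ride on top of the head groups. These offsets
#'   give the bound helix a genuinely orientation-dependent energy, so the
#'   glycosylated face dominates the bound ensemble.
#' @param z_surface membrane surface (phosphate plane) height, A.
#' @param well_width Gaussian well width, A.
#' @param bound_cutoff peptide-centre height below which a frame is
#'   labelled bound, A.
#' @param funnel an [funnel_geometry()] or `NULL` to disable the restraint.
#' @param mass total peptide mass, amu.
#' @param k_core,z_core harmonic repulsion (kcal/mol/A^2) below `z_core` A,
#'   keeping beads out of the membrane interior.
#' @param jitter_sd Gaussian positional jitter added to emitted bead
#'   coordinates, A (emulates backbone thermal fluctuation).
#' @param membrane logical; `FALSE` turns the implicit membrane off
#'   (diagnostic runs).
#' @param trap optional list `list(k = , center = )` adding a harmonic trap
#'   (equipartition diagnostics).
#' @param start_z initial axis height, A.
#' @return object of class `mg_sim_config`.
#' @export
sim_config <- function(temperature = 300, friction = 1, dt_fs = 10,
                       n_steps = 200000L, stride = 100L, seed = 1L,
                       depths = c(glycan = 5, basic = 2.5, aromatic = 1.5,
                                  other = 0.25),
                       offsets = c(glycan = 0, basic = 0.5, aromatic = 2,
                                   other = 4),
                       z_surface = 18, well_width = 2.5, bound_cutoff = 26,
                       funnel = funnel_geometry(), mass = 2300,
                       k_core = 5, z_core = 15, jitter_sd = 0.1,
                       membrane = TRUE, trap = NULL, start_z = 30) {
  if (dt_fs <= 0) stop("time step must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  if (friction < 0) stop("friction must be non-negative")
  classes <- c("glycan", "basic", "aromatic", "other")
  if (!all(classes %in% names(depths)))
    stop("depths must name all bead classes")
  if (!all(classes %in% names(offsets)))
    stop("offsets must name all bead classes")
  structure(list(temperature = temperature, friction = friction,
                 dt_fs = dt_fs, n_steps = as.integer(n_steps),
                 stride = as.integer(stride), seed = as.integer(seed),
                 depths = depths, offsets = offsets, z_surface = z_surface,
                 well_width = well_width, bound_cutoff = bound_cutoff,
                 funnel = funnel, mass = mass, k_core = k_core,
                 z_core = z_core, jitter_sd = jitter_sd,
                 membrane = membrane, trap = trap, start_z = start_z),
            class = "mg_sim_config")
}

## Static upper-leaflet phosphate grid emitted with simulator trajectories
## so the contact collective variable has membrane atoms to count.
make_phosphate_grid <- function(z_surface, half_span = 25, spacing = 5) {
  g <- seq(-half_span, half_span, by = spacing)
  xy <- expand.grid(x = g, y = g)
  n <- nrow(xy)
  atoms <- data.frame(
    name = "P", res_name = "DMP", res_id = seq_len(n), chain = "U",
    segment = "lipid", role = "phosphate", element = "P",
    lipid_id = seq_len(n), leaflet = "upper",
    acyl = NA_character_, carbon = NA_integer_, stringsAsFactors = FALSE)
  list(atoms = atoms, coords = cbind(xy$x, xy$y, rep(z_surface, n)))
}

#' Ground-truth labels from emitted coordinates
#'
#' Reapplies the labelling rules to a simulator trajectory: a frame is
#' bound when the unweighted centre of the peptide beads lies below the
#' bound z-cutoff; a bound frame is Side1 when the glycan bead sits below
#' the mean Calpha height (glycosylated face toward the membrane), Side2
#' otherwise. The event list records alternating binding/unbinding frames.
#'
#' @param trajectory simulator `mg_trajectory`.
#' @param bound_cutoff A.
#' @return `mg_ground_truth`: data.frame `frame`, `bound`, `side` with
#'   `events` (data.frame `frame`, `type`) and `bound_fraction` attributes.
#' @export
ground_truth_labels <- function(trajectory, bound_cutoff) {
  at <- trajectory$topology$atoms
  pep <- which(at$segment == "peptide")
  ca <- which(at$segment == "peptide" & at$role == "ca")
  gl <- which(at$role == "glycan")
  nf <- n_frames(trajectory)
  com_z <- vapply(seq_len(nf), function(i)
    mean(trajectory$coords[pep, 3L, i]), numeric(1L))
  bound <- com_z < bound_cutoff
  side <- rep("none", nf)
  if (length(gl) == 1L) {
    ca_z <- vapply(seq_len(nf), function(i)
      mean(trajectory$coords[ca, 3L, i]), numeric(1L))
    gl_z <- trajectory$coords[gl, 3L, ]
    side[bound] <- ifelse(gl_z[bound] < ca_z[bound], "Side1", "Side2")
  }
  trans <- which(diff(bound) != 0L)
  events <- data.frame(
    frame = trans + 1L,
    type = ifelse(bound[trans + 1L], "bind", "unbind"))
  structure(data.frame(frame = seq_len(nf), bound = bound, side = side),
            events = events, bound_fraction = mean(bound),
            class = c("mg_ground_truth", "data.frame"))
}

#' Funnel-restrained Langevin binding simulation
#'
#' Rigid-body Langevin dynamics (BAOAB) of the helical bead model in
#' per-bead membrane wells plus the funnel restraint: the peptide diffuses
#' in the funnel, binds and unbinds at the membrane surface, and rolls
#' between its two faces. Degrees of freedom are the axis centre (x, y, z)
#' and the roll angle about the helix axis. Identical seeds give identical
#' trajectories bitwise. The emitted trajectory contains the peptide beads
#' plus a static phosphate grid at the membrane surface, and ground-truth
#' labels are recomputed from the emitted coordinates so they are
#' self-consistent by construction.
#'
#' @param helix output of [build_ideal_helix()].
#' @param config an [sim_config()].
#' @param emit_membrane include the phosphate grid in the trajectory.
#' @return list: `trajectory`, `ground_truth`, `states` (raw integrator
#'   samples: step, x, y, z, phi, potential, kinetic energies), `config`.
#' @export
simulate_funnel_langevin <- function(helix, config = sim_config(),
                                     emit_membrane = TRUE) {
  stopifnot(inherits(config, "mg_sim_config"))
  nb <- length(helix$radial)
  depth <- unname(config$depths[helix$class])
  center <- config$z_surface + unname(config$offsets[helix$class])
  if (anyNA(depth) || anyNA(center))
    stop("unknown bead class in helix model")
  kT <- .kB * config$temperature
  mass_t <- config$mass * .mass_conv
  inertia <- sum((config$mass / nb) * helix$radial^2) * .mass_conv
  dt <- config$dt_fs * 1e-3
  fz <- config$funnel
  set.seed(config$seed)
  v0 <- c(rnorm(3L, 0, sqrt(kT / mass_t)), rnorm(1L, 0, sqrt(kT / inertia)))
  states <- .langevin_run(
    n_steps = config$n_steps, dt = dt, stride = config$stride,
    kT = kT, gamma = config$friction, mass_t = mass_t, inertia = inertia,
    q0 = c(0, 0, config$start_z, 0), v0 = v0,
    bead_rad = helix$radial, bead_phase = helix$phase, bead_depth = depth,
    bead_center = center, well_width = config$well_width,
    k_core = config$k_core, z_core = config$z_core,
    membrane_on = isTRUE(config$membrane),
    funnel_on = !is.null(fz),
    f_alpha = if (!is.null(fz)) fz$alpha else 0,
    f_rcyl = if (!is.null(fz)) fz$rcyl else 0,
    f_zcc = if (!is.null(fz)) fz$zcc else 0,
    f_zmax = if (!is.null(fz) && !is.null(fz$zmax)) fz$zmax else -1,
    f_kwall = if (!is.null(fz)) fz$k_wall else 0,
    trap_on = !is.null(config$trap),
    k_trap = if (!is.null(config$trap)) config$trap$k else 0,
    trap_center = if (!is.null(config$trap)) config$trap$center
                  else c(0, 0, 0))
  nf <- nrow(states)
  pep_coords <- array(0, dim = c(nb, 3L, nf))
  for (i in seq_len(nf)) {
    phi <- states[i, "phi"]
    pep_coords[, , i] <- cbind(
      states[i, "x"] + helix$axial,
      states[i, "y"] + helix$radial * sin(phi + helix$phase),
      states[i, "z"] + helix$radial * cos(phi + helix$phase))
  }
  if (config$jitter_sd > 0)
    pep_coords <- pep_coords +
      array(rnorm(length(pep_coords), 0, config$jitter_sd),
            dim = dim(pep_coords))
  if (emit_membrane) {
    grid <- make_phosphate_grid(config$z_surface)
    atoms <- rbind(helix$topology$atoms, grid$atoms)
    top <- mg_topology(atoms, helix_core = helix$topology$helix_core,
                       glycan_residue = helix$topology$glycan_residue)
    coords <- array(0, dim = c(nrow(atoms), 3L, nf))
    coords[seq_len(nb), , ] <- pep_coords
    coords[(nb + 1L):nrow(atoms), , ] <- grid$coords
  } else {
    top <- helix$topology
    coords <- pep_coords
  }
  traj <- mg_trajectory(top, coords,
                        time = states[, "step"] * dt,
                        stride = config$stride)
  gt <- ground_truth_labels(traj, config$bound_cutoff)
  states_df <- as.data.frame(states)
  states_df$seed <- config$seed
  list(trajectory = traj, ground_truth = gt, states = states_df,
       config = config)
}

#' Generate bilayer frames with prescribed chain order
#'
#' Places DMPC-like acyl chains (carbons 2..14 per chain, two explicit
#' hydrogens per carbon) on a lattice, two mirrored leaflets, and samples
#' each C-H orientation at the fixed polar angle theta* =
#' acos(sqrt((2 S* + 1) / 3)) with uniform azimuth, so the recovered S_CD
#' equals the target exactly (`"fixed-angle"`); `"noisy"` adds Gaussian
#' polar-angle noise and `"isotropic"` draws orientations uniformly on the
#' sphere.
#'
#' @param n_lipids even total lipid count (split over two leaflets).
#' @param n_frames number of frames.
#' @param target_order list with elements `c1` and `c2`: named numeric
#'   vectors of target S_CD per carbon (names = carbon indices 2..14),
#'   each in (-0.5, 1].
#' @param mode `"fixed-angle"`, `"noisy"` or `"isotropic"`.
#' @param noise_sd polar-angle noise, rad (noisy mode).
#' @param seed RNG seed.
#' @param z_head head-group height, A.
#' @param spacing lattice spacing, A.
#' @return an `mg_trajectory` of the bilayer.
#' @export
gen_bilayer_frames <- function(n_lipids = 64L, n_frames = 50L,
                               target_order = list(
                                 c1 = setNames(rep(0.2, 13L), 2:14),
                                 c2 = setNames(rep(0.2, 13L), 2:14)),
                               mode = c("fixed-angle", "noisy", "isotropic"),
                               noise_sd = 0.1, seed = 1L,
                               z_head = 18, spacing = 8) {
  mode <- match.arg(mode)
  if (n_lipids %% 2L != 0L) stop("n_lipids must be even (two leaflets)")
  for (ch in c("c1", "c2")) {
    s <- target_order[[ch]]
    if (is.null(s) || is.null(names(s))) stop("target_order$", ch,
                                              " must be named by carbon")
    if (any(s <= -0.5 | s > 1))
      stop("unattainable target order: S* must lie in (-0.5, 1]")
  }
  set.seed(seed)
  per_leaf <- n_lipids / 2L
  side <- ceiling(sqrt(per_leaf))
  bond <- 1.09; drop <- 1.27
  atoms_list <- list(); coords0 <- list()
  lipid <- 0L
  for (leaf in c("upper", "lower")) {
    sgn <- if (leaf == "upper") 1 else -1
    for (li in seq_len(per_leaf)) {
      lipid <- lipid + 1L
      gx <- ((li - 1L) %% side) * spacing
      gy <- ((li - 1L) %/% side) * spacing
      rows <- data.frame(
        name = c("P", "N"), res_name = "DMP", res_id = lipid,
        chain = if (leaf == "upper") "U" else "L", segment = "lipid",
        role = c("phosphate", "choline"), element = c("P", "N"),
        lipid_id = lipid, leaflet = leaf, acyl = NA_character_,
        carbon = NA_integer_, stringsAsFactors = FALSE)
      xyz <- rbind(c(gx, gy, sgn * z_head), c(gx, gy, sgn * (z_head + 2)))
      for (ch in c("c1", "c2")) {
        suffix <- if (ch == "c1") "A" else "B"
        xoff <- if (ch == "c1") -0.8 else 0.8
        carbons <- as.integer(names(target_order[[ch]]))
        for (k in carbons) {
          cz <- sgn * (z_head - 2 - drop * (k - 2L))
          cpos <- c(gx + xoff, gy, cz)
          rows <- rbind(rows, data.frame(
            name = c(paste0("C", k, suffix), paste0("F", k, suffix),
                     paste0("G", k, suffix)),
            res_name = "DMP", res_id = lipid,
            chain = if (leaf == "upper") "U" else "L", segment = "lipid",
            role = c("carbon", "hydrogen", "hydrogen"),
            element = c("C", "H", "H"), lipid_id = lipid, leaflet = leaf,
            acyl = ch, carbon = k, stringsAsFactors = FALSE))
          xyz <- rbind(xyz, matrix(cpos, 3L, 3L, byrow = TRUE))
        }
      }
      atoms_list[[lipid]] <- rows
      coords0[[lipid]] <- xyz
    }
  }
  atoms <- do.call(rbind, atoms_list)
  base <- do.call(rbind, coords0)
  top <- mg_topology(atoms)
  is_h <- atoms$role == "hydrogen"
  h_idx <- which(is_h)
  ## carbon row for each hydrogen: the matching carbon atom of same
  ## lipid/chain/carbon
  carbon_key <- paste(atoms$lipid_id, atoms$acyl, atoms$carbon)
  carb_rows <- which(atoms$role == "carbon")
  c_of_h <- carb_rows[match(carbon_key[h_idx], carbon_key[carb_rows])]
  theta_of_h <- vapply(h_idx, function(i) {
    acos(sqrt((2 * target_order[[atoms$acyl[i]]][[
      as.character(atoms$carbon[i])]] + 1) / 3))
  }, numeric(1L))
  sgn_of_h <- ifelse(atoms$leaflet[h_idx] == "upper", 1, -1)
  nh <- length(h_idx)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- base
    if (mode == "isotropic") {
      ct <- runif(nh, -1, 1)
      theta <- acos(ct)
    } else {
      theta <- theta_of_h
      if (mode == "noisy") {
        theta <- theta + rnorm(nh, 0, noise_sd)
        theta <- pmin(pmax(theta, 0), pi)
      }
    }
    psi <- runif(nh, 0, 2 * pi)
    d <- cbind(sin(theta) * cos(psi), sin(theta) * sin(psi),
               sgn_of_h * cos(theta))
    xyz[h_idx, ] <- xyz[c_of_h, ] + bond * d
    frames[[f]] <- xyz
  }
  mg_trajectory(top, frames)
}

#' Build a pose-clustering fixture with known labels
#'
#' Frames are drawn from reference Calpha conformations according to
#' `weights`, perturbed by isotropic Gaussian noise and a random rigid move
#' (rotation plus translation), with the generating label recorded per
#' frame.
#'
#' @param n_frames number of frames.
#' @param mode_references list of `n x 3` Calpha reference conformations
#'   (equal sizes).
#' @param noise_sigma isotropic Gaussian Calpha noise, A.
#' @param weights mode probabilities (sum to 1).
#' @param seed RNG seed.
#' @param topology optional peptide topology; defaults to a Calpha-only
#'   chain whose core is the full residue range.
#' @return list: `trajectory`, `labels` (integer per frame), `seed`.
#' @export
make_cluster_fixture <- function(n_frames, mode_references, noise_sigma,
                                 weights = NULL, seed = 1L,
                                 topology = NULL) {
  sizes <- vapply(mode_references, nrow, 1L)
  if (length(unique(sizes)) != 1L)
    stop("mode references must share the same atom count")
  n_at <- sizes[1L]
  weights <- weights %||% rep(1 / length(mode_references),
                              length(mode_references))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  topology <- topology %||% make_ca_topology(n_at)
  set.seed(seed)
  labels <- sample.int(length(mode_references), n_frames, replace = TRUE,
                       prob = weights)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    m <- mode_references[[labels[f]]] +
      matrix(rnorm(n_at * 3L, 0, noise_sigma), n_at, 3L)
    R <- .random_rotation()
    t <- runif(3L, -10, 10)
    frames[[f]] <- sweep(m %*% R, 2L, t, "+")
  }
  list(trajectory = mg_trajectory(topology, frames), labels = labels,
       seed = seed)
}

## Uniform-ish random proper rotation via QR of a Gaussian matrix.
.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9L), 3L, 3L))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}
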