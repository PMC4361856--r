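## Pipeline orchestration: one structured YAML config with sections
## mirroring the analysis stages; CSV outputs; provenance via config hash.

.config_defaults <- function() {
  list(
    trajectory = NULL,
    trajectory_b = NULL,
    output_dir = NULL,
    selections = list(
      side1 = "peptide_ca:3,6,7,18",
      side2 = "peptide_ca:1,12,16",
      phosphate = "membrane_p",
      tracked = "peptide_ca"),
    funnel = list(alpha_rad = 0.8, rcyl_A = 1, zcc_A = 35, zmax_A = 45,
                  k_wall = 10),
    contact = list(r0_A = 5, n = 8L, m = 16L, threshold = 0.5,
                   normalization = "per_group_atom"),
    clustering = list(n_clusters = 10L, core_start = 5L, core_end = 12L,
                      max_frames = 400L),
    order_parameters = list(chains = c("c1", "c2"), h_mode = "explicit",
                            n_blocks = 5L),
    simulation = list(seed = 1L))
}

.check_range <- function(errors, section, key, value, lo = -Inf, hi = Inf,
                         type = "numeric") {
  path <- paste0(section, ".", key)
  if (type == "numeric" && (!is.numeric(value) || length(value) != 1L ||
                            !is.finite(value)))
    return(c(errors, paste0(path, ": must be a finite number")))
  if (type == "numeric" && (value < lo || value > hi))
    return(c(errors, sprintf("%s: must lie in [%g, %g]", path, lo, hi)))
  errors
}

#' Validate and normalise a pipeline configuration
#'
#' Reads a YAML config (or takes a list), reports every unknown key and
#' every type/range violation in one aggregated error, and fills the
#' documented defaults: switching parameters r0 = 5 A, n = 8, m = 16;
#' bound threshold 0.5; funnel alpha = 0.8 rad, Rcyl = 1 A, Zcc = 35 A;
#' 10 cluster families over helix-core residues 5-12.
#'
#' @param config file path to a YAML config, or a nested list.
#' @return normalised config list of class `mg_config`, carrying a
#'   `config_hash` attribute that changes whenever any parameter changes.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  defaults <- .config_defaults()
  errors <- character(0L)
  unknown_top <- setdiff(names(config), names(defaults))
  if (length(unknown_top) > 0L)
    errors <- c(errors, paste0("unknown key: ", unknown_top))
  out <- defaults
  for (sec in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[sec]])) {
      given <- config[[sec]] %||% list()
      if (!is.list(given)) {
        errors <- c(errors, paste0(sec, ": must be a section (mapping)"))
        next
      }
      unknown <- setdiff(names(given), names(defaults[[sec]]))
      if (length(unknown) > 0L)
        errors <- c(errors, paste0("unknown key: ", sec, ".", unknown))
      for (k in intersect(names(given), names(defaults[[sec]])))
        out[[sec]][[k]] <- given[[k]]
    } else {
      out[[sec]] <- config[[sec]]
    }
  }
  ct <- out$contact
  errors <- .check_range(errors, "contact", "r0_A", ct$r0_A, 1e-6, Inf)
  errors <- .check_range(errors, "contact", "threshold", ct$threshold, 0, Inf)
  errors <- .check_range(errors, "contact", "n", ct$n, 2, 64)
  errors <- .check_range(errors, "contact", "m", ct$m, 2, 128)
  if (is.numeric(ct$n) && is.numeric(ct$m) && length(ct$n) == 1L &&
      length(ct$m) == 1L && is.finite(ct$n) && is.finite(ct$m) &&
      ct$n >= ct$m)
    errors <- c(errors, "contact.n: must be smaller than contact.m")
  if (!identical(ct$normalization, "per_group_atom") &&
      !identical(ct$normalization, "raw_sum"))
    errors <- c(errors, "contact.normalization: must be per_group_atom or raw_sum")
  fn <- out$funnel
  errors <- .check_range(errors, "funnel", "alpha_rad", fn$alpha_rad,
                         1e-6, pi / 2 - 1e-6)
  errors <- .check_range(errors, "funnel", "rcyl_A", fn$rcyl_A, 1e-6, Inf)
  errors <- .check_range(errors, "funnel", "zcc_A", fn$zcc_A, 1e-6, Inf)
  errors <- .check_range(errors, "funnel", "k_wall", fn$k_wall, 1e-6, Inf)
  cl <- out$clustering
  errors <- .check_range(errors, "clustering", "n_clusters", cl$n_clusters,
                         1, 1e6)
  errors <- .check_range(errors, "clustering", "core_start", cl$core_start,
                         1, 1e4)
  errors <- .check_range(errors, "clustering", "core_end", cl$core_end,
                         1, 1e4)
  op <- out$order_parameters
  errors <- .check_range(errors, "order_parameters", "n_blocks",
                         op$n_blocks, 2, 1000)
  if (!all(op$chains %in% c("c1", "c2")))
    errors <- c(errors, "order_parameters.chains: entries must be c1 or c2")
  if (!op$h_mode %in% c("explicit", "reconstructed"))
    errors <- c(errors,
                "order_parameters.h_mode: must be explicit or reconstructed")
  if (length(errors) > 0L)
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  attr(out, "config_hash") <- .config_hash(out)
  class(out) <- c("mg_config", "list")
  out
}

## Hash of the analysis parameters: input/output locations are excluded so
## that the same analysis on the same data hashes identically wherever the
## files happen to live, while any parameter change alters the hash.
.config_hash <- function(config) {
  params <- config[setdiff(names(config),
                           c("trajectory", "trajectory_b", "output_dir"))]
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(params[order(names(params))]), tmp)
  unname(tools::md5sum(tmp))
}

.require_sections <- function(raw, needed) {
  if (is.character(raw)) raw <- yaml::read_yaml(raw) %||% list()
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L)
    stop("config is missing required section(s): ",
         paste(missing, collapse = ", "))
  raw
}

.funnel_from_config <- function(fn) {
  funnel_geometry(alpha = fn$alpha_rad, rcyl = fn$rcyl_A, zcc = fn$zcc_A,
                  zmax = fn$zmax_A, k_wall = fn$k_wall)
}

#' Run the full binding analysis
#'
#' Orchestrates funnel-biased frame exclusion, per-side contact series,
#' bound-pose classification, helix-core RMSD clustering and representative
#' extraction, logging per-stage counts. Frames flagged by the funnel are
#' dropped from all statistics. With zero bound frames the report is
#' emitted gracefully with an empty cluster table.
#'
#' @param config YAML path or list; must name the `trajectory`,
#'   `selections`, `funnel`, `contact` and `clustering` sections.
#' @param trajectory optional pre-loaded `mg_trajectory` (overrides the
#'   config's `trajectory` path).
#' @return `mg_report` list: per-side contact summaries, bound fractions,
#'   cluster table, representatives, retained/excluded counts and a
#'   provenance block (config hash, seed, package version).
#' @export
run_binding_analysis <- function(config, trajectory = NULL) {
  raw <- .require_sections(config, c(
    if (is.null(trajectory)) "trajectory",
    "selections", "funnel", "contact", "clustering"))
  cfg <- validate_config(raw)
  if (is.null(trajectory)) {
    message("reading trajectory: ", cfg$trajectory)
    trajectory <- read_structure(cfg$trajectory, format = "pdb")$trajectory
  }
  top <- trajectory$topology
  nf <- n_frames(trajectory)
  sels <- lapply(cfg$selections, function(sp) build_selection(top, sp))
  geom <- .funnel_from_config(cfg$funnel)
  excluded <- frame_bias_flags(trajectory, geom, sels$tracked)
  message(sprintf("frames: %d total, %d excluded by the funnel wall",
                  nf, sum(excluded)))
  params <- switching_params(cfg$contact$r0_A, cfg$contact$n, cfg$contact$m)
  series <- per_side_series(trajectory, sels$side1, sels$side2,
                            sels$phosphate, params, excluded = excluded,
                            normalization = cfg$contact$normalization)
  mask1 <- classify_bound(series$side1, cfg$contact$threshold)
  mask2 <- classify_bound(series$side2, cfg$contact$threshold)
  bound <- as.logical(mask1) | as.logical(mask2)
  n_bound <- sum(bound)
  message(sprintf(
    "bound poses: %d (Side1 fraction %.3f, Side2 fraction %.3f)",
    n_bound, attr(mask1, "bound_fraction"), attr(mask2, "bound_fraction")))
  core <- c(cfg$clustering$core_start, cfg$clustering$core_end)
  clusters <- NULL; reps <- NULL; cluster_table <- data.frame(
    cluster = integer(), population = integer(), fraction = numeric(),
    representative_frame = integer())
  if (n_bound >= 2L) {
    cluster_mask <- bound
    if (n_bound > cfg$clustering$max_frames) {
      keep <- which(bound)[unique(round(seq(1L, n_bound,
        length.out = cfg$clustering$max_frames)))]
      cluster_mask <- rep(FALSE, nf); cluster_mask[keep] <- TRUE
      message(sprintf("clustering downsampled to %d bound frames",
                      sum(cluster_mask)))
    }
    dm <- rmsd_matrix(trajectory, cluster_mask, top, core = core)
    kk <- min(cfg$clustering$n_clusters, length(dm$frames))
    clusters <- average_linkage(dm, n_clusters = kk)
    reps <- representatives(clusters)
    cluster_table <- clusters$populations
    cluster_table$representative_frame <- unname(reps)
    message(sprintf("clustered %d poses into %d families (top family: %d)",
                    length(dm$frames), kk, cluster_table$population[1L]))
  } else {
    message("fewer than 2 bound frames: cluster table left empty")
  }
  contacts <- data.frame(
    frame = series$side1$frame, time_ps = series$side1$time_ps,
    s_side1 = series$side1$s, s_side2 = series$side2$s,
    excluded = excluded, bound_side1 = as.logical(mask1),
    bound_side2 = as.logical(mask2))
  provenance <- list(config_hash = attr(cfg, "config_hash"),
                     seed = cfg$simulation$seed,
                     version = as.character(utils::packageVersion("memglyco")))
  report <- structure(list(
    contacts = contacts,
    side_summary = list(side1 = summary(series$side1),
                        side2 = summary(series$side2)),
    bound_fraction = list(
      side1 = attr(mask1, "bound_fraction"),
      side2 = attr(mask2, "bound_fraction"),
      any = if (any(!excluded)) sum(bound) / sum(!excluded) else 0),
    clusters = clusters, cluster_table = cluster_table,
    n_retained = sum(!excluded), n_excluded = sum(excluded),
    provenance = provenance), class = "mg_report")
  if (!is.null(cfg$output_dir)) .write_report(report, cfg$output_dir)
  report
}

.write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) {
    attr(df, "config_hash") <- report$provenance$config_hash
    df
  }
  .write_csv_hashed(stamp(report$contacts),
                    file.path(dir, "contacts.csv"),
                    report$provenance$config_hash)
  .write_csv_hashed(stamp(report$cluster_table),
                    file.path(dir, "clusters.csv"),
                    report$provenance$config_hash)
  invisible(dir)
}

## CSV with a provenance comment line carrying the config hash.
.write_csv_hashed <- function(df, path, hash) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @export
print.mg_report <- function(x, ...) {
  cat("mg_report:", nrow(x$contacts), "frames (", x$n_retained,
      "retained )\n")
  cat(sprintf("  mean s: Side1 %.3f, Side2 %.3f\n",
              x$side_summary$side1$mean_s, x$side_summary$side2$mean_s))
  cat(sprintf("  bound fractions: Side1 %.3f, Side2 %.3f, any %.3f\n",
              x$bound_fraction$side1, x$bound_fraction$side2,
              x$bound_fraction$any))
  if (nrow(x$cluster_table) > 0L) print(head(x$cluster_table, 10L),
                                        row.names = FALSE)
  else cat("  (no bound poses to cluster)\n")
  invisible(x)
}

#' Run the order-parameter analysis
#'
#' Computes per-chain S_CD profiles for one or two systems (for example a
#' peptide-bound bilayer against a pure bilayer) and, when two systems are
#' given, the per-carbon comparison including the deepest perturbed carbon
#' per chain.
#'
#' @param config YAML path or list with `trajectory` (and optionally
#'   `trajectory_b`) plus an `order_parameters` section.
#' @param trajectory,trajectory_b optional pre-loaded `mg_trajectory`s.
#' @return list with `profiles` (per system, per chain), and when two
#'   systems are present `comparison` (per chain) and `deepest_carbon`.
#' @export
run_order_analysis <- function(config, trajectory = NULL,
                               trajectory_b = NULL) {
  raw <- .require_sections(config, c(
    if (is.null(trajectory)) "trajectory", "order_parameters"))
  cfg <- validate_config(raw)
  if (is.null(trajectory))
    trajectory <- read_structure(cfg$trajectory, format = "pdb")$trajectory
  if (is.null(trajectory_b) && !is.null(cfg$trajectory_b))
    trajectory_b <- read_structure(cfg$trajectory_b,
                                   format = "pdb")$trajectory
  op <- cfg$order_parameters
  prof <- function(traj) {
    setNames(lapply(op$chains, function(ch)
      scd_profile(traj, chain = ch, h_mode = op$h_mode,
                  n_blocks = op$n_blocks)), op$chains)
  }
  out <- list(profiles = list(system_a = prof(trajectory)),
              provenance = list(config_hash = attr(cfg, "config_hash")))
  if (!is.null(trajectory_b)) {
    out$profiles$system_b <- prof(trajectory_b)
    comps <- setNames(lapply(op$chains, function(ch)
      profile_compare(out$profiles$system_a[[ch]],
                      out$profiles$system_b[[ch]])), op$chains)
    out$comparison <- comps
    out$deepest_carbon <- vapply(comps, function(cc)
      attr(cc, "deepest_carbon")[[1L]], integer(1L))
    for (ch in op$chains)
      message(sprintf(
        "chain %s: deepest perturbed carbon %s", ch,
        ifelse(is.na(out$deepest_carbon[[ch]]), "none",
               out$deepest_carbon[[ch]])))
  }
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (sys in names(out$profiles))
      for (ch in names(out$profiles[[sys]]))
        .write_csv_hashed(out$profiles[[sys]][[ch]],
                          file.path(cfg$output_dir,
                                    sprintf("scd_%s_%s.csv", sys, ch)),
                          attr(cfg, "config_hash"))
  }
  out
}
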