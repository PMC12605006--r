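# Synthetic two-state trajectory generator. Emulates, at desk scale, a set
# of MD replicas in which an 8-residue helix segment (helix 12 plus the
# preceding threonine) stochastically switches between an "active" anchor
# pose packed against a rigid toy LBD scaffold and an "inactive" anchor pose
# far from it, following a two-state continuous-time Markov (telegraph)
# process observed at a fixed frame interval, with isotropic Gaussian
# coordinate noise. The ground-truth state sequence is retained so the full
# geometry -> classification -> occupancy pipeline can be validated against
# it.

#' Toy LBD geometry for the synthetic generator
#'
#' Builds a rigid pseudo-atom scaffold: C-alpha atoms for residues 248-476
#' on an ideal alpha-helical curve (rise 1.5 A, 3.6 residues/turn, radius
#' 2.3 A) plus C-beta pseudo-atoms at the two criterion residues (296 and
#' 466). Residues 466-476 form the mobile segment with two anchor poses:
#'
#' * active anchor: C-beta(466) sits `active_distance_A` from C-beta(296)
#'   (default 4.0 A, comfortably below the 4.6 A reference cutoff so that
#'   coordinate noise of a few tenths of an Angstrom does not flip the
#'   classification), and the helix RMSD to the reference is 0 by
#'   construction.
#' * inactive anchor: the mobile segment translated by `inactive_shift_A`
#'   (default 55 A), so the pair distance exceeds 45 A and the helix RMSD
#'   exceeds the 1.9 A cutoff more than tenfold.
#'
#' An optional "near-active" anchor (variant-like behaviour) replaces the
#' active anchor with one whose pair distance is `near_active_distance_A`
#' (default 6.6 A, above the cutoff) and whose helix RMSD to the true active
#' pose is about 2.6 A.
#'
#' @param active_distance_A C-beta pair distance in the active anchor (A)
#' @param inactive_shift_A rigid displacement of the inactive anchor (A)
#' @param near_active use the near-active anchor instead of the active one
#' @param near_active_distance_A pair distance of the near-active anchor (A)
#' @return An `h12_toy_geometry`: `topology` (`h12_structure` in the active
#'   anchor pose — also the analysis reference), `mobile_idx`, `core_idx`,
#'   `anchor_active`, `anchor_inactive` (coordinate matrices for the mobile
#'   rows).
#' @export
toy_geometry <- function(active_distance_A = 4.0, inactive_shift_A = 55,
                         near_active = FALSE, near_active_distance_A = 6.6) {
  stopifnot(active_distance_A > 0, inactive_shift_A > 45)
  core_res <- 248:465
  helix_pos <- function(t) {
    cbind(2.3 * cos(1.7453 * t), 2.3 * sin(1.7453 * t), 1.5 * t)
  }
  core_ca <- helix_pos(core_res - 248L)
  rownames(core_ca) <- NULL
  cb296 <- core_ca[match(296L, core_res), ] +
    1.5 * c(cos(1.7453 * (296 - 248)), sin(1.7453 * (296 - 248)), 0)
  # mobile segment: residues 466-476, its own short ideal helix hanging off
  # CB(466), which is placed straight above CB(296)
  build_mobile <- function(dist_a) {
    cb466 <- cb296 + c(0, 0, dist_a)
    ca466 <- cb466 + c(1.5, 0, 0)
    seg <- sweep(helix_pos(0:10), 2, helix_pos(0)[1, ], "-")
    mob_ca <- sweep(seg, 2, ca466, "+")      # residues 466..476
    list(cb466 = cb466, mob_ca = mob_ca)
  }
  act <- build_mobile(active_distance_A)
  mob_res <- 466:476
  # assemble rows in residue order: CA per residue, CB right after the CA of
  # residues 296 and 466
  rows <- list()
  for (i in seq_along(core_res)) {
    rows[[length(rows) + 1L]] <- c(core_res[i], 0, core_ca[i, ])  # 0 = CA
    if (core_res[i] == 296L) rows[[length(rows) + 1L]] <- c(296, 1, cb296)
  }
  for (i in seq_along(mob_res)) {
    rows[[length(rows) + 1L]] <- c(mob_res[i], 0, act$mob_ca[i, ])
    if (mob_res[i] == 466L) rows[[length(rows) + 1L]] <- c(466, 1, act$cb466)
  }
  m <- do.call(rbind, rows)
  atoms <- data.frame(chain = "A", resno = as.integer(m[, 1]),
                      resname = "THR", atom = ifelse(m[, 2] == 1, "CB", "CA"),
                      element = "C", x = m[, 3], y = m[, 4], z = m[, 5],
                      stringsAsFactors = FALSE)
  topo <- structure_model(atoms)
  mobile_idx <- which(topo$atoms$resno >= 466L)
  core_idx <- setdiff(seq_len(nrow(topo$atoms)), mobile_idx)
  anchor_true_active <- coords(topo)[mobile_idx, , drop = FALSE]
  anchor_active <- if (near_active) {
    # same pose shifted along the CB(296)->CB(466) axis so the pair distance
    # becomes near_active_distance_A and the helix RMSD to the true active
    # pose equals the shift magnitude
    sweep(anchor_true_active, 2,
          c(0, 0, near_active_distance_A - active_distance_A), "+")
  } else {
    anchor_true_active
  }
  anchor_inactive <- sweep(anchor_true_active, 2,
                           c(inactive_shift_A, 0, 0), "+")
  structure(list(topology = topo, mobile_idx = mobile_idx,
                 core_idx = core_idx,
                 anchor_active = anchor_active,
                 anchor_inactive = anchor_inactive,
                 near_active = near_active),
            class = "h12_toy_geometry")
}

#' Parameters for the synthetic generator
#'
#' The state sequence is the discrete-time embedding of a two-state
#' continuous-time Markov process: at each frame step of length `dt` the
#' probability of leaving the current state is `1 - exp(-k * dt)` with the
#' state's exit rate. When both rates are positive the stationary active
#' probability is `k_act / (k_act + k_deact)`.
#'
#' @param k_act inactive-to-active rate (per ns)
#' @param k_deact active-to-inactive rate (per ns)
#' @param noise_sigma_A isotropic Gaussian positional noise per coordinate (A)
#' @param n_frames frames per replica (default 1000; with 1 ns/frame this is
#'   the 1-microsecond-per-replica design at desk scale)
#' @param frame_interval_ns frame interval (ns)
#' @param start_state `"active"`, `"inactive"`, or `"stationary"` (initial
#'   state drawn from the stationary distribution
#'   `k_act / (k_act + k_deact)`, for cohorts meant to sample the
#'   equilibrium occupancy without burn-in bias)
#' @param seed RNG seed for this replica
#' @param geometry an `h12_toy_geometry`
#' @return An `h12_synth_params` list.
#' @export
synthetic_params <- function(k_act, k_deact, noise_sigma_A = 0.2,
                             n_frames = 1000L, frame_interval_ns = 1,
                             start_state = c("inactive", "active", "stationary"),
                             seed = 1L, geometry = toy_geometry()) {
  start_state <- match.arg(start_state)
  if (k_act < 0 || k_deact < 0) stop("rates must be non-negative", call. = FALSE)
  if (start_state == "stationary" && (k_act + k_deact) == 0) {
    stop("stationary start requires at least one positive rate", call. = FALSE)
  }
  stopifnot(n_frames >= 1, frame_interval_ns > 0, noise_sigma_A >= 0)
  structure(list(k_act = k_act, k_deact = k_deact,
                 noise_sigma_A = noise_sigma_A, n_frames = as.integer(n_frames),
                 frame_interval_ns = frame_interval_ns,
                 start_state = start_state, seed = as.integer(seed),
                 geometry = geometry),
            class = "h12_synth_params")
}

#' Simulate one replica: state sequence plus trajectory
#'
#' States evolve by per-frame switch probabilities `1 - exp(-k dt)`; the
#' first frame is in `start_state`. Each frame's mobile atoms sit at the
#' current state's anchor pose and all atoms (core included) get i.i.d.
#' Gaussian noise per coordinate. The ground-truth state sequence is
#' returned alongside the coordinates.
#'
#' @param params an `h12_synth_params`
#' @param system_label,replica_index trajectory metadata
#' @return list with `states` (logical, TRUE = active) and `trajectory`
#'   (`h12_trajectory`).
#' @export
simulate_state_sequence <- function(params, system_label = "synthetic",
                                    replica_index = 1L) {
  stopifnot(inherits(params, "h12_synth_params"))
  g <- params$geometry
  set.seed(params$seed)
  dt <- params$frame_interval_ns
  p_act <- 1 - exp(-params$k_act * dt)     # inactive -> active per step
  p_deact <- 1 - exp(-params$k_deact * dt) # active -> inactive per step
  n <- params$n_frames
  states <- logical(n)
  states[1] <- switch(params$start_state,
    active = TRUE,
    inactive = FALSE,
    stationary = stats::runif(1) < params$k_act / (params$k_act + params$k_deact))
  if (n > 1) {
    u <- stats::runif(n - 1)
    for (k in 2:n) {
      states[k] <- if (states[k - 1]) u[k - 1] >= p_deact else u[k - 1] < p_act
    }
  }
  base <- coords(g$topology)
  n_atoms <- nrow(base)
  frames <- array(stats::rnorm(n_atoms * 3 * n, sd = params$noise_sigma_A),
                  c(n_atoms, 3L, n))
  for (k in seq_len(n)) {
    pose <- base
    pose[g$mobile_idx, ] <- if (states[k]) g$anchor_active else g$anchor_inactive
    frames[, , k] <- frames[, , k] + pose
  }
  list(states = states,
       trajectory = trajectory(g$topology, frames, dt, system_label,
                               replica_index))
}

#' Simulate a cohort of replicas in memory
#'
#' Per-replica seeds are derived deterministically from the parameter seed
#' (`seed + replica - 1`), so a cohort is reproducible and replicas are
#' independent.
#'
#' @param params an `h12_synth_params` (its `seed` seeds replica 1)
#' @param n_replicas number of replicas (default 15)
#' @param system_label cohort label
#' @return list with `trajectories`, `states` (list of logical vectors) and
#'   `truth_occupancy_pct` (per replica, from the ground-truth states).
#' @export
simulate_cohort <- function(params, n_replicas = 15L,
                            system_label = "synthetic") {
  reps <- lapply(seq_len(n_replicas), function(r) {
    p <- params
    p$seed <- params$seed + r - 1L
    simulate_state_sequence(p, system_label = system_label, replica_index = r)
  })
  list(trajectories = lapply(reps, `[[`, "trajectory"),
       states = lapply(reps, `[[`, "states"),
       truth_occupancy_pct = vapply(reps, function(x) 100 * mean(x$states),
                                    numeric(1)))
}

#' Generate a cohort on disk
#'
#' Writes, per system: the topology PDB (shared), one XYZ trajectory per
#' replica, a ground-truth state TSV (`system`, `replica`, `frame`,
#' `active`), and a JSON manifest plus an analysis-config stub referencing
#' the generated files. Byte-identical across runs with the same seeds.
#'
#' @param systems named list: each element a list with `params`
#'   (`h12_synth_params`) and optionally `n_replicas` (default 15)
#' @param out_dir output directory (created if needed)
#' @return (invisibly) the manifest as a list.
#' @export
generate_cohort <- function(systems, out_dir) {
  if (is.null(names(systems)) || anyDuplicated(names(systems))) {
    stop("systems must be a named list with distinct labels", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  topo_path <- file.path(out_dir, "topology.pdb")
  ref_path <- file.path(out_dir, "reference.pdb")
  manifest <- list(systems = list())
  truth_rows <- list()
  wrote_topo <- FALSE
  for (label in names(systems)) {
    sys <- systems[[label]]
    n_rep <- if (is.null(sys$n_replicas)) 15L else as.integer(sys$n_replicas)
    coh <- simulate_cohort(sys$params, n_rep, system_label = label)
    if (!wrote_topo) {
      write_pdb(sys$params$geometry$topology, topo_path)
      # reference = true active pose of a non-near-active geometry
      ref_geom <- toy_geometry()
      write_pdb(ref_geom$topology, ref_path)
      wrote_topo <- TRUE
    }
    paths <- character(n_rep)
    for (r in seq_len(n_rep)) {
      paths[r] <- file.path(out_dir, sprintf("%s_rep%02d.xyz", label, r))
      write_traj_xyz(coh$trajectories[[r]], paths[r])
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        system = label, replica = r,
        frame = seq_along(coh$states[[r]]),
        active = as.integer(coh$states[[r]]))
    }
    manifest$systems[[label]] <- list(
      label = label, n_replicas = n_rep,
      trajectories = basename(paths),
      k_act = sys$params$k_act, k_deact = sys$params$k_deact,
      noise_sigma_A = sys$params$noise_sigma_A,
      n_frames = sys$params$n_frames,
      frame_interval_ns = sys$params$frame_interval_ns,
      start_state = sys$params$start_state, seed = sys$params$seed,
      truth_occupancy_pct = round(coh$truth_occupancy_pct, 4))
  }
  truth <- do.call(rbind, truth_rows)
  utils::write.table(truth, file.path(out_dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$topology <- basename(topo_path)
  manifest$reference <- basename(ref_path)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  config <- default_config(
    reference_pdb = ref_path, topology_pdb = topo_path,
    systems = lapply(names(systems), function(label) {
      list(label = label,
           trajectories = file.path(out_dir,
                                    manifest$systems[[label]]$trajectories))
    }),
    frame_interval_ns = systems[[1]]$params$frame_interval_ns,
    output_dir = file.path(out_dir, "analysis"))
  write_config(config, file.path(out_dir, "config.json"))
  invisible(manifest)
}

#' Paper-like preset cohort specifications
#'
#' Four systems mirroring the study design (active/inactive starting state
#' for wild type and variant, 15 replicas each). Rates are chosen so the
#' cohorts reproduce the qualitative pattern of the reported statistics:
#' active WT occupies the active state about a quarter of the time, the
#' active variant only transiently, the inactive WT reaches the active
#' state in a minority of replicas and then persists, and the inactive
#' variant rarely reaches it. The variant systems use the near-active
#' anchor geometry.
#'
#' @param seed base seed; per-system seeds are spaced by 1000 so replica
#'   streams never overlap
#' @param n_frames frames per replica
#' @param frame_interval_ns frame interval (ns)
#' @param noise_sigma_A coordinate noise (A)
#' @return named list of system specs suitable for [generate_cohort()].
#' @export
paper_like_systems <- function(seed = 1L, n_frames = 1000L,
                               frame_interval_ns = 1, noise_sigma_A = 0.2) {
  mk <- function(k_act, k_deact, start, near, off) {
    list(params = synthetic_params(
      k_act = k_act, k_deact = k_deact, noise_sigma_A = noise_sigma_A,
      n_frames = n_frames, frame_interval_ns = frame_interval_ns,
      start_state = start, seed = seed + off,
      geometry = toy_geometry(near_active = near)),
      n_replicas = 15L)
  }
  list(
    active_WT      = mk(0.01,    0.03, "active",   FALSE, 0L),
    active_T296I   = mk(2e-4,    0.05, "active",   TRUE,  1000L),
    inactive_WT    = mk(5.1e-4,  2e-3, "inactive", FALSE, 2000L),
    inactive_T296I = mk(6.9e-5,  0.05, "inactive", TRUE,  3000L))
}
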