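# Per-frame metrics -> state classification, occupancy, dwell times, and the
# skew-normal cutoff derivation.

# ---- State criteria -------------------------------------------------------

#' Geometric state criteria
#'
#' Two criteria classify a frame as "active" when a geometric metric falls
#' strictly below a reference cutoff:
#'
#' * `distance_criterion()`: the C-beta pair distance between the helix-3
#'   variant site (residue 296) and the residue preceding helix 12 (466).
#'   The default cutoff, 4.6 Angstrom, is the distance measured in the
#'   agonist-bound active-state crystal structure.
#' * `rmsd_criterion()`: RMSD of helix 12 plus the preceding threonine
#'   (C-alpha of residues 466-473) to the active reference conformation,
#'   after superposing each frame on the stable LBD core (C-alpha 248-459,
#'   excluding the remodeled 460-466 loop and helix 12). The default cutoff,
#'   1.9 Angstrom, is the mean of a skew-normal fit to the pooled active-WT
#'   RMSD histogram (see [fit_skew_normal_cutoff()]).
#'
#' @param res_a,res_b residue numbers of the distance pair (author numbering)
#' @param atom atom name used by the metric (`"CB"` for distance, `"CA"` for
#'   RMSD by default)
#' @param cutoff_A reference cutoff in Angstrom; frames with metric strictly
#'   below it are active (ties classify inactive, so the rule is
#'   deterministic)
#' @param chain optional chain restriction
#' @return An object of class `h12_criterion`.
#' @export
distance_criterion <- function(res_a = 296, res_b = 466, atom = "CB",
                               cutoff_A = 4.6, chain = NULL) {
  stopifnot(cutoff_A > 0)
  structure(list(name = sprintf("cbeta_distance_%d_%d", res_a, res_b),
                 metric = "cbeta_distance",
                 sel_a = selection_spec(c(res_a, res_a), atom, chain),
                 sel_b = selection_spec(c(res_b, res_b), atom, chain),
                 cutoff_A = cutoff_A, active_direction = "below"),
            class = "h12_criterion")
}

#' @rdname distance_criterion
#' @param calc_residues inclusive residue range whose RMSD is measured
#' @param fit_residues inclusive residue range used for superposition
#' @export
rmsd_criterion <- function(calc_residues = c(466, 473),
                           fit_residues = c(248, 459), atom = "CA",
                           cutoff_A = 1.9, chain = NULL) {
  stopifnot(cutoff_A > 0)
  structure(list(name = sprintf("h12_rmsd_%d_%d", calc_residues[1], calc_residues[2]),
                 metric = "h12_rmsd",
                 sel_calc = selection_spec(calc_residues, atom, chain),
                 sel_fit = selection_spec(fit_residues, atom, chain),
                 cutoff_A = cutoff_A, active_direction = "below"),
            class = "h12_criterion")
}

# ---- Metric series --------------------------------------------------------

#' Compute the per-frame metric series of a trajectory
#'
#' One metric value per frame, in frame order. For the distance criterion the
#' reference structure is not consulted (the cutoff embodies it); for the
#' RMSD criterion each frame is superposed on the reference over the fit
#' selection and the RMSD of the calc selection is measured without
#' refitting.
#'
#' @param traj an `h12_trajectory`
#' @param criterion an `h12_criterion`
#' @param reference `h12_structure` of the active reference state (required
#'   for the RMSD criterion); selections are resolved on the trajectory
#'   topology and on the reference independently
#' @return An object of class `h12_metric_series` with fields `values`
#'   (Angstrom), `frame_interval_ns`, `system_label`, `replica_index`,
#'   `metric`.
#' @export
compute_metric_series <- function(traj, criterion, reference = NULL) {
  stopifnot(inherits(traj, "h12_trajectory"), inherits(criterion, "h12_criterion"))
  topo <- traj$topology
  nf <- n_frames(traj)
  if (criterion$metric == "cbeta_distance") {
    ia <- select_atoms(topo, criterion$sel_a)
    ib <- select_atoms(topo, criterion$sel_b)
    if (length(ia) != 1L || length(ib) != 1L) {
      stop("distance criterion selections must each resolve to one atom",
           call. = FALSE)
    }
    d <- traj$frames[ia, , ] - traj$frames[ib, , ]
    if (nf == 1L) d <- matrix(d, nrow = 3)
    values <- sqrt(colSums(d^2))
  } else if (criterion$metric == "h12_rmsd") {
    if (is.null(reference)) {
      stop("the RMSD criterion requires an active-state reference structure",
           call. = FALSE)
    }
    fit_t <- select_atoms(topo, criterion$sel_fit)
    calc_t <- select_atoms(topo, criterion$sel_calc)
    fit_r <- select_atoms(reference, criterion$sel_fit)
    calc_r <- select_atoms(reference, criterion$sel_calc)
    if (length(fit_t) != length(fit_r) || length(calc_t) != length(calc_r)) {
      stop("fit/calc selections resolve to different atom counts on topology vs reference",
           call. = FALSE)
    }
    ref_fit <- coords(reference)[fit_r, , drop = FALSE]
    ref_calc <- coords(reference)[calc_r, , drop = FALSE]
    values <- vapply(seq_len(nf), function(k) {
      fr <- traj$frames[, , k]
      tf <- kabsch_superpose(fr[fit_t, , drop = FALSE], ref_fit)
      rmsd(apply_transform(fr[calc_t, , drop = FALSE], tf), ref_calc)
    }, numeric(1))
  } else {
    stop("unknown metric: ", criterion$metric, call. = FALSE)
  }
  structure(list(values = as.numeric(values),
                 frame_interval_ns = traj$frame_interval_ns,
                 system_label = traj$system_label,
                 replica_index = traj$replica_index,
                 metric = criterion$metric),
            class = "h12_metric_series")
}

#' Wrap precomputed metric values as a metric series
#' @param values numeric per-frame metric values (Angstrom)
#' @inheritParams trajectory
#' @export
metric_series <- function(values, frame_interval_ns = 1,
                          system_label = "system", replica_index = 1L,
                          metric = "cbeta_distance") {
  stopifnot(is.numeric(values), length(values) >= 1, all(is.finite(values)),
            frame_interval_ns > 0)
  structure(list(values = as.numeric(values),
                 frame_interval_ns = frame_interval_ns,
                 system_label = system_label,
                 replica_index = as.integer(replica_index), metric = metric),
            class = "h12_metric_series")
}

# ---- Classification and occupancy ----------------------------------------

#' Classify frames against a criterion cutoff
#'
#' A frame is active iff its metric value is strictly below the cutoff;
#' a value exactly at the cutoff is inactive (deterministic tie rule).
#' Classification depends only on values and cutoff, never on the
#' frame-interval metadata.
#'
#' @param series an `h12_metric_series`
#' @param criterion an `h12_criterion` (or a single numeric cutoff)
#' @return An `h12_state_series` with logical `active` per frame.
#' @export
classify_frames <- function(series, criterion) {
  stopifnot(inherits(series, "h12_metric_series"))
  cutoff <- if (is.numeric(criterion)) criterion else criterion$cutoff_A
  name <- if (is.numeric(criterion)) sprintf("cutoff_%g", criterion) else criterion$name
  structure(list(active = series$values < cutoff,
                 cutoff_A = cutoff, criterion_name = name,
                 frame_interval_ns = series$frame_interval_ns,
                 system_label = series$system_label,
                 replica_index = series$replica_index),
            class = "h12_state_series")
}

#' Construct a state series directly from flags (mostly for testing)
#' @param active logical vector of per-frame active flags
#' @inheritParams trajectory
#' @export
state_series <- function(active, frame_interval_ns = 1,
                         system_label = "system", replica_index = 1L) {
  stopifnot(is.logical(active), length(active) >= 1, frame_interval_ns > 0)
  structure(list(active = active, cutoff_A = NA_real_,
                 criterion_name = "manual",
                 frame_interval_ns = frame_interval_ns,
                 system_label = system_label,
                 replica_index = as.integer(replica_index)),
            class = "h12_state_series")
}

#' Occupancy: percentage of frames in the active state
#' @param series an `h12_state_series`
#' @return frequency of occurrence in percent, in `[0, 100]`
#' @export
occupancy <- function(series) {
  stopifnot(inherits(series, "h12_state_series"), length(series$active) >= 1)
  100 * sum(series$active) / length(series$active)
}

#' Dwell (persistence) times of the active state
#'
#' Maximal runs of consecutive active frames; each duration is the run
#' length times the frame interval. Their sum equals
#' occupancy/100 x total simulated time exactly, by construction.
#'
#' @param series an `h12_state_series`
#' @return numeric vector of active-run durations in ns (file order;
#'   empty if the state is never reached)
#' @export
dwell_times <- function(series) {
  stopifnot(inherits(series, "h12_state_series"))
  r <- rle(series$active)
  as.numeric(r$lengths[r$values]) * series$frame_interval_ns
}

#' Did the replica reach the active state at all?
#' @param series an `h12_state_series`
#' @return `TRUE` iff at least one frame is active (equivalently
#'   occupancy > 0)
#' @export
reached_active <- function(series) {
  stopifnot(inherits(series, "h12_state_series"))
  any(series$active)
}

#' Summarize one replica
#' @param series an `h12_state_series`
#' @return An `h12_replica_summary`: system label, replica index, occupancy
#'   percent, reached flag, dwell times (ns).
#' @export
replica_summary <- function(series) {
  structure(list(system_label = series$system_label,
                 replica_index = series$replica_index,
                 frequency_pct = occupancy(series),
                 reached_active = reached_active(series),
                 dwell_times_ns = dwell_times(series),
                 n_frames = length(series$active),
                 frame_interval_ns = series$frame_interval_ns),
            class = "h12_replica_summary")
}

#' Export a metric + state series as TSV
#'
#' Columns: `frame`, `time_ns`, `value_A`, `active`. Floats use fixed
#' formatting so repeated runs are byte-identical.
#'
#' @param metric an `h12_metric_series`
#' @param state matching `h12_state_series`
#' @param path output path
#' @export
export_series_tsv <- function(metric, state, path) {
  stopifnot(length(metric$values) == length(state$active))
  n <- length(metric$values)
  df <- data.frame(frame = seq_len(n),
                   time_ns = sprintf("%.3f", (seq_len(n) - 1) * metric$frame_interval_ns),
                   value_A = sprintf("%.4f", metric$values),
                   active = as.integer(state$active))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- Skew-normal cutoff derivation ----------------------------------------

#' Skew-normal density
#' @param x evaluation points
#' @param xi location (Angstrom)
#' @param omega scale (Angstrom, > 0)
#' @param alpha shape (real; 0 recovers the normal density)
#' @return density values
#' @export
dskewnorm <- function(x, xi, omega, alpha) {
  z <- (x - xi) / omega
  2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
}

#' Mean of a skew-normal distribution
#' @inheritParams dskewnorm
#' @return `xi + omega * delta * sqrt(2/pi)` with
#'   `delta = alpha / sqrt(1 + alpha^2)`
#' @export
skewnorm_mean <- function(xi, omega, alpha) {
  xi + omega * (alpha / sqrt(1 + alpha^2)) * sqrt(2 / pi)
}

#' Draw skew-normal variates (used by the synthetic fixtures)
#' @param n number of draws
#' @inheritParams dskewnorm
#' @export
rskewnorm <- function(n, xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- stats::rnorm(n); u1 <- stats::rnorm(n)
  xi + omega * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
}

#' Fit a skew-normal ("skewed Gaussian") to a metric histogram
#'
#' Pooled metric values (across all replicas of one system) are binned into
#' a density-normalized histogram; the three-parameter skew-normal density is
#' fitted to the bin midpoints by least squares. The distribution mean
#' implied by the fitted parameters is the derived cutoff. This mirrors
#' deriving the helix-12 RMSD reference cutoff from the pooled active-WT
#' histogram.
#'
#' @param values pooled metric values (Angstrom), at least 100
#' @param bin_width_A histogram bin width (default 0.1 Angstrom); the derived
#'   mean should be stable to about +/- 0.02 Angstrom over widths 0.05-0.2
#' @param force_alpha optionally pin the shape (e.g. `0` for a plain
#'   Gaussian fit on the same histogram)
#' @return An `h12_skewfit`: `xi`, `omega`, `alpha`, `derived_mean`, `rss`
#'   (residual sum of squares), `bin_width_A`, `convergence`.
#' @export
fit_skew_normal_cutoff <- function(values, bin_width_A = 0.1,
                                   force_alpha = NULL) {
  values <- as.numeric(values)
  if (length(values) < 100L) {
    stop("skew-normal cutoff fit requires at least 100 pooled values",
         call. = FALSE)
  }
  if (bin_width_A <= 0) stop("bin_width_A must be positive", call. = FALSE)
  rng <- range(values)
  if (diff(rng) < .Machine$double.eps^0.5) {
    stop("degenerate input: all metric values identical", call. = FALSE)
  }
  breaks <- seq(floor(rng[1] / bin_width_A) * bin_width_A,
                ceiling(rng[2] / bin_width_A) * bin_width_A + bin_width_A / 2,
                by = bin_width_A)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$density
  # moment-based start: solve sample skewness for delta, clamped to validity
  m <- mean(values); s <- stats::sd(values)
  g1 <- mean(((values - m) / s)^3)
  g1 <- max(min(g1, 0.9), -0.9)
  b <- sqrt(2 / pi)
  num <- abs(g1)^(2 / 3)
  delta0 <- sign(g1) * sqrt((pi / 2) * num / (num + ((4 - pi) / 2)^(2 / 3)))
  delta0 <- max(min(delta0, 0.95), -0.95)
  alpha0 <- delta0 / sqrt(1 - delta0^2)
  omega0 <- s / sqrt(max(1 - 2 * delta0^2 / pi, 0.1))
  xi0 <- m - omega0 * delta0 * b
  obj <- if (is.null(force_alpha)) {
    function(p) sum((dskewnorm(x, p[1], exp(p[2]), p[3]) - y)^2)
  } else {
    function(p) sum((dskewnorm(x, p[1], exp(p[2]), force_alpha) - y)^2)
  }
  p0 <- if (is.null(force_alpha)) c(xi0, log(omega0), alpha0) else c(m, log(s))
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  if (fit$convergence != 0) {
    stop("skew-normal fit did not converge (optim code ", fit$convergence,
         ", value ", signif(fit$value, 4), ")", call. = FALSE)
  }
  xi <- fit$par[1]; omega <- exp(fit$par[2])
  alpha <- if (is.null(force_alpha)) fit$par[3] else force_alpha
  structure(list(xi = xi, omega = omega, alpha = alpha,
                 derived_mean = skewnorm_mean(xi, omega, alpha),
                 rss = fit$value, bin_width_A = bin_width_A,
                 n_values = length(values), convergence = fit$convergence),
            class = "h12_skewfit")
}

#' @export
print.h12_skewfit <- function(x, ...) {
  cat(sprintf(paste0("<h12_skewfit: xi = %.4f, omega = %.4f, alpha = %.3f, ",
                     "derived mean = %.4f A (bin %.3g A, n = %d, rss = %.3g)>\n"),
              x$xi, x$omega, x$alpha, x$derived_mean, x$bin_width_A,
              x$n_values, x$rss))
  invisible(x)
}
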