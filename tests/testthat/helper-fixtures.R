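# Fixtures are built in code at test time; nothing binary on disk.

# Minimal LBD-like model: one CA per residue over an author-numbered range,
# CB on selected residues, arranged on a non-degenerate helical curve.
make_ca_fixture <- function(resnos = 248:476, cb_at = c(296L, 466L),
                            gly_at = integer()) {
  t <- seq_along(resnos) - 1
  ca <- cbind(2.3 * cos(1.7 * t), 2.3 * sin(1.7 * t), 1.5 * t)
  rows <- list()
  for (i in seq_along(resnos)) {
    rn <- resnos[i]
    resname <- if (rn %in% gly_at) "GLY" else "THR"
    rows[[length(rows) + 1L]] <- data.frame(
      chain = "A", resno = rn, resname = resname, atom = "CA",
      element = "C", x = ca[i, 1], y = ca[i, 2], z = ca[i, 3])
    if (rn %in% cb_at && !(rn %in% gly_at)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = "A", resno = rn, resname = resname, atom = "CB",
        element = "C", x = ca[i, 1] + 1.5, y = ca[i, 2], z = ca[i, 3])
    }
  }
  structure_model(do.call(rbind, rows))
}

# Random proper rotation matrix (QR of a Gaussian matrix, det fixed to +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# State series straight from flags with given dt.
flags_series <- function(flags, dt = 1, label = "sys", rep = 1L) {
  state_series(flags, frame_interval_ns = dt, system_label = label,
               replica_index = rep)
}

# Small in-memory cohort -> list of state series under a criterion.
classify_cohort <- function(cohort, criterion, reference = NULL) {
  lapply(cohort$trajectories, function(tr) {
    classify_frames(compute_metric_series(tr, criterion, reference), criterion)
  })
}
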