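test_that("toy geometry satisfies both criteria constraints", {
  g <- toy_geometry()
  x <- coords(g$topology)
  ia <- select_atoms(g$topology, selection_spec(c(296, 296), "CB"))
  ib <- select_atoms(g$topology, selection_spec(c(466, 466), "CB"))
  d_act <- pair_distance(x, ia, ib)
  expect_lt(d_act, 4.6)
  xi <- x; xi[g$mobile_idx, ] <- g$anchor_inactive
  d_inact <- pair_distance(xi, ia, ib)
  expect_gt(d_inact, 45)
  expect_gt(d_inact, 10 * 4.6)             # violates by >= 10x
  expect_gt(rmsd(g$anchor_active, g$anchor_inactive), 10 * 1.9)
  # near-active variant anchor sits above the distance cutoff
  gn <- toy_geometry(near_active = TRUE)
  xn <- coords(gn$topology); xn[gn$mobile_idx, ] <- gn$anchor_active
  expect_equal(pair_distance(xn, ia, ib), 6.6, tolerance = 1e-9)
})

test_that("absorbing active state gives 100% occupancy through the pipeline", {
  g <- toy_geometry()
  p <- synthetic_params(k_act = 0.05, k_deact = 0, noise_sigma_A = 0.2,
                        n_frames = 200, seed = 3, start_state = "active",
                        geometry = g)
  sim <- simulate_state_sequence(p)
  expect_true(all(sim$states))
  crit <- distance_criterion()
  st <- classify_frames(compute_metric_series(sim$trajectory, crit), crit)
  expect_gt(occupancy(st), 95)  # noise can nudge single frames over
})

test_that("symmetric rates give ~50% ground-truth occupancy (closed form)", {
  p <- synthetic_params(k_act = 0.05, k_deact = 0.05, noise_sigma_A = 0,
                        n_frames = 2e4, seed = 9, start_state = "stationary")
  sim <- simulate_state_sequence(p)
  expect_lte(abs(100 * mean(sim$states) - 50), 3)
})

test_that("stationary occupancy matches k_act/(k_act + k_deact) over a cohort", {
  p <- synthetic_params(k_act = 0.01, k_deact = 0.03, noise_sigma_A = 0,
                        n_frames = 1000, seed = 13, start_state = "stationary")
  coh <- simulate_cohort(p, 15)
  expect_lte(abs(mean(coh$truth_occupancy_pct) - 25), 3)
})

test_that("zero-noise classification recovers ground truth exactly", {
  g <- toy_geometry()
  p <- synthetic_params(k_act = 0.02, k_deact = 0.04, noise_sigma_A = 0,
                        n_frames = 300, seed = 17, start_state = "inactive",
                        geometry = g)
  sim <- simulate_state_sequence(p)
  for (crit in list(distance_criterion(), rmsd_criterion())) {
    st <- classify_frames(
      compute_metric_series(sim$trajectory, crit, g$topology), crit)
    expect_identical(st$active, sim$states)
  }
})

test_that("active dwell lengths are geometric with the embedded rate", {
  k_deact <- 0.05; dt <- 1
  p <- synthetic_params(k_act = 0.05, k_deact = k_deact, noise_sigma_A = 0,
                        n_frames = 4e4, seed = 29, start_state = "stationary")
  sim <- simulate_state_sequence(p)
  runs <- rle(sim$states)
  dwell <- runs$lengths[runs$values]
  # drop the possibly-censored final run
  if (sim$states[length(sim$states)]) dwell <- dwell[-length(dwell)]
  p_leave <- 1 - exp(-k_deact * dt)
  expect_equal(mean(dwell), 1 / p_leave, tolerance = 0.1 / p_leave)
  # chi-square GOF against the geometric pmf, tail lumped
  kmax <- max(10, stats::qgeom(0.99, p_leave) + 1)
  obs <- tabulate(pmin(dwell, kmax), nbins = kmax)
  probs <- stats::dgeom(0:(kmax - 1), p_leave)
  probs[kmax] <- probs[kmax] + stats::pgeom(kmax - 1, p_leave, lower.tail = FALSE)
  keep <- probs * length(dwell) >= 5
  gof <- suppressWarnings(stats::chisq.test(
    c(sum(obs[!keep]), obs[keep]),
    p = c(sum(probs[!keep]), probs[keep]) / sum(probs)))
  expect_gt(gof$p.value, 0.01)
})

test_that("generate_cohort writes a deterministic, round-trippable bundle", {
  g <- toy_geometry()
  systems <- list(
    sysA = list(params = synthetic_params(0.02, 0.02, 0.1, n_frames = 20,
                                          seed = 41, geometry = g),
                n_replicas = 2L),
    sysB = list(params = synthetic_params(0.001, 0.05, 0.1, n_frames = 20,
                                          seed = 141, geometry = g),
                n_replicas = 2L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_cohort(systems, d1)
  m2 <- generate_cohort(systems, d2)
  files <- sort(list.files(d1))
  expect_true(all(c("topology.pdb", "reference.pdb", "ground_truth.tsv",
                    "manifest.json", "config.json",
                    "sysA_rep01.xyz", "sysB_rep02.xyz") %in% files))
  # same seeds twice -> byte-identical trajectory/truth outputs
  for (f in setdiff(files, "config.json")) {  # config embeds absolute paths
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # ground truth TSV matches in-memory truth
  truth <- read.delim(file.path(d1, "ground_truth.tsv"))
  expect_equal(nrow(truth), 4 * 20)
  coh <- simulate_cohort(systems$sysA$params, 2, system_label = "sysA")
  expect_equal(truth$active[truth$system == "sysA" & truth$replica == 1],
               as.integer(coh$states[[1]]))
  expect_error(generate_cohort(list(a = systems$sysA, a = systems$sysB),
                               withr::local_tempdir()), "distinct")
})

test_that("full pipeline recovers ground-truth occupancy at noise <= 0.3 A", {
  # At sigma = 0.3 the pair-distance spread (sd ~ sqrt(2)*0.3 A) puts ~8% of
  # true-active frames above the 4.6 A cutoff (anchor at 4.0 A), so recovery
  # is downward-biased by at most a few percentage points on top of
  # binomial sampling error; at the default sigma = 0.2 the bias is < 2% of
  # active frames.
  p <- synthetic_params(k_act = 0.02, k_deact = 0.04, noise_sigma_A = 0.3,
                        n_frames = 500, seed = 59, start_state = "stationary")
  coh <- simulate_cohort(p, 5)
  crit <- distance_criterion()
  occ <- vapply(classify_cohort(coh, crit), occupancy, numeric(1))
  expect_true(all(occ <= coh$truth_occupancy_pct + 0.5))
  expect_true(all(occ >= coh$truth_occupancy_pct - 4.5))

  p2 <- synthetic_params(k_act = 0.02, k_deact = 0.04, noise_sigma_A = 0.2,
                         n_frames = 500, seed = 61, start_state = "stationary")
  coh2 <- simulate_cohort(p2, 5)
  occ2 <- vapply(classify_cohort(coh2, crit), occupancy, numeric(1))
  expect_true(all(abs(occ2 - coh2$truth_occupancy_pct) <= 2))
})

test_that("parameter validation", {
  expect_error(synthetic_params(-1, 0.1), "non-negative")
  expect_error(synthetic_params(0, 0, start_state = "stationary"),
               "positive rate")
})
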