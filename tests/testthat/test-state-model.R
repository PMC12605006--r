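test_that("compute_metric_series: distance metric matches closed forms", {
  m <- make_ca_fixture(resnos = 295:467, cb_at = c(296L, 466L))
  xyz <- coords(m)
  ia <- select_atoms(m, selection_spec(c(296, 296), "CB"))
  ib <- select_atoms(m, selection_spec(c(466, 466), "CB"))
  # 3 frames: coincident CBs, then a 3-4-5 pair
  fr <- array(rep(xyz, 3), c(nrow(xyz), 3, 3))
  fr[ib, , 1] <- fr[ia, , 1]
  fr[ia, , 2] <- c(0, 0, 0); fr[ib, , 2] <- c(3, 4, 0)
  tr <- trajectory(m, fr, 1)
  ms <- compute_metric_series(tr, distance_criterion())
  expect_equal(ms$values[1], 0)
  expect_equal(ms$values[2], 5)
  expect_length(ms$values, 3L)
})

test_that("zero-noise synthetic series equals the anchor ground truth", {
  g <- toy_geometry()
  p <- synthetic_params(k_act = 0.05, k_deact = 0.05, noise_sigma_A = 0,
                        n_frames = 40, seed = 5, start_state = "active",
                        geometry = g)
  sim <- simulate_state_sequence(p)
  ms <- compute_metric_series(sim$trajectory, distance_criterion())
  expect_equal(unique(round(ms$values[sim$states], 6)), 4.0)
  msr <- compute_metric_series(sim$trajectory, rmsd_criterion(), g$topology)
  expect_equal(msr$values[sim$states], rep(0, sum(sim$states)),
               tolerance = 1e-9)
  expect_true(all(msr$values[!sim$states] > 19))  # >> 1.9 A cutoff
})

test_that("classify_frames uses strict below-cutoff with deterministic ties", {
  ms <- metric_series(c(3, 5, 4, 6, 2))
  st <- classify_frames(ms, distance_criterion(cutoff_A = 4.6))
  expect_identical(st$active, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(classify_frames(metric_series(c(4.6, 4.6)), 4.6)$active,
                   c(FALSE, FALSE))  # tie -> inactive
  expect_false(any(classify_frames(metric_series(c(5, 6, 7)), 4.6)$active))
  # classification ignores frame-interval metadata
  ms2 <- metric_series(c(3, 5, 4, 6, 2), frame_interval_ns = 42)
  expect_identical(classify_frames(ms2, 4.6)$active, st$active)
})

test_that("occupancy, dwell times and reached_active agree with hand counts", {
  st <- flags_series(c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(occupancy(st), 60)
  expect_equal(occupancy(flags_series(rep(TRUE, 4))), 100)
  expect_equal(occupancy(flags_series(rep(FALSE, 4))), 0)
  expect_equal(dwell_times(flags_series(c(TRUE, TRUE, FALSE, TRUE, FALSE))),
               c(2, 1))
  expect_equal(dwell_times(flags_series(rep(FALSE, 5))), numeric(0))
  expect_equal(dwell_times(flags_series(c(TRUE, TRUE, FALSE), dt = 0.5)),
               1.0)
  expect_false(reached_active(flags_series(rep(FALSE, 1000))))
  expect_true(reached_active(flags_series(c(rep(FALSE, 999), TRUE))))
})

test_that("dwell-time conservation holds exactly on random series (property)", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(50:1000, 1)
    dt <- runif(1, 0.1, 2)
    flags <- runif(n) < runif(1)
    st <- flags_series(flags, dt = dt)
    # brute-force run scanner oracle
    runs <- numeric(0); cur <- 0
    for (k in seq_len(n)) {
      if (flags[k]) cur <- cur + 1
      if ((!flags[k] || k == n) && cur > 0) { runs <- c(runs, cur); cur <- 0 }
    }
    expect_equal(dwell_times(st), runs * dt)
    expect_equal(sum(dwell_times(st)), occupancy(st) / 100 * n * dt,
                 tolerance = 1e-12)
    expect_identical(reached_active(st), occupancy(st) > 0)
  }
})

test_that("occupancy is non-decreasing in the cutoff (monotonicity)", {
  set.seed(88)
  for (i in 1:20) {
    vals <- metric_series(rexp(200, rate = 0.3))
    cuts <- sort(runif(8, 0, 10))
    occ <- vapply(cuts, function(cc) occupancy(classify_frames(vals, cc)),
                  numeric(1))
    expect_true(all(diff(occ) >= 0))
  }
})

test_that("skew-normal machinery: closed-form mean and parameter recovery", {
  expect_equal(skewnorm_mean(1.5, 0.5, 4),
               1.5 + 0.5 * (4 / sqrt(17)) * sqrt(2 / pi), tolerance = 1e-12)
  set.seed(19)
  v <- rskewnorm(2e4, 1.5, 0.5, 4)
  fit <- fit_skew_normal_cutoff(v, 0.1)
  expect_equal(fit$derived_mean,
               skewnorm_mean(fit$xi, fit$omega, fit$alpha), tolerance = 1e-9)
  expect_equal(fit$derived_mean, skewnorm_mean(1.5, 0.5, 4), tolerance = 0.03)
  # symmetric limit reduces to a Gaussian
  set.seed(20)
  fits <- fit_skew_normal_cutoff(rnorm(2e4, 2.0, 0.3), 0.1)
  expect_equal(fits$derived_mean, 2.0, tolerance = 0.02)
})

test_that("alpha forced to 0 equals a plain Gaussian fit on the histogram", {
  set.seed(21)
  v <- rnorm(5000, 2, 0.3)
  f0 <- fit_skew_normal_cutoff(v, 0.1, force_alpha = 0)
  expect_equal(f0$alpha, 0)
  expect_equal(f0$derived_mean, f0$xi)  # mean == location when alpha = 0
  expect_equal(f0$derived_mean, 2, tolerance = 0.03)
})

test_that("right-tailed mixture pushes the fitted mean above the mode", {
  set.seed(22)
  # 95% tight mode at 1.7 A plus a contiguous 5% right tail, the shape an
  # RMSD histogram takes when excursions away from the reference are rare
  v <- c(rnorm(9500, 1.7, 0.15), 1.7 + rexp(500, rate = 2))
  fit <- fit_skew_normal_cutoff(v, 0.1)
  expect_gt(fit$derived_mean, 1.7)
  expect_gt(fit$alpha, 0)
})

test_that("skew fit input validation", {
  expect_error(fit_skew_normal_cutoff(rnorm(50)), "at least 100")
  expect_error(fit_skew_normal_cutoff(rep(1.5, 200)), "degenerate")
  expect_error(fit_skew_normal_cutoff(rnorm(200), bin_width_A = 0), "positive")
})

test_that("series TSV export is stable and complete", {
  ms <- metric_series(c(3, 5, 2), frame_interval_ns = 2)
  st <- classify_frames(ms, 4.6)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_series_tsv(ms, st, f)
  df <- read.delim(f)
  expect_equal(names(df), c("frame", "time_ns", "value_A", "active"))
  expect_equal(df$active, c(1L, 0L, 1L))
  expect_equal(df$time_ns, c(0, 2, 4))
})
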