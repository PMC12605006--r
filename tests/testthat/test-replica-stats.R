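test_that("summarize_system collects frequencies and reached counts", {
  all_off <- lapply(1:15, function(r) flags_series(rep(FALSE, 100), rep = r))
  s <- summarize_system(all_off)
  expect_equal(s$frequencies_pct, rep(0, 15))
  expect_equal(s$n_reached, 0L)

  # 6 of 15 replicas with at least one active frame (reached-table fixture)
  series <- lapply(1:15, function(r) {
    flags <- rep(FALSE, 100)
    if (r <= 6) flags[sample(100, sample(1:30, 1))] <- TRUE
    flags_series(flags, rep = r)
  })
  s6 <- summarize_system(series)
  expect_equal(s6$n_reached, 6L)
  expect_equal(s6$n_reached, sum(s6$frequencies_pct > 0))

  expect_error(summarize_system(list(flags_series(c(TRUE), label = "a"),
                                     flags_series(c(TRUE), label = "b"))),
               "mixed")
})

test_that("n_reached equals count(frequencies > 0) over random fixtures", {
  set.seed(55)
  for (i in 1:20) {
    series <- lapply(1:10, function(r) {
      flags_series(runif(50) < runif(1, 0, 0.2), rep = r)
    })
    s <- summarize_system(series)
    expect_equal(s$n_reached, sum(s$frequencies_pct > 0))
    expect_equal(s$pooled_frame_pct, mean(s$frequencies_pct))  # equal lengths
  }
})

test_that("Mann-Whitney exact path matches hand enumeration and wilcox.test", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2 * 1/20 over C(6,3) arrangements
  expect_equal(r$method, "exact_enumeration")

  set.seed(66)
  for (i in 1:20) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    a <- rnorm(n); b <- rnorm(m)
    ours <- mann_whitney_u(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = TRUE, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney handles ties and large n via the approximation", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)
  set.seed(67)
  a <- rnorm(15); b <- rnorm(15) + 1
  ours <- mann_whitney_u(a, b)
  expect_equal(ours$method, "normal_approx_cc")  # min(n, m) = 15 > 8
  a2 <- round(rnorm(15), 1); b2 <- round(rnorm(15) + 1, 1)
  ours2 <- mann_whitney_u(a2, b2)
  ref2 <- suppressWarnings(wilcox.test(a2, b2, exact = FALSE, correct = TRUE))
  expect_equal(ours2$p_value, ref2$p.value, tolerance = 1e-10)
  # two-sided p symmetric under group swap
  expect_equal(mann_whitney_u(b2, a2)$p_value, ours2$p_value)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("indicator t test reproduces the published worked example", {
  r1 <- indicator_t_test(15, 6, 15, 1, "one_sided")
  expect_equal(round(r1$p_value, 3), 0.016)
  r2 <- indicator_t_test(15, 4, 15, 1, "one_sided")
  expect_equal(round(r2$p_value, 3), 0.076)
  r3 <- indicator_t_test(15, 5, 15, 5, "one_sided")
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 0.5)
  expect_equal(r1$df, 28)
  expect_error(indicator_t_test(15, 0, 15, 0), "degenerate")
  expect_error(indicator_t_test(15, 16, 15, 1), "0 <= k <= n")
  expect_error(indicator_t_test(1, 0, 15, 1), "at least 2")
})

test_that("indicator t equals a generic pooled t on expanded 0/1 vectors", {
  for (k_a in c(0, 1, 4, 6, 8, 15)) {
    for (k_b in c(0, 1, 5, 15)) {
      va <- c(rep(1, k_a), rep(0, 15 - k_a))
      vb <- c(rep(1, k_b), rep(0, 15 - k_b))
      if (var(va) == 0 && var(vb) == 0) {
        expect_error(indicator_t_test(15, k_a, 15, k_b), "degenerate")
        next
      }
      ours <- indicator_t_test(15, k_a, 15, k_b, "one_sided")
      ref <- t.test(va, vb, var.equal = TRUE, alternative = "greater")
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
      two <- indicator_t_test(15, k_a, 15, k_b, "two_sided")
      ref2 <- t.test(va, vb, var.equal = TRUE)
      expect_equal(two$p_value, ref2$p.value, tolerance = 1e-12)
    }
  }
})

test_that("star mapping is a pure threshold function", {
  expect_equal(significance_stars(c(0.2, 0.05, 0.01, 0.001, 1e-4, 1e-6)),
               c("n.s.", "*", "**", "***", "****", "****"))
})

test_that("compare_systems emits both tests with stars", {
  set.seed(91)
  mk <- function(p, label) {
    summarize_system(lapply(1:15, function(r) {
      flags_series(runif(200) < p, label = label, rep = r)
    }))
  }
  a <- mk(0.25, "wt"); b <- mk(0.01, "variant")
  cmp <- compare_systems(a, b)
  expect_named(cmp, c("mann_whitney", "indicator_t", "pair"))
  expect_lte(cmp$mann_whitney$p_value, 0.05)
  expect_true(cmp$mann_whitney$stars != "n.s.")

  # identical summaries -> everything non-significant
  same <- mk(0.15, "x")
  cmp2 <- compare_systems(same, same)
  expect_equal(cmp2$mann_whitney$p_value, 1.0)
  expect_equal(cmp2$mann_whitney$stars, "n.s.")
  expect_equal(cmp2$indicator_t$stars, "n.s.")
})
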