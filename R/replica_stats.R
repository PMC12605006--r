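# Replica-level aggregation and significance tests: two-sided Mann-Whitney U
# on per-replica occupancy frequencies, and a one-sided pooled Student's t
# on reached-active indicators (0/1 per replica).

#' Summarize replicas of one system
#'
#' @param series_list list of `h12_state_series`, one per replica, sharing
#'   the same system label
#' @return An `h12_system_summary`: label, replica count, per-replica
#'   occupancy frequencies (percent), number of replicas that reached the
#'   active state, per-replica dwell-time lists, and the pooled-frame
#'   occupancy percentage (frames pooled over replicas).
#' @export
summarize_system <- function(series_list) {
  if (length(series_list) < 1L) stop("need at least one replica", call. = FALSE)
  labels <- unique(vapply(series_list, function(s) s$system_label, character(1)))
  if (length(labels) > 1L) {
    stop("replicas carry mixed system labels: ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  summaries <- lapply(series_list, replica_summary)
  freqs <- vapply(summaries, function(s) s$frequency_pct, numeric(1))
  reached <- vapply(summaries, function(s) s$reached_active, logical(1))
  n_active <- sum(vapply(series_list, function(s) sum(s$active), numeric(1)))
  n_total <- sum(vapply(series_list, function(s) length(s$active), numeric(1)))
  structure(list(system_label = labels,
                 n_replicas = length(series_list),
                 replica_indices = vapply(summaries, function(s) s$replica_index, integer(1)),
                 frequencies_pct = freqs,
                 n_reached = sum(reached),
                 reached = reached,
                 dwell_times_ns = lapply(summaries, function(s) s$dwell_times_ns),
                 pooled_frame_pct = 100 * n_active / n_total,
                 mean_frequency_pct = mean(freqs)),
            class = "h12_system_summary")
}

#' @export
print.h12_system_summary <- function(x, ...) {
  cat(sprintf("<h12_system_summary: %s, N = %d, mean occupancy %.2f%% (pooled %.2f%%), reached %d/%d>\n",
              x$system_label, x$n_replicas, x$mean_frequency_pct,
              x$pooled_frame_pct, x$n_reached, x$n_replicas))
  invisible(x)
}

# Exact null distribution of the Mann-Whitney U statistic (no ties):
# counts[u+1] = number of rank arrangements with statistic u, by the
# standard recurrence f(i, j, u) = f(i-1, j, u-j) + f(i, j-1, u) over group
# sizes i, j (sums to choose(n + m, n)).
mw_null_counts <- function(n, m) {
  prev_row <- vector("list", m + 1L)
  for (j in 0:m) prev_row[[j + 1L]] <- 1  # f(0, j, 0) = 1
  for (i in seq_len(n)) {
    row <- vector("list", m + 1L)
    row[[1L]] <- 1                        # f(i, 0, 0) = 1
    for (j in seq_len(m)) {
      umax <- i * j
      a <- prev_row[[j + 1L]]             # f(i-1, j, .), length (i-1)*j + 1
      b <- row[[j]]                       # f(i, j-1, .), length i*(j-1) + 1
      f <- numeric(umax + 1L)
      ia <- seq_along(a) + j              # u = j .. j + (i-1)*j
      f[ia] <- a
      f[seq_along(b)] <- f[seq_along(b)] + b
      row[[j + 1L]] <- f
    }
    prev_row <- row
  }
  prev_row[[m + 1L]]
}

#' Two-sided Mann-Whitney U test
#'
#' U counts, over all cross pairs, the times a value of `a` exceeds one of
#' `b` (ties count 1/2). For small samples (min(n, m) <= `exact_max`) with
#' no ties the two-sided p-value is exact, from full enumeration of the null
#' distribution of U; otherwise the normal approximation with tie correction
#' (and, by default, continuity correction) is used, which is the regime for
#' the 15-vs-15 replica comparisons.
#'
#' @param a,b numeric vectors (per-replica occupancy frequencies)
#' @param exact_max largest min-group-size handled exactly (no ties only)
#' @param continuity apply continuity correction in the normal approximation
#' @return An `h12_test_result` with `test_name`, `sidedness`, `statistic`
#'   (U of group a), `p_value`, `group_sizes`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 8, continuity = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a); m <- length(b)
  if (n < 1 || m < 1) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && min(n, m) <= exact_max) {
    counts <- mw_null_counts(n, m)
    total <- sum(counts)
    cdf_lo <- sum(counts[seq_len(u_a + 1)]) / total         # P(U <= u)
    cdf_hi <- sum(counts[(u_a + 1):(n * m + 1)]) / total     # P(U >= u)
    p <- min(1, 2 * min(cdf_lo, cdf_hi))
    method <- "exact_enumeration"
  } else {
    mu <- n * m / 2
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1))
    sigma2 <- n * m / 12 * ((n + m + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1; z <- 0
    } else {
      dev <- abs(u_a - mu)
      if (continuity) dev <- max(dev - 0.5, 0)
      z <- dev / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- if (continuity) "normal_approx_cc" else "normal_approx"
  }
  structure(list(test_name = "mann_whitney_two_sided", sidedness = "two_sided",
                 statistic = u_a, p_value = p, group_sizes = c(n, m),
                 method = method),
            class = "h12_test_result")
}

#' One- or two-sided pooled t test on reached-state indicators
#'
#' Expands the reached counts into 0/1 indicator vectors (k ones, n - k
#' zeros per group) and applies the classical two-sample Student's t test
#' with pooled variance, df = n_a + n_b - 2. One-sided direction is
#' group a greater than group b (the hypothesis that the wild type reaches
#' the active state more often than the variant). With reached counts of
#' 6/15 vs 1/15 this reproduces p = 0.016, and 4/15 vs 1/15 gives p = 0.076
#' (Welch's variant would give 0.017 / 0.077 and is deliberately not used).
#'
#' @param n_a,k_a group a: number of replicas, number that reached
#' @param n_b,k_b group b likewise
#' @param sidedness `"one_sided"` (a > b) or `"two_sided"`
#' @return An `h12_test_result`.
#' @export
indicator_t_test <- function(n_a, k_a, n_b, k_b,
                             sidedness = c("one_sided", "two_sided")) {
  sidedness <- match.arg(sidedness)
  if (n_a < 2 || n_b < 2) stop("each group needs at least 2 replicas", call. = FALSE)
  if (k_a < 0 || k_a > n_a || k_b < 0 || k_b > n_b) {
    stop("reached counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  pa <- k_a / n_a; pb <- k_b / n_b
  ss_a <- k_a * (1 - pa)^2 + (n_a - k_a) * pa^2
  ss_b <- k_b * (1 - pb)^2 + (n_b - k_b) * pb^2
  df <- n_a + n_b - 2
  s2 <- (ss_a + ss_b) / df
  if (s2 <= 0) {
    stop("degenerate indicator t test: zero pooled variance (all indicators constant)",
         call. = FALSE)
  }
  t_stat <- (pa - pb) / sqrt(s2 * (1 / n_a + 1 / n_b))
  p <- if (sidedness == "one_sided") {
    stats::pt(t_stat, df, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  }
  structure(list(test_name = "student_t_pooled", sidedness = sidedness,
                 statistic = t_stat, p_value = p, df = df,
                 group_sizes = c(n_a, n_b), reached = c(k_a, k_b),
                 method = "pooled_indicator_t"),
            class = "h12_test_result")
}

#' @export
print.h12_test_result <- function(x, ...) {
  cat(sprintf("<%s (%s): statistic = %.4f, p = %.4g (%s) n = %d,%d>\n",
              x$test_name, x$sidedness, x$statistic, x$p_value,
              significance_stars(x$p_value), x$group_sizes[1], x$group_sizes[2]))
  invisible(x)
}

#' Map a p-value to significance stars
#'
#' Thresholds: `n.s.` above 0.05, `*` at p <= 0.05, `**` at 0.01,
#' `***` at 0.001, `****` at 0.0001.
#'
#' @param p p-value in `[0, 1]`
#' @return character annotation
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (pp <= 1e-4) "****" else if (pp <= 1e-3) "***"
    else if (pp <= 1e-2) "**" else if (pp <= 0.05) "*" else "n.s."
  }, character(1))
}

#' Compare two system summaries
#'
#' Emits both replica-level tests: the two-sided Mann-Whitney U on
#' per-replica occupancy frequencies (the boxplot comparison) and the
#' one-sided indicator t test on reached-active counts (the
#' reached-state-table comparison), with star annotations.
#'
#' @param summary_a,summary_b `h12_system_summary` objects; the one-sided
#'   t-test direction is a > b
#' @param continuity continuity correction for the Mann-Whitney
#'   approximation path
#' @return list of two `h12_test_result`s (`mann_whitney`, `indicator_t`),
#'   each carrying a `stars` field.
#' @export
compare_systems <- function(summary_a, summary_b, continuity = TRUE) {
  stopifnot(inherits(summary_a, "h12_system_summary"),
            inherits(summary_b, "h12_system_summary"))
  mw <- mann_whitney_u(summary_a$frequencies_pct, summary_b$frequencies_pct,
                       continuity = continuity)
  tt <- tryCatch(
    indicator_t_test(summary_a$n_replicas, summary_a$n_reached,
                     summary_b$n_replicas, summary_b$n_reached,
                     sidedness = "one_sided"),
    error = function(e) {
      structure(list(test_name = "student_t_pooled", sidedness = "one_sided",
                     statistic = NA_real_, p_value = NA_real_,
                     group_sizes = c(summary_a$n_replicas, summary_b$n_replicas),
                     reached = c(summary_a$n_reached, summary_b$n_reached),
                     method = "degenerate", note = conditionMessage(e)),
                class = "h12_test_result")
    })
  mw$stars <- significance_stars(mw$p_value)
  tt$stars <- if (is.na(tt$p_value)) "n.s." else significance_stars(tt$p_value)
  list(mann_whitney = mw, indicator_t = tt,
       pair = c(summary_a$system_label, summary_b$system_label))
}
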