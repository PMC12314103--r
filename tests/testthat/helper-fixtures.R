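# Shared fixtures and independent oracles.

# Track built directly from coordinate vectors, unsmoothed by default.
make_kin <- function(x, y, fps = 30, valid = rep(TRUE, length(x)),
                     window = 1) {
  tr <- tip_track(seq_along(x) - 1L, x, y, valid = valid, fps = fps)
  segment_and_smooth(tr, window = window, polyorder = 0)
}

# Analytic minimum-jerk reach sampled at n frames over `duration` s.
sample_min_jerk <- function(d = 100, duration = 1, n = 1000) {
  tau <- seq(0, 1, length.out = n)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  list(x = d * s, y = rep(0, n), fps = (n - 1) / duration)
}

# Independent AUC oracle: mean over all (good, poor) pairs of
# [s_g > s_p] + 0.5 [s_g == s_p].
pairwise_auc <- function(scores, labels) {
  g <- scores[labels == "good"]
  p <- scores[labels == "poor"]
  tot <- 0
  for (a in g) for (b in p) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(g) * length(p))
}

# Independent permutation enumerator (recursive, unrelated to the
# package's internal generator).
enumerate_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in enumerate_perms(n - 1L))
    for (pos in seq_len(n)) out[[length(out) + 1L]] <- append(sub, n, pos - 1L)
  out
}

# Exhaustive two-sided permutation p-value for Spearman rho.
brute_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  rhos <- vapply(enumerate_perms(length(y)),
                 function(idx) cor(rx, ry[idx]), numeric(1))
  mean(abs(rhos) >= obs - 1e-12)
}

# Small deterministic rubric table: n surgeons, 2 trials, 3 raters.
make_rubric <- function(scores_by_surgeon) {
  cats <- rubric_categories()
  rows <- list()
  for (s in names(scores_by_surgeon)) {
    for (tr in c("T1", "T2")) for (r in c("R1", "R2", "R3")) {
      sc <- as.list(setNames(rep(scores_by_surgeon[[s]], 9), cats))
      rows[[length(rows) + 1L]] <- tibble::tibble(surgeon = s, trial = tr,
                                                  rater = r, !!!sc)
    }
  }
  dplyr::bind_rows(rows)
}

# Long cohort table from a named list of per-surgeon values for a single
# parameter cell, plus filler cells so screening has >= 1 row.
make_cohort <- function(values, metric = "pd", hand = "right",
                        phase = "All") {
  out <- tibble::tibble(surgeon = names(values), metric = metric,
                        hand = hand, phase = phase,
                        value = unname(values))
  class(out) <- c("cohort_table", class(out))
  out
}

reference_screen_path <- function() {
  system.file("extdata", "reference_screen_pvalues.csv",
              package = "microskill")
}

# The published cohort's 14 rubric totals, in surgeon order.
published_totals <- c(42.0, 43.7, 41.7, 43.3, 42.3, 39.0, 30.3, 26.0, 24.3,
                      24.7, 22.7, 17.7, 29.3, 24.0)
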