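# Per-locus Cox screens, Kaplan-Meier/log-rank and gain-frequency
# arithmetic.

sim_surv_clinical <- function(n, x, loghr, seed, base_rate = 0.08,
                              censor_max = 12) {
  # covariates and event times on a stream disjoint from the one that
  # generated x, so the locus stays independent of the adjustment set
  cl <- toy_clinical(n, seed = seed + 10000)
  set.seed(seed + 20000)
  t_event <- rexp(n, base_rate * exp(loghr * x))
  t_cens <- runif(n, 0, censor_max)
  cl$met_time <- pmax(pmin(t_event, t_cens), 1e-6)
  cl$met_event <- as.integer(t_event <= t_cens)
  cl
}

test_that("the Cox screen recovers a planted hazard and centers nulls at 1", {
  set.seed(50)
  n <- 250
  x <- 0.5 * rbinom(n, 1, 0.3) + rnorm(n, sd = 0.1)
  cl <- sim_surv_clinical(n, x, loghr = 1.6, seed = 50)
  L <- 60
  Y <- cbind(x, matrix(rnorm(n * (L - 1), sd = 0.2), n))
  colnames(Y) <- c("hazard", sprintf("null%02d", 1:(L - 1)))
  res <- cox_screen(lm_from_values(Y), cl, outcome = "metastasis")
  expect_equal(which.min(res$p), 1L)
  expect_lt(res$q[1], 0.1)
  # null log hazard ratios center on zero
  expect_lt(abs(mean(res$loghr[-1], na.rm = TRUE)), 0.2)
  expect_equal(res$hr, exp(res$loghr))
})

test_that("the Cox coefficient is invariant to time rescaling", {
  set.seed(51)
  n <- 150
  x <- rnorm(n)
  cl <- sim_surv_clinical(n, x, loghr = 0.7, seed = 51)
  m <- lm_from_values(matrix(x, ncol = 1))
  r1 <- cox_screen(m, cl, outcome = "metastasis")
  cl2 <- cl
  cl2$met_time <- cl$met_time * 365.25
  r2 <- cox_screen(m, cl2, outcome = "metastasis")
  expect_equal(r1$loghr, r2$loghr, tolerance = 1e-6)
})

test_that("constant predictors give NA rows; too few events abort", {
  cl <- toy_clinical(40)
  Y <- cbind(rep(1, 40), rnorm(40))
  res <- cox_screen(lm_from_values(Y), cl, outcome = "bcr")
  expect_true(is.na(res$loghr[1]))
  expect_false(is.na(res$loghr[2]))
  cl$bcr_event <- c(1, rep(0, 39))
  expect_error(cox_screen(lm_from_values(Y), cl, outcome = "bcr"),
               "insufficient events")
})

test_that("log-rank equals the hand-computed observed-minus-expected tally", {
  # small two-group toy with hand-checkable event times
  cl <- data.frame(
    sample_id = sprintf("s%02d", 1:10),
    group = "groupA",
    met_time = c(1, 2, 3, 4, 5, 2, 4, 5, 6, 8),
    met_event = c(1, 1, 0, 1, 1, 1, 1, 0, 1, 1),
    stringsAsFactors = FALSE)
  gain <- setNames(rep(c(FALSE, TRUE), each = 5), cl$sample_id)
  res <- km_logrank(gain, cl, outcome = "metastasis")
  # manual tally over distinct event times
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(cl$met_time[cl$met_event == 1]))) {
    at_risk <- cl$met_time >= t
    n_j <- sum(at_risk)
    n1 <- sum(at_risk & gain)
    d <- sum(cl$met_time == t & cl$met_event == 1)
    d1 <- sum(cl$met_time == t & cl$met_event == 1 & gain)
    o_minus_e <- o_minus_e + d1 - d * n1 / n_j
    if (n_j > 1)
      v <- v + d * (n1 / n_j) * (1 - n1 / n_j) * (n_j - d) / (n_j - 1)
  }
  expect_equal(res$chisq, o_minus_e^2 / v, tolerance = 1e-10)
  expect_equal(res$df, 1L)
})

test_that("identical strata give log-rank 0 and p = 1", {
  cl <- data.frame(sample_id = sprintf("s%02d", 1:8), group = "groupA",
                   met_time = rep(c(1, 2, 3, 4), 2),
                   met_event = rep(c(1, 1, 0, 1), 2),
                   stringsAsFactors = FALSE)
  gain <- setNames(rep(c(TRUE, FALSE), each = 4), cl$sample_id)
  res <- km_logrank(gain, cl, outcome = "metastasis")
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
})

test_that("strongly separated strata are detected; curves are valid KM steps", {
  set.seed(52)
  n <- 60
  gain <- setNames(rep(c(TRUE, FALSE), each = n / 2),
                   sprintf("s%03d", 1:n))
  cl <- toy_clinical(n, seed = 52)
  cl$met_time <- ifelse(gain, rexp(n, 1) + 0.01, 10)
  cl$met_event <- as.integer(gain)   # events only in the gain stratum
  res <- km_logrank(gain, cl, outcome = "metastasis")
  expect_lt(res$p, 0.05)
  for (st in unique(res$curves$stratum)) {
    s <- res$curves$survival[res$curves$stratum == st]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(max(s), 1)
  }
  expect_error(km_logrank(setNames(rep(TRUE, n), names(gain)), cl,
                          outcome = "metastasis"), "non-empty")
})

test_that("gain frequency arithmetic matches the printed example", {
  calls <- matrix("neutral", 282, 1, dimnames = list(sprintf("s%03d", 1:282),
                                                     "MYC_like"))
  calls[1:54, 1] <- "gain"
  f <- frequency_of_gain(calls, "MYC_like")
  expect_equal(f$n_gain, 54)
  expect_equal(f$n_total, 282)
  expect_equal(f$pct, 19)
  calls[, 1] <- "neutral"
  expect_equal(frequency_of_gain(calls, "MYC_like")$pct, 0)
  calls[, 1] <- "gain"
  expect_equal(frequency_of_gain(calls, "MYC_like")$pct, 100)
})

test_that("PGA survival models detect a PGA-driven hazard", {
  set.seed(53)
  n <- 200
  pga_vals <- rexp(n, 0.2)
  cl <- sim_surv_clinical(n, pga_vals, loghr = 0.3, seed = 53)
  pga <- data.frame(sample_id = cl$sample_id, pga_total = pga_vals,
                    pga_gain = pga_vals, pga_loss = 0,
                    n_altered_segments = 1L, excluded = FALSE,
                    stringsAsFactors = FALSE)
  res <- pga_survival(pga, cl, outcome = "metastasis")
  expect_gt(res$loghr, 0)
  expect_lt(res$p, 0.01)
  resq <- pga_survival(pga, cl, outcome = "metastasis", quartiles = TRUE)
  expect_gt(resq$loghr, 0)
})
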