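# EM mixture fitting, segment state calling and percent genome altered.

test_that("EM recovers the generating mixture on 10,000 draws", {
  seg <- mixture_draws(10000, means = c(-0.5, 0, 0.5), sds = 0.08,
                       weights = c(0.1, 0.8, 0.1), seed = 4)
  fit <- fit_mixture(seg, weighting = "none")
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_lt(max(abs(fit$means - c(-0.5, 0, 0.5))), 0.02)
  expect_lt(max(abs(fit$weights - c(0.1, 0.8, 0.1))), 0.02)
  # log-likelihood never decreases along the EM trace
  expect_true(all(diff(fit$loglik) >= -1e-7))
})

test_that("EM agrees with an independent mixture fitter", {
  seg <- mixture_draws(4000, seed = 6)
  fit <- fit_mixture(seg, weighting = "none")
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  mc <- mclust::Mclust(seg$seg_mean, G = 3, modelNames = "V",
                       verbose = FALSE)
  expect_lt(max(abs(sort(mc$parameters$mean) - fit$means)), 0.01)
  expect_lt(abs(mc$loglik - max(fit$loglik)), 1)
})

test_that("symmetric two-point data puts the outer components at the points", {
  seg <- segments_from_means(rep(c(-1, 1), each = 50))
  fit <- fit_mixture(seg)
  expect_lt(abs(fit$means[["loss"]] + 1), 1e-3)
  expect_lt(abs(fit$means[["gain"]] - 1), 1e-3)
  expect_lt(fit$weights[["neutral"]], 0.05)
})

test_that("constant data is flagged degenerate, not an error", {
  seg <- segments_from_means(rep(0, 100))
  fit <- fit_mixture(seg)
  expect_true(fit$degenerate)
})

test_that("fewer than 30 segments is an error", {
  expect_error(fit_mixture(segments_from_means(rnorm(10))), "at least 30")
})

test_that("hard calls equal the brute-force weighted-density argmax", {
  seg <- mixture_draws(500, seed = 12)
  fit <- fit_mixture(seg, weighting = "none")
  calls <- call_segments(seg, fit)
  # oracle: evaluate the three weighted normal densities directly
  for (i in sample(500, 100)) {
    d <- fit$weights * dnorm(seg$seg_mean[i], fit$means, fit$sds)
    lab <- c("loss", "neutral", "gain")[which.max(d)]
    expect_identical(calls$state[i], lab)
  }
  expect_equal(calls$post_loss + calls$post_neutral + calls$post_gain,
               rep(1, 500))
})

test_that("a segment at the neutral mean is called neutral; ties go neutral", {
  fit <- structure(list(weights = c(loss = 0.25, neutral = 0.25,
                                    gain = 0.5),
                        means = c(loss = -0.5, neutral = 0, gain = 0.5),
                        sds = c(loss = 0.1, neutral = 0.1, gain = 0.1),
                        loglik = 0, n_iter = 1L, converged = TRUE,
                        degenerate = FALSE, weighting = "none"),
                   class = "mixture_fit")
  at_mean <- call_segments(segments_from_means(0), fit)
  expect_identical(at_mean$state, "neutral")
  # equidistant between neutral and gain with equal weights and sds
  fit$weights <- c(loss = 1 / 3, neutral = 1 / 3, gain = 1 / 3)
  tie <- call_segments(segments_from_means(0.25), fit)
  expect_identical(tie$state, "neutral")
})

test_that("PGA arithmetic is exact on hand-built calls", {
  g <- toy_genome()  # 250 Mb total
  calls <- data.frame(
    sample_id = c("s1", "s1", "s1", "s2", "s2"),
    chrom = c("chr1", "chr2", "chr2", "chr1", "chr3"),
    start = c(0, 0, 30e6, 0, 0),
    end = c(25e6, 10e6, 40e6, 50e6, 5e6),
    n_bins = 1L,
    seg_mean = c(0.6, -0.5, 0, 0, 0),
    state = c("gain", "loss", "neutral", "neutral", "neutral"),
    stringsAsFactors = FALSE)
  pga <- compute_pga(calls, g)
  s1 <- pga[pga$sample_id == "s1", ]
  expect_equal(s1$pga_gain, 10)           # 25 Mb / 250 Mb
  expect_equal(s1$pga_loss, 4)            # 10 Mb / 250 Mb
  expect_equal(s1$pga_total, 14)
  expect_equal(s1$n_altered_segments, 2L)
  expect_false(s1$excluded)
  s2 <- pga[pga$sample_id == "s2", ]
  expect_equal(s2$pga_total, 0)
  expect_true(s2$excluded)
})

test_that("single gain covering 10% of the genome gives PGA 10/10/0", {
  g <- toy_genome()
  calls <- data.frame(sample_id = "s1", chrom = "chr1", start = 0, end = 25e6,
                      n_bins = 1L, seg_mean = 0.7, state = "gain",
                      stringsAsFactors = FALSE)
  pga <- compute_pga(calls, g)
  expect_equal(c(pga$pga_total, pga$pga_gain, pga$pga_loss), c(10, 10, 0))
})

test_that("coordinates outside the genome are rejected", {
  calls <- data.frame(sample_id = "s1", chrom = "chr1", start = 0, end = 51e6,
                      n_bins = 1L, seg_mean = 0, state = "neutral",
                      stringsAsFactors = FALSE)
  expect_error(compute_pga(calls, toy_genome()), "outside genome bounds")
})

test_that("negating all segment means swaps gain and loss exactly", {
  cfg <- sim_config(n_tumor_groupA = 20, n_tumor_groupB = 20,
                    n_normal_groupA = 0, n_normal_groupB = 0,
                    mixture_truth = list(
                      means = c(loss = -0.5, neutral = 0, gain = 0.5),
                      sds = c(0.08, 0.08, 0.08),
                      weights = c(0.1, 0.8, 0.1)),
                    n_null_loci = 0, seed = 9)
  sim <- simulate_cohort(cfg)
  g <- toy_genome()
  fit1 <- fit_mixture(sim$segments)
  pga1 <- compute_pga(call_segments(sim$segments, fit1), g)
  neg <- sim$segments
  neg$seg_mean <- -neg$seg_mean
  fit2 <- fit_mixture(neg)
  pga2 <- compute_pga(call_segments(neg, fit2), g)
  expect_equal(fit2$means[["loss"]], -fit1$means[["gain"]])
  expect_equal(fit2$weights[["loss"]], fit1$weights[["gain"]])
  expect_identical(pga1$pga_gain, pga2$pga_loss)
  expect_identical(pga1$pga_loss, pga2$pga_gain)
  expect_identical(pga1$pga_total, pga2$pga_total)
})

test_that("estimated PGA tracks planted PGA on simulated cohorts", {
  errs <- numeric(5)
  for (s in 1:5) {
    cfg <- sim_config(n_tumor_groupA = 25, n_tumor_groupB = 25,
                      n_normal_groupA = 0, n_normal_groupB = 0,
                      mixture_truth = list(
                        means = c(loss = -0.5, neutral = 0, gain = 0.5),
                        sds = c(0.08, 0.08, 0.08),
                        weights = c(0.1, 0.8, 0.1)),
                      n_null_loci = 0, noise_sd = 0.1, seed = 100 + s)
    sim <- simulate_cohort(cfg)
    fit <- fit_mixture(sim$segments)
    pga <- compute_pga(call_segments(sim$segments, fit), toy_genome())
    m <- merge(pga, sim$truth$pga, by = "sample_id")
    errs[s] <- mean(abs(m$pga_total - m$pga_true))
  }
  expect_lt(mean(errs), 1)
})
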