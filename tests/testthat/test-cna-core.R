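# Bin normalization, recursive binary segmentation and gene-level
# summarization.

make_bins <- function(values, chrom = "chr1", width = 1000,
                      col = "log2_ratio") {
  n <- length(values)
  df <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * width,
                   end = seq_len(n) * width, stringsAsFactors = FALSE)
  df[[col]] <- values
  df
}

test_that("normalization returns log2 quotient, median-centered", {
  ref <- make_bins(rep(100, 50), col = "intensity")
  # identity: tumor equals reference everywhere
  out <- normalize_to_reference(ref, ref)
  expect_true(all(out$log2_ratio == 0))
  # doubling on the last 10 bins leaves the majority at 0, the arm at +1
  tum <- ref
  tum$intensity[41:50] <- 200
  out <- normalize_to_reference(tum, ref)
  expect_equal(unname(out$log2_ratio[1:40]), rep(0, 40))
  expect_equal(unname(out$log2_ratio[41:50]), rep(1, 10))
  # random positive bins against the direct arithmetic oracle
  set.seed(9)
  tum$intensity <- rlnorm(50, 4, 0.3)
  ref2 <- ref
  ref2$intensity <- rlnorm(50, 4, 0.3)
  out <- normalize_to_reference(tum, ref2)
  lr <- log2(tum$intensity / ref2$intensity)
  expect_equal(out$log2_ratio, lr - median(lr))
  # mismatched grids are rejected
  expect_error(normalize_to_reference(tum[-1, ], ref2), "grids differ")
})

test_that("constant tracks yield one segment per chromosome", {
  tr <- rbind(make_bins(rep(0.3, 40), chrom = "chr1"),
              make_bins(rep(-0.1, 7), chrom = "chr2"))
  seg <- segment_bins(tr, min_bins = 5, alpha = 0.01)
  expect_equal(nrow(seg), 2)
  expect_equal(sort(seg$seg_mean), c(-0.1, 0.3))
  expect_equal(seg$n_bins[seg$chrom == "chr1"], 40L)
})

test_that("a clean step is split exactly at the change point", {
  tr <- make_bins(c(rep(0, 50), rep(1, 50)))
  seg <- segment_bins(tr, min_bins = 5, alpha = 0.01)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$seg_mean, c(0, 1))
  expect_equal(seg$end[1], 50 * 1000)
})

test_that("segmentation matches a naive exhaustive recursion", {
  # independent oracle: O(n^2) loop over all splits, plain means and
  # Welch statistic recomputed from scratch, recursing on accepted splits
  naive_best <- function(x, min_bins) {
    n <- length(x)
    best <- NULL
    for (k in min_bins:(n - min_bins)) {
      a <- x[1:k]; b <- x[(k + 1):n]
      v1 <- var(a) / k; v2 <- var(b) / (n - k)
      se2 <- max(v1 + v2, .Machine$double.eps)
      t <- (mean(a) - mean(b)) / sqrt(se2)
      if (is.null(best) || abs(t) > abs(best$t)) best <- list(k = k, t = t)
    }
    if (is.null(best)) return(NULL)
    df <- max(se2_df <- {
      va <- var(x[1:best$k]); vb <- var(x[(best$k + 1):n])
      n1 <- best$k; n2 <- n - best$k
      s2 <- va / n1 + vb / n2
      s2^2 / (va^2 / (n1^2 * (n1 - 1)) + vb^2 / (n2^2 * (n2 - 1)))
    }, 1)
    best$p <- 2 * pt(-abs(best$t), df)
    best
  }
  naive_segment <- function(x, min_bins, alpha) {
    if (length(x) < 2 * min_bins) return(length(x))
    sp <- naive_best(x, min_bins)
    if (is.null(sp) || !(sp$p < alpha)) return(length(x))
    c(naive_segment(x[1:sp$k], min_bins, alpha),
      naive_segment(x[(sp$k + 1):length(x)], min_bins, alpha))
  }
  set.seed(14)
  for (rep in 1:5) {
    x <- rnorm(80, 0, 0.1) + rep(c(0, 0.8, -0.5), times = c(30, 25, 25))
    seg <- segment_bins(make_bins(x), min_bins = 5, alpha = 0.01)
    expect_equal(seg$n_bins, as.integer(naive_segment(x, 5, 0.01)))
  }
})

test_that("noisy change points land within 2 bins of truth almost always", {
  set.seed(77)
  hits <- 0L
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    x <- rnorm(300, 0, 0.1) + rep(c(0, 1, 0), times = c(100, 100, 100))
    seg <- segment_bins(make_bins(x), min_bins = 5, alpha = 0.01)
    ends <- seg$end / 1000
    ok <- any(abs(ends - 100) <= 2) && any(abs(ends - 200) <= 2)
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("segment means conserve the overall bin mean", {
  set.seed(31)
  x <- rnorm(200, 0, 0.2) + rep(c(0, 0.6), each = 100)
  seg <- segment_bins(make_bins(x), min_bins = 5, alpha = 0.01)
  expect_equal(sum(seg$seg_mean * seg$n_bins) / sum(seg$n_bins), mean(x))
})

test_that("locus summarization is a length-weighted overlap mean", {
  seg <- data.frame(sample_id = "s1", chrom = "chr1",
                    start = c(0, 1000), end = c(1000, 2000),
                    n_bins = c(10L, 10L), seg_mean = c(0, 1),
                    stringsAsFactors = FALSE)
  ann <- data.frame(locus_id = c("inside", "straddle", "nohit"),
                    chrom = c("chr1", "chr1", "chr2"),
                    start = c(100, 500, 0), end = c(400, 1500, 100),
                    stringsAsFactors = FALSE)
  lm <- summarize_loci(seg, ann)
  expect_equal(unname(lm$values["s1", "inside"]), 0)
  expect_equal(unname(lm$values["s1", "straddle"]), 0.5)
  expect_true(is.na(lm$values["s1", "nohit"]))
  # locus wholly inside a single segment takes its mean
  seg2 <- seg; seg2$seg_mean <- c(0.4, 0.4)
  expect_equal(unname(summarize_loci(seg2, ann[1, ])$values[1, 1]), 0.4)
})

test_that("locus summarization matches brute-force interval integration", {
  set.seed(8)
  # random non-overlapping segments for two samples
  mk_sample <- function(sid) {
    cuts <- sort(sample(1:999, 20)) * 100
    bounds <- c(0, cuts, 1e5)
    data.frame(sample_id = sid, chrom = "chr1",
               start = bounds[-length(bounds)], end = bounds[-1],
               n_bins = 1L, seg_mean = rnorm(length(bounds) - 1),
               stringsAsFactors = FALSE)
  }
  seg <- rbind(mk_sample("s1"), mk_sample("s2"))
  st <- sample(0:(1e5 - 500), 300)
  ann <- data.frame(locus_id = sprintf("L%03d", 1:300), chrom = "chr1",
                    start = st, end = st + sample(100:5000, 300, TRUE),
                    stringsAsFactors = FALSE)
  lm <- summarize_loci(seg, ann)
  for (sid in c("s1", "s2")) {
    ss <- seg[seg$sample_id == sid, ]
    for (i in sample(300, 40)) {
      ov <- pmin(ss$end, ann$end[i]) - pmax(ss$start, ann$start[i])
      w <- pmax(ov, 0)
      want <- if (sum(w) > 0) sum(w * ss$seg_mean) / sum(w) else NA_real_
      expect_equal(unname(lm$values[sid, ann$locus_id[i]]), want)
    }
  }
})

test_that("splitting a segment at constant mean leaves locus values unchanged", {
  seg <- data.frame(sample_id = "s1", chrom = "chr1", start = 0, end = 2000,
                    n_bins = 20L, seg_mean = 0.7, stringsAsFactors = FALSE)
  split <- data.frame(sample_id = "s1", chrom = "chr1",
                      start = c(0, 800), end = c(800, 2000),
                      n_bins = c(8L, 12L), seg_mean = c(0.7, 0.7),
                      stringsAsFactors = FALSE)
  ann <- data.frame(locus_id = c("a", "b"), chrom = "chr1",
                    start = c(100, 700), end = c(900, 1800),
                    stringsAsFactors = FALSE)
  expect_equal(summarize_loci(seg, ann)$values,
               summarize_loci(split, ann)$values)
})

test_that("annotation chromosomes absent from the genome are rejected", {
  seg <- segments_from_means(c(0.1, 0.2))
  ann <- data.frame(locus_id = "x", chrom = "chrX", start = 0, end = 10,
                    stringsAsFactors = FALSE)
  expect_error(summarize_loci(seg, ann, genome = toy_genome()), "absent")
})
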