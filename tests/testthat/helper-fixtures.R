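# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A segment table from a vector of means: unit-length segments laid end
# to end on one chromosome for one sample (n_bins = 1 each).
segments_from_means <- function(means, sample_id = "s1", chrom = "chr1",
                                len = 1) {
  n <- length(means)
  data.frame(sample_id = sample_id, chrom = chrom,
             start = (seq_len(n) - 1) * len, end = seq_len(n) * len,
             n_bins = 1L, seg_mean = means, stringsAsFactors = FALSE)
}

# Draws from a known 3-component mixture, as a segment table.
mixture_draws <- function(n, means = c(-0.5, 0, 0.5), sds = 0.08,
                          weights = c(0.1, 0.8, 0.1), seed = 1) {
  set.seed(seed)
  sds <- rep(sds, length.out = 3)
  k <- sample(1:3, n, replace = TRUE, prob = weights)
  segments_from_means(rnorm(n, means[k], sds[k]))
}

# Minimal clinical table with all modeled covariates and outcomes.
toy_clinical <- function(n, seed = 1, two_groups = TRUE) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    group = if (two_groups) rep(c("groupA", "groupB"), length.out = n)
            else rep("groupA", n),
    ancestry_fraction = runif(n),
    age = rnorm(n, 60, 7),
    psa = rlnorm(n, 2, 0.5),
    grade_group = sample(1:5, n, replace = TRUE),
    bcr_time = rexp(n, 0.1) + 0.01,
    bcr_event = rbinom(n, 1, 0.4),
    met_time = rexp(n, 0.05) + 0.01,
    met_event = rbinom(n, 1, 0.3),
    stringsAsFactors = FALSE
  )
}

# A locus_matrix straight from a values matrix, with dummy coordinates.
lm_from_values <- function(values) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("L%04d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%03d", seq_len(nrow(values)))
  loci <- data.frame(locus_id = colnames(values), chrom = "chr1",
                     start = (seq_len(ncol(values)) - 1) * 1000,
                     end = seq_len(ncol(values)) * 1000,
                     stringsAsFactors = FALSE)
  locus_matrix(values, loci)
}

# Independent Benjamini-Hochberg step-up, written longhand as an oracle.
bh_by_hand <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
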