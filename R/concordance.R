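#' Per-locus correlation between two copy number matrices
#'
#' Cross-platform validation utility: for every locus shared between two
#' matrices, the rank correlation of its values across the shared samples
#' is computed, Benjamini-Hochberg adjusted across loci, and summarized as
#' the count (and percentage) of loci that are both significant and
#' positively correlated.
#'
#' @param a,b [locus_matrix()] objects sharing samples and loci.
#' @param threshold FDR threshold for the summary count (default 0.05).
#' @return List with `table` (per-locus `locus_id`, `rho`, `p`, `q`),
#'   `n_loci`, `n_concordant` (q < threshold and rho > 0) and `pct`
#'   (rounded to the nearest integer).
#' @export
per_locus_correlation <- function(a, b, threshold = 0.05) {
  stopifnot(inherits(a, "locus_matrix"), inherits(b, "locus_matrix"))
  loci <- intersect(colnames(a$values), colnames(b$values))
  samples <- intersect(rownames(a$values), rownames(b$values))
  if (length(samples) < 3) stop("need at least 3 shared samples")
  if (!length(loci)) stop("no shared loci")
  A <- a$values[samples, loci, drop = FALSE]
  B <- b$values[samples, loci, drop = FALSE]
  res <- t(vapply(seq_along(loci), function(i) {
    x <- A[, i]; y <- B[, i]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  }, numeric(2)))
  tab <- data.frame(locus_id = loci, rho = res[, 1], p = res[, 2],
                    q = bh_adjust(res[, 2]), stringsAsFactors = FALSE)
  n_conc <- sum(!is.na(tab$q) & tab$q < threshold & tab$rho > 0)
  list(table = tab, n_loci = length(loci), n_concordant = n_conc,
       pct = round(100 * n_conc / length(loci)))
}

#' Correspondence-at-the-top curve
#'
#' Measures agreement between two rankings of the same locus universe:
#' for every k, the proportion of loci shared between the top k of both
#' lists. Lists are ranked by descending absolute value by default
#' (agreement for the largest-magnitude copy number changes), or by the
#' signed value; ties are broken by locus id for determinism.
#'
#' @param scores_a,scores_b Named numeric vectors over the identical locus
#'   universe (names are locus ids).
#' @param ranking `"absolute"` (default) or `"signed"`.
#' @return Data frame with columns `k` (1..N) and `concordance`.
#' @export
cat_curve <- function(scores_a, scores_b,
                      ranking = c("absolute", "signed")) {
  ranking <- match.arg(ranking)
  if (is.null(names(scores_a)) || is.null(names(scores_b)))
    stop("score vectors must be named by locus id")
  if (!setequal(names(scores_a), names(scores_b)) ||
      length(scores_a) != length(scores_b))
    stop("the two score vectors must cover the identical locus universe")
  key <- function(s) if (ranking == "absolute") abs(s) else s
  rank_of <- function(s) {
    ord <- order(-key(s), names(s), method = "radix")
    stats::setNames(seq_along(s), names(s)[ord])
  }
  ra <- rank_of(scores_a)
  rb <- rank_of(scores_b)[names(ra)]
  n <- length(ra)
  # |top-k(A) n top-k(B)| = #{i : max(rank_a, rank_b) <= k}
  m <- pmax(ra, rb)
  inter <- cumsum(tabulate(m, nbins = n))
  data.frame(k = seq_len(n), concordance = inter / seq_len(n))
}
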