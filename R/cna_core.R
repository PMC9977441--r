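#' Normalize tumor bin intensities against a pooled reference
#'
#' Converts raw per-bin intensities into log2 copy ratios against the
#' per-bin mean of a pooled normal cohort, then median-centers each sample
#' so that the copy-neutral majority of the genome sits at 0.
#'
#' @param tumor_bins Data frame with `chrom`, `start`, `end` and a positive
#'   `intensity` column for one sample.
#' @param reference_bins Data frame on the identical bin grid with a
#'   positive `intensity` column holding the pooled-normal per-bin means.
#' @param sample_id Sample identifier attached to the output track.
#' @return A bin track data frame (`sample_id`, `chrom`, `start`, `end`,
#'   `log2_ratio`) sorted by position.
#' @export
normalize_to_reference <- function(tumor_bins, reference_bins,
                                   sample_id = "sample") {
  tumor_bins <- validate_bins(tumor_bins, value_col = "intensity")
  reference_bins <- validate_bins(reference_bins, value_col = "intensity")
  same_grid <- identical(tumor_bins$chrom, reference_bins$chrom) &&
    identical(as.numeric(tumor_bins$start), as.numeric(reference_bins$start)) &&
    identical(as.numeric(tumor_bins$end), as.numeric(reference_bins$end))
  if (!same_grid) stop("tumor and reference bin grids differ")
  if (any(!is.finite(reference_bins$intensity)) ||
      any(reference_bins$intensity <= 0))
    stop("reference intensities must be finite and strictly positive")
  if (any(!is.finite(tumor_bins$intensity)) || any(tumor_bins$intensity <= 0))
    stop("tumor intensities must be finite and strictly positive")
  lr <- log2(tumor_bins$intensity / reference_bins$intensity)
  lr <- lr - stats::median(lr)
  data.frame(
    sample_id = sample_id,
    chrom = tumor_bins$chrom,
    start = tumor_bins$start,
    end = tumor_bins$end,
    log2_ratio = lr,
    stringsAsFactors = FALSE
  )
}

# Best single split of x by the Welch two-sample statistic. Returns the
# split index k (left = 1..k) with its two-sided normal-theory p-value,
# honouring the min_bins margin. NULL when no admissible split exists.
best_split <- function(x, min_bins) {
  n <- length(x)
  if (n < 2L * min_bins) return(NULL)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  k <- seq.int(min_bins, n - min_bins)
  n1 <- k
  n2 <- n - k
  m1 <- cs[k] / n1
  m2 <- (cs[n] - cs[k]) / n2
  ss1 <- cs2[k] - n1 * m1^2
  ss2 <- (cs2[n] - cs2[k]) - n2 * m2^2
  v1 <- ss1 / pmax(n1 - 1, 1)
  v2 <- ss2 / pmax(n2 - 1, 1)
  se2 <- v1 / n1 + v2 / n2
  se2 <- pmax(se2, .Machine$double.eps)
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / pmax(v1^2 / (n1^2 * pmax(n1 - 1, 1)) +
                       v2^2 / (n2^2 * pmax(n2 - 1, 1)),
                     .Machine$double.eps)
  df <- pmax(df, 1)
  best <- which.max(abs(tstat))
  p <- 2 * stats::pt(-abs(tstat[best]), df = df[best])
  # a perfectly clean break has zero within-side variance: force acceptance
  # (guarding against floating dust on constant tracks)
  scale <- max(1, abs(m1[best]), abs(m2[best]))
  if (se2[best] <= .Machine$double.eps &&
      abs(m1[best] - m2[best]) > 1e-9 * scale) p <- 0
  list(k = k[best], p = p)
}

segment_one_chrom <- function(x, min_bins, alpha) {
  n <- length(x)
  boundaries <- c(0L, n)
  # iterative stack-based recursion over (lo, hi] intervals
  todo <- list(c(0L, n))
  while (length(todo)) {
    iv <- todo[[length(todo)]]
    todo[[length(todo)]] <- NULL
    lo <- iv[1]; hi <- iv[2]
    sp <- best_split(x[(lo + 1L):hi], min_bins)
    if (!is.null(sp) && sp$p < alpha) {
      cut <- lo + sp$k
      boundaries <- c(boundaries, cut)
      todo <- c(todo, list(c(lo, cut)), list(c(cut, hi)))
    }
  }
  sort(unique(boundaries))
}

#' Segment a bin-level log2 ratio track
#'
#' Recursive binary segmentation: each chromosome is recursively split at
#' the bin boundary maximizing a Welch-type two-sample statistic; a split
#' is accepted when its normal-theory p-value falls below `alpha` and both
#' sides retain at least `min_bins` bins. Chromosomes with fewer than
#' `2 * min_bins` bins yield a single segment. The procedure is fully
#' deterministic given its inputs.
#'
#' @param track Bin track data frame (`sample_id`, `chrom`, `start`, `end`,
#'   `log2_ratio`), e.g. from [normalize_to_reference()].
#' @param min_bins Minimum bins per segment (default 5, must be >= 2).
#' @param alpha Split acceptance threshold on the p-value (default 0.01).
#' @return A segment table (`sample_id`, `chrom`, `start`, `end`, `n_bins`,
#'   `seg_mean`).
#' @export
segment_bins <- function(track, min_bins = 5, alpha = 0.01) {
  if (min_bins < 2) stop("min_bins must be >= 2")
  track <- validate_bins(track)
  if (!"sample_id" %in% names(track)) track$sample_id <- "sample"
  out <- list()
  for (sid in unique(track$sample_id)) {
    tr <- track[track$sample_id == sid, , drop = FALSE]
    for (ch in unique(tr$chrom)) {
      b <- tr[tr$chrom == ch, , drop = FALSE]
      cuts <- segment_one_chrom(b$log2_ratio, min_bins, alpha)
      nseg <- length(cuts) - 1L
      idx_lo <- cuts[-length(cuts)] + 1L
      idx_hi <- cuts[-1]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid,
        chrom = ch,
        start = b$start[idx_lo],
        end = b$end[idx_hi],
        n_bins = idx_hi - idx_lo + 1L,
        seg_mean = vapply(seq_len(nseg), function(i)
          mean(b$log2_ratio[idx_lo[i]:idx_hi[i]]), numeric(1)),
        stringsAsFactors = FALSE
      )
    }
  }
  validate_segments(do.call(rbind, out))
}

#' Summarize segments (or bins) to gene-level copy number
#'
#' Projects per-sample segment means onto an annotation of loci: each
#' locus value is the overlap-length-weighted mean of the segment means
#' intersecting it; loci with no overlapping segment are `NA` for that
#' sample.
#'
#' @param segments Segment table; bin tracks work too after renaming
#'   `log2_ratio` to `seg_mean` and adding `n_bins = 1`.
#' @param annotation Data frame of loci (`locus_id`, `chrom`, `start`,
#'   `end`), 0-based half-open, e.g. from [read_bed()].
#' @param genome Optional [genome_model()]; when supplied, annotation
#'   chromosomes absent from the genome raise an error.
#' @return A [locus_matrix()] of samples x loci.
#' @export
summarize_loci <- function(segments, annotation, genome = NULL) {
  segments <- validate_segments(segments)
  if (!"locus_id" %in% names(annotation))
    annotation$locus_id <- paste0(annotation$chrom, ":", annotation$start,
                                  "-", annotation$end)
  if (!is.null(genome)) {
    bad <- setdiff(unique(annotation$chrom), genome$chrom_names)
    if (length(bad))
      stop("annotation chromosomes absent from genome model: ",
           paste(bad, collapse = ", "))
  }
  samples <- unique(segments$sample_id)
  values <- matrix(NA_real_, length(samples), nrow(annotation),
                   dimnames = list(samples, annotation$locus_id))
  # GRanges are 1-based closed; shift starts by +1 on the way in
  gr_loci <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1, annotation$end))
  gr_seg <- GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(segments$start + 1, segments$end))
  hits <- GenomicRanges::findOverlaps(gr_seg, gr_loci)
  if (length(hits)) {
    si <- S4Vectors::queryHits(hits)
    li <- S4Vectors::subjectHits(hits)
    w <- GenomicRanges::width(IRanges::pintersect(gr_seg[si], gr_loci[li]))
    row <- match(segments$sample_id[si], samples)
    cell <- (li - 1L) * length(samples) + row
    num <- rowsum(w * segments$seg_mean[si], cell)
    den <- rowsum(w, cell)
    idx <- as.integer(rownames(num))
    values[idx] <- num / den
  }
  locus_matrix(values, annotation)
}
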