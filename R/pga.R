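#' Percent genome altered per sample
#'
#' Sums the lengths of segments called gained and lost separately for each
#' sample and divides by the whole genome size, expressed in percent
#' (0-100). Samples with no altered segment are reported with PGA 0 and
#' flagged `excluded`; the flag marks them for omission from downstream
#' PGA-based correlations and survival models, mirroring the usual
#' practice of dropping samples without any called segmental alteration.
#'
#' @param calls Segment table with a `state` column, from
#'   [call_segments()].
#' @param genome A [genome_model()]; its `total_size` is the PGA
#'   denominator.
#' @return Data frame with one row per sample: `sample_id`, `pga_total`,
#'   `pga_gain`, `pga_loss`, `n_altered_segments`, `excluded`.
#' @export
compute_pga <- function(calls, genome) {
  calls <- validate_segments(calls)
  if (!"state" %in% names(calls))
    stop("calls must carry a 'state' column; run call_segments() first")
  stopifnot(inherits(genome, "genome_model"))
  lens <- stats::setNames(genome$chrom_lengths, genome$chrom_names)
  bad <- setdiff(unique(calls$chrom), genome$chrom_names)
  if (length(bad))
    stop("segments on chromosomes absent from genome: ",
         paste(bad, collapse = ", "))
  if (any(calls$start < 0) || any(calls$end > lens[calls$chrom]))
    stop("segment coordinates outside genome bounds")
  samples <- unique(calls$sample_id)
  len <- calls$end - calls$start
  agg <- function(state) {
    sel <- calls$state == state
    s <- rowsum(len[sel], calls$sample_id[sel])
    out <- stats::setNames(rep(0, length(samples)), samples)
    out[rownames(s)] <- s[, 1]
    out
  }
  gain_bp <- agg("gain")
  loss_bp <- agg("loss")
  n_alt <- {
    sel <- calls$state != "neutral"
    s <- rowsum(rep(1L, sum(sel)), calls$sample_id[sel])
    out <- stats::setNames(rep(0L, length(samples)), samples)
    out[rownames(s)] <- s[, 1]
    out
  }
  data.frame(
    sample_id = samples,
    pga_total = 100 * (gain_bp[samples] + loss_bp[samples]) / genome$total_size,
    pga_gain = 100 * gain_bp[samples] / genome$total_size,
    pga_loss = 100 * loss_bp[samples] / genome$total_size,
    n_altered_segments = n_alt[samples],
    excluded = n_alt[samples] == 0L,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
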