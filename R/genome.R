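#' Genome model
#'
#' A minimal description of the genome over which segments and loci live:
#' ordered chromosome names, their lengths in base pairs, and the total
#' genome size used as the denominator of percent genome altered (PGA).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in base
#'   pairs. Names are the chromosome identifiers; order is kept.
#' @return An object of class `genome_model` with elements `chrom_names`,
#'   `chrom_lengths` and `total_size`.
#' @examples
#' g <- genome_model(c(chr1 = 1e6, chr2 = 2e6))
#' g$total_size
#' @export
genome_model <- function(chrom_lengths) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (anyDuplicated(names(chrom_lengths)))
    stop("duplicated chromosome names")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("all chromosome lengths must be finite and > 0")
  structure(
    list(
      chrom_names = names(chrom_lengths),
      chrom_lengths = as.numeric(stats::setNames(chrom_lengths,
                                                 names(chrom_lengths))),
      total_size = sum(as.numeric(chrom_lengths))
    ),
    class = "genome_model"
  )
}

#' Toy genome of five 50 Mb chromosomes
#'
#' Desk-scale default genome used by the synthetic cohort generator: large
#' enough to exercise multi-chromosome bookkeeping, small enough for fast
#' simulation.
#'
#' @return A [genome_model()] with chromosomes `chr1`..`chr5`, 50 Mb each.
#' @export
toy_genome <- function() {
  genome_model(stats::setNames(rep(5e7, 5), paste0("chr", 1:5)))
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_names), "chromosomes,",
      format(x$total_size, big.mark = ","), "bp total\n")
  invisible(x)
}
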