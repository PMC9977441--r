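#' Locus-level copy number matrix
#'
#' Container pairing a samples x loci matrix of continuous copy number
#' values (log2 units) with the locus annotation (BED-style, 0-based
#' half-open coordinates). Missing values (`NA`) mark loci with no
#' overlapping copy number signal for a sample.
#'
#' @param values Numeric matrix, samples in rows, loci in columns. Row
#'   names are sample ids, column names locus ids.
#' @param loci Data frame with columns `locus_id`, `chrom`, `start`, `end`
#'   matching `colnames(values)`.
#' @return An object of class `locus_matrix` with elements `values` and
#'   `loci`.
#' @export
locus_matrix <- function(values, loci) {
  stopifnot(is.matrix(values), is.data.frame(loci))
  need <- c("locus_id", "chrom", "start", "end")
  missing <- setdiff(need, names(loci))
  if (length(missing))
    stop("locus annotation is missing columns: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(loci$locus_id)) stop("duplicated locus ids")
  if (any(loci$end <= loci$start))
    stop("loci with end <= start (coordinates are 0-based half-open)")
  if (is.null(colnames(values))) colnames(values) <- loci$locus_id
  if (!identical(colnames(values), as.character(loci$locus_id)))
    stop("colnames(values) must match loci$locus_id, in order")
  if (is.null(rownames(values))) stop("values must have sample ids as rownames")
  structure(list(values = values, loci = loci), class = "locus_matrix")
}

#' @export
print.locus_matrix <- function(x, ...) {
  cat("locus_matrix:", nrow(x$values), "samples x", ncol(x$values), "loci;",
      sum(is.na(x$values)), "missing values\n")
  invisible(x)
}

#' @export
dim.locus_matrix <- function(x) dim(x$values)

#' Drop high-missingness loci and mean-impute the remainder
#'
#' Loci with more than `max_missing` proportion of missing samples are
#' removed; remaining missing values are replaced by the locus mean. This
#' keeps per-locus model design matrices full rank before genome-wide
#' screens.
#'
#' @param x A [locus_matrix()].
#' @param max_missing Maximum tolerated proportion of missing samples per
#'   locus (default 0.1).
#' @return A `locus_matrix` with no missing values.
#' @export
prepare_locus_matrix <- function(x, max_missing = 0.1) {
  stopifnot(inherits(x, "locus_matrix"))
  v <- x$values
  frac_na <- colMeans(is.na(v))
  keep <- frac_na <= max_missing
  v <- v[, keep, drop = FALSE]
  loci <- x$loci[keep, , drop = FALSE]
  nas <- which(is.na(v), arr.ind = TRUE)
  if (nrow(nas)) {
    mu <- colMeans(v, na.rm = TRUE)
    v[nas] <- mu[nas[, 2]]
  }
  locus_matrix(v, loci)
}
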