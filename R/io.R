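# File formats. Internal coordinates are uniformly 0-based half-open;
# conversions happen only here. SEG files are 1-based inclusive on disk
# (the convention of segmented copy number files), BED 0-based half-open.

#' Read / write SEG files
#'
#' SEG files are tab-delimited with header
#' `ID chrom loc.start loc.end num.mark seg.mean` and 1-based inclusive
#' coordinates; they are converted to the package's internal 0-based
#' half-open convention on the way in (and back on the way out). An
#' optional trailing `state` column (from [call_segments()]) round-trips.
#'
#' @param path File path.
#' @return `read_seg`: a segment table.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("SEG file missing columns: ", paste(missing, collapse = ", "))
  bad <- which(df$loc.end < df$loc.start)
  if (length(bad))
    stop("SEG rows with end < start at line(s): ",
         paste(bad + 1L, collapse = ", "))
  out <- data.frame(sample_id = df$ID, chrom = df$chrom,
                    start = df$loc.start - 1, end = df$loc.end,
                    n_bins = df$num.mark, seg_mean = df$seg.mean,
                    stringsAsFactors = FALSE)
  if ("state" %in% names(df)) out$state <- df$state
  validate_segments(out)
}

#' @rdname read_seg
#' @param segments Segment table (optionally with a `state` column).
#' @return `write_seg`: `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  segments <- validate_segments(segments)
  out <- data.frame(ID = segments$sample_id, chrom = segments$chrom,
                    loc.start = segments$start + 1, loc.end = segments$end,
                    num.mark = segments$n_bins, seg.mean = segments$seg_mean)
  if ("state" %in% names(segments)) out$state <- segments$state
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED locus annotation
#'
#' Headerless, tab-delimited, 0-based half-open; columns chrom, start,
#' end and (optionally) name. Unnamed rows get `chrom:start-end` ids.
#'
#' @param path File path.
#' @return Data frame with `locus_id`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED needs at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop("BED rows with end <= start at line(s): ",
         paste(bad, collapse = ", "))
  coord_id <- paste0(df$chrom, ":", df$start, "-", df$end)
  locus_id <- if (ncol(df) >= 4) as.character(df[[4]]) else coord_id
  blank <- is.na(locus_id) | !nzchar(locus_id)
  locus_id[blank] <- coord_id[blank]
  data.frame(locus_id = locus_id, chrom = df$chrom, start = df$start,
             end = df$end, stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param loci Data frame with `chrom`, `start`, `end` and optionally
#'   `locus_id`.
#' @export
write_bed <- function(loci, path) {
  cols <- loci[, c("chrom", "start", "end")]
  if ("locus_id" %in% names(loci)) cols$name <- loci$locus_id
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a clinical table
#'
#' Tab-delimited with a header; see the package vignette for the expected
#' columns (`sample_id`, `group`, `ancestry_fraction`, `age`, `psa`,
#' `grade_group`, `bcr_time`, `bcr_event`, `met_time`, `met_event`).
#'
#' @param path File path.
#' @export
read_clinical <- function(path) {
  validate_clinical(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_clinical
#' @param clinical Clinical table.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a locus matrix as TSV
#'
#' On disk: loci as rows, with leading `locus_id`, `chrom`, `start`,
#' `end` annotation columns followed by one column per sample. Missing
#' values are written as `NA`. Round-trips losslessly.
#'
#' @param path File path.
#' @export
read_locus_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("locus_id", "chrom", "start", "end")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("locus matrix file missing columns: ",
         paste(missing, collapse = ", "))
  sample_cols <- setdiff(names(df), need)
  values <- t(as.matrix(df[, sample_cols, drop = FALSE]))
  colnames(values) <- df$locus_id
  rownames(values) <- sample_cols
  locus_matrix(values, df[, need])
}

#' @rdname read_locus_matrix
#' @param x A [locus_matrix()].
#' @export
write_locus_matrix <- function(x, path) {
  stopifnot(inherits(x, "locus_matrix"))
  df <- cbind(x$loci[, c("locus_id", "chrom", "start", "end")],
              as.data.frame(t(x$values)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a screen result sorted by q-value
#'
#' @param result A screen result data frame (from [screen_group()],
#'   [screen_ancestry()] or [cox_screen()]).
#' @param path File path.
#' @export
write_screen_result <- function(result, path) {
  result <- result[order(result$q, result$p), , drop = FALSE]
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
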