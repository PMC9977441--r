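# Internal validators for the core tabular types. These are deliberately
# strict: every public entry point funnels its inputs through one of these
# so that malformed tables fail early with an informative message.

seg_cols <- c("sample_id", "chrom", "start", "end", "n_bins", "seg_mean")

validate_segments <- function(segments) {
  stopifnot(is.data.frame(segments))
  missing <- setdiff(seg_cols, names(segments))
  if (length(missing))
    stop("segment table is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(segments)) {
    if (any(!is.finite(segments$seg_mean)))
      stop("non-finite seg_mean values")
    if (any(segments$end <= segments$start))
      stop("segments with end <= start (coordinates are 0-based half-open)")
    if (any(segments$n_bins < 1))
      stop("segments with n_bins < 1")
    ord <- order(segments$sample_id, segments$chrom, segments$start)
    segments <- segments[ord, , drop = FALSE]
    key <- paste(segments$sample_id, segments$chrom)
    same <- key[-1] == key[-nrow(segments)]
    if (nrow(segments) > 1 &&
        any(same & segments$start[-1] < segments$end[-nrow(segments)]))
      stop("overlapping segments within a sample/chromosome")
    rownames(segments) <- NULL
  }
  segments
}

validate_bins <- function(bins, value_col = "log2_ratio") {
  stopifnot(is.data.frame(bins))
  need <- c("chrom", "start", "end", value_col)
  missing <- setdiff(need, names(bins))
  if (length(missing))
    stop("bin table is missing columns: ", paste(missing, collapse = ", "))
  if (any(bins$end <= bins$start))
    stop("bins with end <= start")
  ord <- order(bins$chrom, bins$start)
  bins <- bins[ord, , drop = FALSE]
  same <- bins$chrom[-1] == bins$chrom[-nrow(bins)]
  if (nrow(bins) > 1 && any(same & bins$start[-1] < bins$end[-nrow(bins)]))
    stop("overlapping bins within a chromosome")
  rownames(bins) <- NULL
  bins
}

clinical_cols <- c("sample_id", "group", "ancestry_fraction", "age", "psa",
                   "grade_group", "bcr_time", "bcr_event", "met_time",
                   "met_event")

validate_clinical <- function(clinical,
                              require = c("sample_id", "group")) {
  stopifnot(is.data.frame(clinical))
  missing <- setdiff(require, names(clinical))
  if (length(missing))
    stop("clinical table is missing columns: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(clinical$sample_id))
    stop("duplicated sample_id in clinical table")
  if ("grade_group" %in% names(clinical) &&
      any(!clinical$grade_group %in% 1:5))
    stop("grade_group must be in 1..5")
  if ("ancestry_fraction" %in% names(clinical)) {
    a <- clinical$ancestry_fraction
    if (any(!is.finite(a)) || any(a < 0 | a > 1))
      stop("ancestry_fraction must lie in [0, 1]")
  }
  clinical
}

# Gleason Grade Groups 1-2 are modelled as low-risk, 3-5 as high-risk.
grade_high <- function(grade_group) as.integer(grade_group >= 3)
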