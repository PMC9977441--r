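#' Locus set
#'
#' A set of locus ids with a provenance tag and the FDR threshold that
#' produced it, used by the germline filtering step.
#'
#' @param ids Character vector of locus ids (deduplicated, order kept).
#' @param provenance Free-text tag, e.g. `"tumor_race"`, `"tumor_ancestry"`,
#'   `"normal_germline"`.
#' @param fdr The FDR threshold used to derive the set (`NA` if not
#'   applicable).
#' @return An object of class `locus_set`.
#' @export
locus_set <- function(ids, provenance = "unspecified", fdr = NA_real_) {
  ids <- as.character(ids)
  structure(list(ids = unique(ids), provenance = provenance, fdr = fdr),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat("locus_set '", x$provenance, "': ", length(x$ids), " loci",
      if (!is.na(x$fdr)) paste0(" (FDR < ", x$fdr, ")"), "\n", sep = "")
  invisible(x)
}

#' @export
length.locus_set <- function(x) length(x$ids)

#' Derive germline copy-number-variable loci from a normal-tissue cohort
#'
#' Runs the group screen on a normal-tissue locus matrix and returns the
#' loci whose copy number differs between the two self-identified groups
#' at `q < fdr`. Copy number differences between groups observed in
#' normal tissue are taken to be germline in origin. By default no
#' clinical covariates enter the model (normal-tissue donors typically
#' lack tumor covariates such as PSA and grade).
#'
#' @param normal_matrix [locus_matrix()] for the normal-tissue cohort.
#' @param normal_clinical Clinical table with `sample_id` and `group`.
#' @param fdr FDR threshold (default 0.001, deliberately stringent so that
#'   only strongly supported germline loci are removed from tumor lists).
#' @param covariates Covariates for the screen (default none).
#' @param moderation Passed to [screen_group()].
#' @return A [locus_set()] with provenance `"normal_germline"`.
#' @export
derive_germline_set <- function(normal_matrix, normal_clinical, fdr = 0.001,
                                covariates = character(0),
                                moderation = TRUE) {
  if (fdr < 0 || fdr > 1) stop("fdr must lie in [0, 1]")
  res <- screen_group(normal_matrix, normal_clinical,
                      moderation = moderation, covariates = covariates)
  locus_set(res$locus_id[!is.na(res$q) & res$q < fdr],
            provenance = "normal_germline", fdr = fdr)
}

#' Remove germline loci from a tumor hit list
#'
#' Splits a tumor hit set into the loci retained after removing those also
#' present in the germline set, and reports the overlap arithmetic.
#' Matching is by locus id within a shared annotation universe.
#'
#' @param tumor_hits A [locus_set()] of tumor screen hits.
#' @param germline A [locus_set()] of germline loci.
#' @return List with `retained` and `removed` locus sets and a `summary`
#'   data frame (`n_input`, `n_removed`, `n_retained`, `removed_pct`;
#'   percentage rounded to the nearest integer).
#' @export
filter_germline <- function(tumor_hits, germline) {
  stopifnot(inherits(tumor_hits, "locus_set"), inherits(germline, "locus_set"))
  removed_ids <- intersect(tumor_hits$ids, germline$ids)
  retained_ids <- setdiff(tumor_hits$ids, germline$ids)
  n_in <- length(tumor_hits$ids)
  list(
    retained = locus_set(retained_ids,
                         provenance = paste0(tumor_hits$provenance,
                                             "_minus_germline"),
                         fdr = tumor_hits$fdr),
    removed = locus_set(removed_ids,
                        provenance = paste0(tumor_hits$provenance,
                                            "_germline_overlap"),
                        fdr = tumor_hits$fdr),
    summary = data.frame(
      n_input = n_in,
      n_removed = length(removed_ids),
      n_retained = length(retained_ids),
      removed_pct = if (n_in) round(100 * length(removed_ids) / n_in) else 0
    )
  )
}

#' Overlap between two locus sets
#'
#' @param a,b [locus_set()] objects over the same annotation universe.
#' @return List with `n_intersection` and `pct_of_a` (percentage of `a`'s
#'   loci also in `b`, rounded to the nearest integer).
#' @export
overlap_sets <- function(a, b) {
  stopifnot(inherits(a, "locus_set"), inherits(b, "locus_set"))
  n <- length(intersect(a$ids, b$ids))
  list(n_intersection = n,
       pct_of_a = if (length(a$ids)) round(100 * n / length(a$ids)) else 0)
}
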