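#' Reference-based cell-type deconvolution of methylation beta values
#'
#' Estimates cell-type fractions per sample by constrained least squares:
#' each sample's beta vector over the shared CpGs is approximated by a
#' non-negative combination of the signature columns summing to one. The
#' sum-to-one constraint is imposed through an augmented heavily-weighted
#' row during the non-negative least squares solve (Lawson-Hanson NNLS via
#' pracma) followed by exact renormalization, which keeps the solver
#' deterministic and dependency-light.
#'
#' @param betas Numeric matrix of beta values, CpGs in rows (rownames are
#'   CpG ids), samples in columns.
#' @param signature Numeric matrix of reference beta values, CpGs in rows,
#'   cell types in columns; entries in \[0, 1\].
#' @return An object of class `deconv_result`: `fractions` (samples x
#'   cell types, non-negative, rows summing to one) and `residual_norm`
#'   (per-sample Euclidean residual of the fit on the shared CpGs).
#' @export
deconvolve <- function(betas, signature) {
  stopifnot(is.matrix(betas), is.matrix(signature))
  if (is.null(rownames(betas)) || is.null(rownames(signature)))
    stop("betas and signature need CpG ids as rownames")
  if (any(signature < 0 | signature > 1))
    stop("signature entries must lie in [0, 1]")
  shared <- intersect(rownames(betas), rownames(signature))
  k <- ncol(signature)
  if (length(shared) < 2 * k)
    stop("need at least 2x as many shared CpGs as cell types (",
         length(shared), " shared, ", k, " types)")
  S <- signature[shared, , drop = FALSE]
  if (qr(S)$rank < k) stop("signature matrix is rank-deficient")
  B <- betas[shared, , drop = FALSE]
  lambda <- 100 * max(abs(S), 1)
  A <- rbind(S, rep(lambda, k))
  fractions <- matrix(NA_real_, ncol(B), k,
                      dimnames = list(colnames(B), colnames(signature)))
  residual_norm <- stats::setNames(numeric(ncol(B)), colnames(B))
  for (j in seq_len(ncol(B))) {
    sol <- pracma::lsqnonneg(A, c(B[, j], lambda))
    f <- sol$x
    tot <- sum(f)
    if (tot <= 0) stop("degenerate deconvolution (all-zero fractions) for ",
                       colnames(B)[j])
    f <- f / tot
    fractions[j, ] <- f
    residual_norm[j] <- sqrt(sum((S %*% f - B[, j])^2))
  }
  structure(list(fractions = fractions, residual_norm = residual_norm),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat("deconv_result:", nrow(x$fractions), "samples x", ncol(x$fractions),
      "cell types; median residual norm",
      signif(stats::median(x$residual_norm), 3), "\n")
  invisible(x)
}

#' Correlate an immune cell fraction with percent genome altered
#'
#' Spearman rank correlation (average ranks for ties) between a chosen
#' cell type's estimated fraction and per-sample PGA, overall and
#' optionally within each clinical group. Samples flagged `excluded` in
#' the PGA table (no altered segments) are dropped first.
#'
#' @param deconv A [deconvolve()] result (or a samples x cell types
#'   fraction matrix).
#' @param pga A [compute_pga()] result.
#' @param cell_type Column of the fraction matrix to correlate.
#' @param clinical Optional clinical table; when given, per-`group` strata
#'   are added.
#' @param min_n Minimum non-excluded samples required per stratum.
#' @return Data frame with one row per stratum: `stratum`, `rho`, `p`, `n`.
#' @export
correlate_with_pga <- function(deconv, pga, cell_type = "Treg",
                               clinical = NULL, min_n = 5L) {
  fr <- if (inherits(deconv, "deconv_result")) deconv$fractions else deconv
  if (!cell_type %in% colnames(fr))
    stop("cell type not found in fractions: ", cell_type)
  pga <- pga[!pga$excluded, , drop = FALSE]
  shared <- intersect(rownames(fr), pga$sample_id)
  x <- fr[shared, cell_type]
  y <- pga$pga_total[match(shared, pga$sample_id)]
  strata <- list(overall = shared)
  if (!is.null(clinical)) {
    clinical <- validate_clinical(clinical)
    for (g in levels(factor(clinical$group)))
      strata[[g]] <- intersect(shared,
                               clinical$sample_id[clinical$group == g])
  }
  one <- function(ids) {
    if (length(ids) < min_n)
      stop("fewer than ", min_n, " usable samples in a stratum")
    xi <- x[ids]; yi <- y[match(ids, shared)]
    if (stats::sd(xi) == 0 || stats::sd(yi) == 0)
      stop("correlation undefined: an input vector is constant")
    ct <- suppressWarnings(
      stats::cor.test(xi, yi, method = "spearman", exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value, n = length(ids))
  }
  res <- t(vapply(strata, one, c(rho = 0, p = 0, n = 0)))
  data.frame(stratum = rownames(res), rho = res[, "rho"], p = res[, "p"],
             n = as.integer(res[, "n"]), row.names = NULL,
             stringsAsFactors = FALSE)
}
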