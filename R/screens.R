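#' Benjamini-Hochberg adjustment
#'
#' Thin, validating wrapper around `stats::p.adjust(method = "BH")`:
#' step-up q-values, monotone and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\]; `NA` entries propagate.
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.nan(p))) stop("NaN p-values are not allowed")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

# Shared design-matrix builder for the per-locus linear screens.
# predictor: "group" (two-level factor; coefficient = groupB - groupA on
# the alphabetically second level) or "ancestry_fraction" (continuous).
build_design <- function(clinical, predictor,
                         covariates = c("age", "psa", "grade"),
                         log_psa = FALSE) {
  clinical <- validate_clinical(clinical, require = c("sample_id", predictor))
  cols <- list("(Intercept)" = rep(1, nrow(clinical)))
  if (predictor == "group") {
    g <- factor(clinical$group)
    if (nlevels(g) != 2) stop("group must have exactly two levels")
    if (min(table(g)) < 2) stop("need at least 2 samples per group")
    cols[[paste0("group", levels(g)[2])]] <- as.numeric(g == levels(g)[2])
  } else {
    cols[[predictor]] <- clinical[[predictor]]
  }
  if ("age" %in% covariates) cols$age <- clinical$age
  if ("psa" %in% covariates)
    cols$psa <- if (log_psa) log(clinical$psa) else clinical$psa
  if ("grade" %in% covariates)
    cols$grade_high <- grade_high(clinical$grade_group)
  X <- do.call(cbind, cols)
  rownames(X) <- clinical$sample_id
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design matrix (constant or collinear predictor)")
  X
}

# Ordinary (unmoderated) least-squares screen across all loci at once.
ols_screen <- function(Y, X, coef_idx) {
  n <- nrow(X); pdim <- ncol(X)
  if (n <= pdim) stop("fewer samples than model parameters")
  XtX_inv <- chol2inv(chol(crossprod(X)))
  beta <- XtX_inv %*% crossprod(X, Y)
  resid <- Y - X %*% beta
  df <- n - pdim
  s2 <- colSums(resid^2) / df
  se <- sqrt(s2 * XtX_inv[coef_idx, coef_idx])
  est <- beta[coef_idx, ]
  tstat <- est / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  list(estimate = est, se = se, statistic = tstat, p = p, df = df)
}

screen_linear <- function(matrix, clinical, predictor, moderation,
                          covariates, log_psa) {
  stopifnot(inherits(matrix, "locus_matrix"))
  matrix <- prepare_locus_matrix(matrix)
  clinical <- clinical[match(rownames(matrix$values), clinical$sample_id), ,
                       drop = FALSE]
  if (any(is.na(clinical$sample_id)))
    stop("clinical table lacks rows for some samples in the matrix")
  X <- build_design(clinical, predictor, covariates, log_psa)
  coef_idx <- 2L  # predictor of interest immediately follows the intercept
  Y <- matrix$values
  if (moderation) {
    fit <- limma::lmFit(t(Y), design = X)
    fit <- limma::eBayes(fit)
    cn <- colnames(X)[coef_idx]
    res <- list(estimate = fit$coefficients[, cn],
                se = sqrt(fit$s2.post) * fit$stdev.unscaled[, cn],
                statistic = fit$t[, cn],
                p = fit$p.value[, cn])
  } else {
    res <- ols_screen(Y, X, coef_idx)
  }
  data.frame(
    locus_id = colnames(Y),
    estimate = unname(res$estimate),
    se = unname(res$se),
    statistic = unname(res$statistic),
    p = unname(res$p),
    q = bh_adjust(unname(res$p)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Genome-wide screen of copy number against a two-level group
#'
#' Fits, locus by locus, a least-squares model of continuous copy number
#' on the group label adjusted for age, preoperative PSA and binary grade
#' (Grade Groups 1-2 low vs 3-5 high), and tests the group coefficient.
#' With `moderation = TRUE` (the default) residual variances are shrunk by
#' limma's empirical-Bayes moderation before the t-statistics are formed;
#' p-values are Benjamini-Hochberg adjusted across loci.
#'
#' @param matrix A [locus_matrix()]; loci missing in more than 10% of
#'   samples are dropped, remaining missing values mean-imputed.
#' @param clinical Clinical table with `sample_id`, `group` and the
#'   requested covariates.
#' @param moderation Use empirical-Bayes variance moderation (limma).
#' @param covariates Character subset of `c("age", "psa", "grade")`.
#' @param log_psa Enter PSA on the log scale (default: untransformed).
#' @return Screen result data frame: `locus_id`, `estimate` (log2 units,
#'   second group level minus first), `se`, `statistic`, `p`, `q`.
#' @export
screen_group <- function(matrix, clinical, moderation = TRUE,
                         covariates = c("age", "psa", "grade"),
                         log_psa = FALSE) {
  screen_linear(matrix, clinical, "group", moderation, covariates, log_psa)
}

#' Genome-wide screen of copy number against percent African ancestry
#'
#' As [screen_group()], with the continuous ancestry fraction (percent
#' African ancestry / 100) as the predictor of interest. Moderation is off
#' by default (plain per-locus GLM t-tests).
#'
#' @inheritParams screen_group
#' @return Screen result data frame; `estimate` is in log2 units per unit
#'   ancestry fraction.
#' @export
screen_ancestry <- function(matrix, clinical, moderation = FALSE,
                            covariates = c("age", "psa", "grade"),
                            log_psa = FALSE) {
  screen_linear(matrix, clinical, "ancestry_fraction", moderation,
                covariates, log_psa)
}
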