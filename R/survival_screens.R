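#' Per-locus Cox proportional hazards screen
#'
#' Fits, for every locus, a multivariable Cox model of a censored outcome
#' (biochemical recurrence or metastasis) on the continuous locus copy
#' number, adjusted for percent African ancestry, age, preoperative PSA
#' and binary grade (Grade Groups 1-2 vs 3-5). Efron tie handling; Wald
#' p-values; Benjamini-Hochberg adjustment across loci. Per-locus fitting
#' failures (non-convergence, constant predictor) yield an `NA` row and
#' never abort the screen.
#'
#' @param matrix A [locus_matrix()], or a plain one-column numeric matrix
#'   with sample rownames (e.g. a PGA vector) for single-predictor models.
#' @param clinical Clinical table with the outcome columns (`bcr_time`,
#'   `bcr_event` or `met_time`, `met_event`) and covariates.
#' @param outcome `"bcr"` or `"metastasis"`.
#' @param covariates Character subset of
#'   `c("ancestry", "age", "psa", "grade")`.
#' @param min_events Minimum number of events required (default 10).
#' @return Data frame per locus: `locus_id`, `loghr` (log hazard ratio per
#'   log2 copy unit), `se`, `hr`, `p`, `q`.
#' @export
cox_screen <- function(matrix, clinical,
                       outcome = c("bcr", "metastasis"),
                       covariates = c("ancestry", "age", "psa", "grade"),
                       min_events = 10L) {
  outcome <- match.arg(outcome)
  if (inherits(matrix, "locus_matrix")) {
    matrix <- prepare_locus_matrix(matrix)
    V <- matrix$values
  } else {
    V <- as.matrix(matrix)
    if (is.null(colnames(V))) colnames(V) <- paste0("V", seq_len(ncol(V)))
    if (is.null(rownames(V))) stop("matrix must have sample ids as rownames")
  }
  time_col <- if (outcome == "bcr") "bcr_time" else "met_time"
  event_col <- if (outcome == "bcr") "bcr_event" else "met_event"
  clinical <- validate_clinical(clinical,
                                require = c("sample_id", time_col, event_col))
  clinical <- clinical[match(rownames(V), clinical$sample_id), , drop = FALSE]
  if (any(is.na(clinical$sample_id)))
    stop("clinical table lacks rows for some samples in the matrix")
  time <- clinical[[time_col]]
  event <- as.integer(clinical[[event_col]])
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be > 0")
  if (sum(event) < min_events)
    stop("insufficient events: ", sum(event), " < ", min_events)
  covs <- list()
  if ("ancestry" %in% covariates) covs$ancestry <- clinical$ancestry_fraction
  if ("age" %in% covariates) covs$age <- clinical$age
  if ("psa" %in% covariates) covs$psa <- clinical$psa
  if ("grade" %in% covariates)
    covs$grade_high <- grade_high(clinical$grade_group)
  Z <- if (length(covs)) do.call(cbind, covs) else NULL
  surv <- survival::Surv(time, event)
  fit_one <- function(x) {
    if (stats::sd(x) == 0) return(c(NA_real_, NA_real_, NA_real_))
    X <- cbind(locus = x, Z)
    fit <- tryCatch(
      survival::coxph(surv ~ X, ties = "efron",
                      control = survival::coxph.control(iter.max = 50,
                                                        eps = 1e-8)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || is.na(stats::coef(fit)[1]))
      return(c(NA_real_, NA_real_, NA_real_))
    b <- stats::coef(fit)[1]
    s <- sqrt(diag(fit$var))[1]
    c(b, s, 2 * stats::pnorm(-abs(b / s)))
  }
  res <- t(apply(V, 2, fit_one))
  data.frame(
    locus_id = colnames(V),
    loghr = res[, 1],
    se = res[, 2],
    hr = exp(res[, 1]),
    p = res[, 3],
    q = bh_adjust(res[, 3]),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Kaplan-Meier curves and log-rank test for gain vs non-gain
#'
#' Stratifies samples by categorical gain status at one locus and compares
#' the two survival curves with the standard 1-degree-of-freedom log-rank
#' test.
#'
#' @param gain Logical vector (TRUE = gain) named by sample id, e.g.
#'   `call_loci(...)[, locus] == "gain"`.
#' @param clinical Clinical table with the outcome columns.
#' @param outcome `"bcr"` or `"metastasis"`.
#' @return List with `curves` (data frame of `stratum`, `time`, `at_risk`,
#'   `survival`), `chisq`, `df` and `p`.
#' @export
km_logrank <- function(gain, clinical, outcome = c("bcr", "metastasis")) {
  outcome <- match.arg(outcome)
  time_col <- if (outcome == "bcr") "bcr_time" else "met_time"
  event_col <- if (outcome == "bcr") "bcr_event" else "met_event"
  clinical <- validate_clinical(clinical,
                                require = c("sample_id", time_col, event_col))
  if (is.null(names(gain))) stop("gain must be named by sample id")
  gain <- gain[!is.na(gain)]
  clinical <- clinical[match(names(gain), clinical$sample_id), , drop = FALSE]
  if (any(is.na(clinical$sample_id)))
    stop("clinical table lacks rows for some samples in 'gain'")
  if (!any(gain) || all(gain)) stop("both strata must be non-empty")
  strat <- factor(ifelse(gain, "gain", "no_gain"),
                  levels = c("no_gain", "gain"))
  surv <- survival::Surv(clinical[[time_col]],
                         as.integer(clinical[[event_col]]))
  sf <- survival::survfit(surv ~ strat)
  curves <- data.frame(
    stratum = rep(sub("^strat=", "", names(sf$strata)),
                  times = sf$strata),
    time = sf$time,
    at_risk = sf$n.risk,
    survival = sf$surv,
    stringsAsFactors = FALSE
  )
  sd_fit <- survival::survdiff(surv ~ strat)
  chisq <- sd_fit$chisq
  list(curves = curves, chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Gain frequency at a locus
#'
#' @param calls Character state matrix from [call_loci()].
#' @param locus Locus id (a column of `calls`).
#' @return List with `n_gain`, `n_total` (non-missing samples) and `pct`
#'   (rounded to the nearest integer).
#' @export
frequency_of_gain <- function(calls, locus) {
  if (!locus %in% colnames(calls)) stop("locus not found: ", locus)
  st <- calls[, locus]
  st <- st[!is.na(st)]
  n_gain <- sum(st == "gain")
  list(n_gain = n_gain, n_total = length(st),
       pct = if (length(st)) round(100 * n_gain / length(st)) else 0)
}

#' Cox models of outcome on PGA
#'
#' Convenience wrapper running [cox_screen()] with per-sample PGA as a
#' one-column predictor matrix, either continuous or cut into quartiles
#' (entered as an integer score 1-4; quartile cut points are computed on
#' the modeled cohort). Samples flagged `excluded` (no altered segments)
#' are dropped.
#'
#' @param pga A [compute_pga()] result.
#' @param clinical Clinical table.
#' @param outcome `"bcr"` or `"metastasis"`.
#' @param quartiles Model PGA as quartile score instead of the continuous
#'   value.
#' @param covariates Covariates passed to [cox_screen()]; default the
#'   clinical adjustment set without ancestry.
#' @return A one-row [cox_screen()] result.
#' @export
pga_survival <- function(pga, clinical, outcome = c("bcr", "metastasis"),
                         quartiles = FALSE,
                         covariates = c("age", "psa", "grade")) {
  outcome <- match.arg(outcome)
  pga <- pga[!pga$excluded, , drop = FALSE]
  x <- pga$pga_total
  if (quartiles) {
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    x <- as.integer(cut(x, c(-Inf, qs, Inf), labels = FALSE))
  }
  m <- base::matrix(x, ncol = 1,
                    dimnames = list(pga$sample_id,
                                    if (quartiles) "pga_quartile" else "pga"))
  clinical <- clinical[clinical$sample_id %in% pga$sample_id, , drop = FALSE]
  cox_screen(m, clinical, outcome = outcome, covariates = covariates)
}
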