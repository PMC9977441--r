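#' Fit a cohort-wide 3-component Gaussian mixture to segment means
#'
#' Models the pooled distribution of segment mean log2 copy ratios across
#' the whole cohort as a mixture of three normal components representing
#' lost, copy-neutral and gained regions, fitted by
#' expectation-maximization. Components are relabeled so that
#' `mean_loss < mean_neutral < mean_gain`. Observations may be weighted by
#' the number of supporting bins (default: a segment mean's precision
#' scales with its bin count), by segment length, or not at all.
#'
#' Initialization is deterministic: component means start at the 10th,
#' 50th and 90th percentiles of the (weighted) segment means, standard
#' deviations at half the pooled SD, and weights at (0.15, 0.70, 0.15).
#' If a fit degenerates numerically it is restarted from jittered
#' quantile initializations (using `seed`), up to `max_restarts` times.
#'
#' @param segments Segment table (see [segment_bins()]).
#' @param weighting One of `"by_bins"`, `"by_length"`, `"none"`.
#' @param seed Integer seed controlling restart jitter only; the first
#'   attempt is deterministic.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param sd_floor Lower bound on component standard deviations (log2
#'   units), guarding against likelihood blow-up on near-constant data.
#' @param max_restarts Restarts attempted after a numerically failed fit.
#' @return An object of class `mixture_fit`: `weights`, `means`, `sds`
#'   (each named loss/neutral/gain), `loglik` (per-iteration trace),
#'   `n_iter`, `converged`, `degenerate` (TRUE when the components
#'   collapse onto fewer than three distinct means).
#' @export
fit_mixture <- function(segments,
                        weighting = c("by_bins", "by_length", "none"),
                        seed = 1L, tol = 1e-8, max_iter = 500L,
                        sd_floor = 1e-3, max_restarts = 5L) {
  weighting <- match.arg(weighting)
  segments <- validate_segments(segments)
  x <- segments$seg_mean
  if (length(x) < 30)
    stop("need at least 30 segments pooled cohort-wide to fit the mixture")
  w <- switch(weighting,
              by_bins = as.numeric(segments$n_bins),
              by_length = as.numeric(segments$end - segments$start),
              none = rep(1, length(x)))
  w <- w / mean(w)

  init_quantiles <- function(jitter_sd = 0) {
    q <- stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
    if (jitter_sd > 0) q <- sort(q + stats::rnorm(3, 0, jitter_sd))
    s <- stats::sd(x) / 2
    if (!is.finite(s) || s < sd_floor) s <- sd_floor
    list(pi = c(0.15, 0.70, 0.15), mu = q, sigma = rep(s, 3))
  }

  run_em <- function(init) {
    pi_k <- init$pi; mu <- init$mu; sigma <- init$sigma
    loglik <- numeric(0)
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      dens <- vapply(1:3, function(k)
        pi_k[k] * stats::dnorm(x, mu[k], sigma[k]), numeric(length(x)))
      tot <- rowSums(dens)
      if (any(!is.finite(tot)) || any(tot <= 0)) return(NULL)
      ll <- sum(w * log(tot))
      if (!is.finite(ll)) return(NULL)
      loglik <- c(loglik, ll)
      resp <- dens / tot
      wk <- colSums(w * resp)
      pi_new <- wk / sum(w)
      mu_new <- mu; sig_new <- sigma
      for (k in 1:3) {
        if (wk[k] > 1e-12) {
          mu_new[k] <- sum(w * resp[, k] * x) / wk[k]
          sig_new[k] <- sqrt(sum(w * resp[, k] * (x - mu_new[k])^2) / wk[k])
        }
        if (!is.finite(sig_new[k]) || sig_new[k] < sd_floor)
          sig_new[k] <- sd_floor
      }
      pi_k <- pi_new; mu <- mu_new; sigma <- sig_new
      n_ll <- length(loglik)
      if (n_ll >= 2) {
        rel <- abs(loglik[n_ll] - loglik[n_ll - 1]) /
          (abs(loglik[n_ll - 1]) + 1e-12)
        if (rel < tol) { converged <- TRUE; break }
      }
      if (iter >= max_iter) break
    }
    ord <- order(mu)
    list(pi = pi_k[ord], mu = mu[ord], sigma = sigma[ord],
         loglik = loglik, n_iter = iter, converged = converged)
  }

  fit <- run_em(init_quantiles())
  if (is.null(fit)) {
    set.seed(seed)
    for (r in seq_len(max_restarts)) {
      fit <- run_em(init_quantiles(jitter_sd = stats::sd(x) / 4 + sd_floor))
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      stop("mixture fit failed after ", max_restarts, " restarts")
  }

  lab <- c("loss", "neutral", "gain")
  degenerate <- min(diff(fit$mu)) < 1e-4
  structure(
    list(weights = stats::setNames(fit$pi, lab),
         means = stats::setNames(fit$mu, lab),
         sds = stats::setNames(fit$sigma, lab),
         loglik = fit$loglik,
         n_iter = fit$n_iter,
         converged = fit$converged,
         degenerate = degenerate,
         weighting = weighting),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("mixture_fit (", x$n_iter, " EM iterations, ",
      if (x$converged) "converged" else "not converged",
      if (x$degenerate) ", degenerate" else "", ")\n", sep = "")
  print(round(rbind(weight = x$weights, mean = x$means, sd = x$sds), 4))
  invisible(x)
}

# Posterior responsibilities of the three states for arbitrary values.
state_posteriors <- function(values, fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  dens <- vapply(1:3, function(k)
    fit$weights[k] * stats::dnorm(values, fit$means[k], fit$sds[k]),
    numeric(length(values)))
  dens <- matrix(dens, ncol = 3)
  tot <- rowSums(dens)
  # far in the tails all densities underflow; fall back to nearest mean
  zero <- !is.finite(tot) | tot <= 0
  if (any(zero)) {
    nearest <- apply(abs(outer(values[zero], fit$means, "-")), 1, which.min)
    dens[zero, ] <- 0
    dens[cbind(which(zero), nearest)] <- 1
    tot[zero] <- 1
  }
  post <- dens / tot
  colnames(post) <- c("loss", "neutral", "gain")
  post
}

# Hard state assignment: argmax posterior, ties broken toward neutral.
hard_state <- function(post) {
  ifelse(post[, "neutral"] >= post[, "loss"] &
           post[, "neutral"] >= post[, "gain"],
         "neutral",
         ifelse(post[, "loss"] > post[, "gain"], "loss", "gain"))
}

#' Assign each segment to a copy number state
#'
#' Computes the posterior probability of loss/neutral/gain for every
#' segment under a fitted mixture and assigns the maximum-posterior state,
#' with ties broken toward neutral.
#'
#' @param segments Segment table.
#' @param fit A [fit_mixture()] result.
#' @return The segment table with columns `post_loss`, `post_neutral`,
#'   `post_gain` and `state` appended.
#' @export
call_segments <- function(segments, fit) {
  segments <- validate_segments(segments)
  post <- state_posteriors(segments$seg_mean, fit)
  segments$post_loss <- post[, "loss"]
  segments$post_neutral <- post[, "neutral"]
  segments$post_gain <- post[, "gain"]
  segments$state <- hard_state(post)
  segments
}

#' Categorical gene-level copy number calls
#'
#' Applies the cohort mixture to locus-level continuous values, yielding a
#' samples x loci matrix of states (`"loss"`, `"neutral"`, `"gain"`; `NA`
#' where the value is missing). Used for gain/non-gain stratification in
#' Kaplan-Meier analyses.
#'
#' @param matrix A [locus_matrix()].
#' @param fit A [fit_mixture()] result.
#' @param gain_cutoff Optional fixed log2 cutoff: values above it are
#'   called gain, below its negative loss, overriding the mixture.
#' @return Character matrix of states with the same dimnames as
#'   `matrix$values`.
#' @export
call_loci <- function(matrix, fit, gain_cutoff = NULL) {
  stopifnot(inherits(matrix, "locus_matrix"))
  v <- matrix$values
  ok <- !is.na(v)
  out <- base::matrix(NA_character_, nrow(v), ncol(v), dimnames = dimnames(v))
  if (!is.null(gain_cutoff)) {
    out[ok] <- ifelse(v[ok] > gain_cutoff, "gain",
                      ifelse(v[ok] < -gain_cutoff, "loss", "neutral"))
  } else {
    post <- state_posteriors(v[ok], fit)
    out[ok] <- hard_state(post)
  }
  out
}
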