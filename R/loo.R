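#' Pointwise log-likelihood matrix of a fit
#'
#' Gaussian log density of each observation under each posterior draw of
#' its linear predictor and the residual standard deviation. Requires the
#' fit to have been run with \code{monitor_mu = TRUE}.
#'
#' @param fit A \code{cort_fit}.
#' @return Draws x observations matrix.
#' @export
pointwise_loglik <- function(fit) {
  stopifnot(inherits(fit, "cort_fit"))
  if (is.null(fit$mu))
    stop("fit was run with monitor_mu = FALSE; pointwise log-likelihoods ",
         "are unavailable")
  ll <- stats::dnorm(rep(fit$y, each = nrow(fit$mu)), mean = fit$mu,
                     sd = fit$sigma, log = TRUE)
  matrix(ll, nrow = nrow(fit$mu), ncol = length(fit$y))
}

## Generalized Pareto fit to tail exceedances (profile-likelihood grid
## estimator of Zhang & Stephens 2009, with the weak shape prior used in
## PSIS practice).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  b <- 1 / x[n] +
    (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior_bs * x[floor(n / 4 + 0.5)])
  k_of_b <- vapply(b, function(bj) -mean(log1p(-bj * x)), numeric(1L))
  l <- n * (log(b / k_of_b) + k_of_b - 1)
  w <- vapply(seq_len(m), function(j) 1 / sum(exp(l - l[j])), numeric(1L))
  b_hat <- sum(b * w)
  k_prime <- -mean(log1p(-b_hat * x))     # Zhang-Stephens shape
  sigma_hat <- k_prime / b_hat
  k_hat <- -k_prime                       # tail-shape convention (k > 0 heavy)
  k_hat <- (n * k_hat + 10 * 0.5) / (n + 10)  # shrink toward 0.5
  list(k = k_hat, sigma = sigma_hat)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

## Pareto-smoothed importance-sampling weights for one observation's
## leave-one-out importance ratios (log scale, unnormalized).
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (tail_len < 5L) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_idx <- ord[(S - tail_len + 1L):S]
  cutoff <- lw[ord[S - tail_len]]
  exc <- exp(lw[tail_idx]) - exp(cutoff)
  if (all(exc <= 0)) return(list(lw = lw, k = NA_real_))
  fit <- gpd_fit(exc)
  p <- (seq_len(tail_len) - 0.5) / tail_len
  smoothed <- log(exp(cutoff) + gpd_quantile(p, fit$k, fit$sigma))
  lw[tail_idx[order(lw[tail_idx])]] <- pmin(smoothed, 0)
  list(lw = lw, k = fit$k)
}

#' Approximate leave-one-out cross-validation by PSIS
#'
#' Estimates the expected log pointwise predictive density (elpd) by
#' Pareto-smoothed importance sampling of the leave-one-out posterior from
#' the full-data posterior draws. Observations whose importance-weight
#' tail has a generalized-Pareto shape estimate above 0.7 are flagged as
#' unreliable.
#'
#' @param fit A \code{cort_fit} with pointwise log-likelihoods available.
#' @return Object of class \code{cort_loo}: \code{elpd_loo}, \code{se},
#'   \code{p_loo}, \code{pointwise} (per-observation elpd), and
#'   \code{pareto_k}.
#' @export
loo <- function(fit) {
  ll <- pointwise_loglik(fit)
  n <- ncol(ll)
  pointwise <- numeric(n)
  k <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    lw <- sm$lw - log_sum_exp(sm$lw)
    pointwise[i] <- log_sum_exp(lw + ll[, i])
    k[i] <- sm$k
  }
  lpd <- apply(ll, 2L, function(z) log_sum_exp(z) - log(length(z)))
  out <- list(elpd_loo = sum(pointwise), se = sqrt(n * stats::var(pointwise)),
              p_loo = sum(lpd - pointwise), pointwise = pointwise,
              pareto_k = k, n = n)
  n_bad <- sum(!is.na(k) & k > 0.7)
  if (n_bad > 0L)
    warning(n_bad, " observation(s) with Pareto k > 0.7; elpd estimate ",
            "may be unreliable")
  structure(out, class = "cort_loo")
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' @export
print.cort_loo <- function(x, ...) {
  cat("PSIS-LOO: elpd =", round(x$elpd_loo, 1), "( se", round(x$se, 1),
      "), p_loo =", round(x$p_loo, 1), "\n")
  invisible(x)
}

#' Compare models by LOO expected predictive density
#'
#' Ranks fits by elpd and reports, for each, the difference to the best
#' model with the standard error of that difference computed from the
#' paired pointwise elpd contributions. All fits must be of the same
#' response rows.
#'
#' @param ... Named \code{cort_fit} or \code{cort_loo} objects.
#' @return Data frame ordered by elpd: columns model, elpd, se,
#'   elpd_diff, se_diff.
#' @export
loo_compare <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) &&
      !inherits(fits[[1L]], c("cort_fit", "cort_loo")))
    fits <- fits[[1L]]
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  loos <- lapply(fits, function(f) if (inherits(f, "cort_loo")) f else loo(f))
  ns <- vapply(loos, function(l) l$n, numeric(1L))
  if (length(unique(ns)) != 1L)
    stop("fits were computed on different numbers of observations")
  elpd <- vapply(loos, function(l) l$elpd_loo, numeric(1L))
  best <- which.max(elpd)
  diff_stats <- vapply(seq_along(loos), function(i) {
    d <- loos[[i]]$pointwise - loos[[best]]$pointwise
    c(sum(d), sqrt(length(d) * stats::var(d)))
  }, numeric(2L))
  out <- data.frame(model = names(fits), elpd = elpd,
                    se = vapply(loos, function(l) l$se, numeric(1L)),
                    elpd_diff = diff_stats[1L, ],
                    se_diff = diff_stats[2L, ], row.names = NULL)
  out[order(-out$elpd), ]
}
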