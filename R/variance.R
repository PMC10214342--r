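#' Extract per-draw variance components from a fit
#'
#' Collects, for every random-effect factor, the posterior draws of the
#' variance in each fitted reaction-norm component (the diagonal of that
#' factor's covariance matrix), together with the residual variance.
#'
#' @param fit A \code{cort_fit}.
#' @return An object of class \code{cort_vc}: list with \code{components}
#'   (named list of draws x components matrices), \code{residual} (vector
#'   of residual-variance draws) and \code{variant}.
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "cort_fit"))
  structure(list(components = fit$vc, residual = fit$sigma^2,
                 variant = fit$spec$variant),
            class = "cort_vc")
}

vc_get <- function(vc, factor_, component) {
  m <- vc$components[[factor_]]
  if (is.null(m))
    stop("fit has no '", factor_, "' random effect (variant '",
         vc$variant, "')")
  if (!component %in% colnames(m))
    stop("component '", component, "' was not fitted for factor '",
         factor_, "' (intercept-only term)")
  m[, component]
}

#' Summarize posterior draws
#'
#' Posterior median and equal-tailed 95\% credible interval. Draws that are
#' undefined (\code{NA}, e.g. a ratio with a zero denominator in that draw)
#' are dropped and counted, never treated as zero.
#'
#' @param draws Numeric vector of posterior draws.
#' @return List with \code{median}, \code{lo}, \code{hi}, \code{n_draws},
#'   \code{n_dropped}.
#' @export
summarize_draws <- function(draws) {
  if (length(draws) == 0L) stop("no draws to summarize")
  n_dropped <- sum(is.na(draws))
  draws <- draws[!is.na(draws)]
  if (length(draws) == 0L)
    return(list(median = NA_real_, lo = NA_real_, hi = NA_real_,
                n_draws = 0L, n_dropped = n_dropped))
  q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  list(median = stats::median(draws), lo = q[1L], hi = q[2L],
       n_draws = length(draws), n_dropped = n_dropped)
}

ratio_draws <- function(num, den) {
  out <- ifelse(den > 0, num / den, NA_real_)
  out
}

#' Trait repeatability of cortisol levels
#'
#' Long-term trait repeatability is the share of the total (intercept)
#' variance explained by individual identity across years,
#' \eqn{V_{individual} / V_{total}}; short-term repeatability adds the
#' within-year individual component,
#' \eqn{(V_{individual} + V_{ID\mbox{-}year}) / V_{total}}; where
#' \eqn{V_{total} = V_{individual} + V_{ID\mbox{-}year} + V_{group} +
#' V_{group\mbox{-}year}}. Computed per posterior draw, then summarized.
#'
#' @param vc A \code{cort_vc}.
#' @return List with \code{long_term} and \code{short_term} summaries (see
#'   [summarize_draws()]) and the per-draw vectors in \code{draws}.
#' @export
trait_repeatability <- function(vc) {
  stopifnot(inherits(vc, "cort_vc"))
  v_ind <- vc_get(vc, "individual", "intercept")
  v_iy <- vc_get(vc, "id_year", "intercept")
  v_g <- vc_get(vc, "group", "intercept")
  v_gy <- vc_get(vc, "group_year", "intercept")
  den <- v_ind + v_iy + v_g + v_gy
  long <- ratio_draws(v_ind, den)
  short <- ratio_draws(v_ind + v_iy, den)
  list(long_term = summarize_draws(long),
       short_term = summarize_draws(short),
       draws = list(long_term = long, short_term = short))
}

#' Reaction-norm repeatability
#'
#' The share of among-individual variance in a reaction-norm component
#' that is stable across years:
#' \eqn{V_{c,individual} / (V_{c,individual} + V_{c,ID\mbox{-}year})}.
#'
#' @param vc A \code{cort_vc}.
#' @param component \code{"intercept"}, \code{"linear"} or
#'   \code{"quadratic"}.
#' @return Summary list plus per-draw vector in \code{draws}.
#' @export
rn_repeatability <- function(vc, component = c("intercept", "linear",
                                               "quadratic")) {
  stopifnot(inherits(vc, "cort_vc"))
  component <- match.arg(component)
  v_ind <- vc_get(vc, "individual", component)
  v_iy <- vc_get(vc, "id_year", component)
  r <- ratio_draws(v_ind, v_ind + v_iy)
  c(summarize_draws(r), list(draws = r))
}

within_variance_draws <- function(vc, component, include_technical = FALSE) {
  w <- vc_get(vc, "genetic", component) +
    vc_get(vc, "mother", component) +
    vc_get(vc, "group_year", component) +
    vc_get(vc, "individual", component) +
    vc_get(vc, "id_year", component)
  if (include_technical) w <- w + vc_get(vc, "project", component)
  w
}

#' Between- versus within-community variance
#'
#' Splits the variance of a reaction-norm component into the share
#' explained by community identity,
#' \eqn{V_{group,c} / (V_{group,c} + V_{within,c})}, and its complement,
#' where the within-community variance sums the genetic, maternal,
#' group-year, individual and ID-year components. The technical project
#' term is excluded by default; \code{include_technical = TRUE} adds it to
#' the within-community sum.
#'
#' @inheritParams rn_repeatability
#' @param include_technical Include the project variance in the
#'   within-community sum.
#' @return List with \code{between_group} and \code{within_group}
#'   summaries and the per-draw vectors in \code{draws}.
#' @export
between_within_partition <- function(vc, component = c("intercept",
                                       "linear", "quadratic"),
                                     include_technical = FALSE) {
  stopifnot(inherits(vc, "cort_vc"))
  component <- match.arg(component)
  v_g <- vc_get(vc, "group", component)
  v_w <- within_variance_draws(vc, component, include_technical)
  den <- v_g + v_w
  between <- ratio_draws(v_g, den)
  list(between_group = summarize_draws(between),
       within_group = summarize_draws(1 - between),
       draws = list(between_group = between, within_group = 1 - between))
}

#' Within-community heritability and maternal effects
#'
#' Decomposes the within-community variance of a reaction-norm component
#' into the five biological shares: genetic heritability
#' \eqn{h^2 = V_{genetic,c} / V_{within,c}}, maternal effects
#' \eqn{m^2 = V_{mother,c} / V_{within,c}}, and the group-year, individual
#' and ID-year shares, which sum to one in every draw (to a sixth
#' project share when \code{include_technical = TRUE}).
#'
#' @inheritParams between_within_partition
#' @return List of summaries (\code{h2_genetic}, \code{m2_maternal},
#'   \code{p_group_year}, \code{p_individual}, \code{p_id_year}, and
#'   \code{p_project} if requested) and per-draw vectors in \code{draws}.
#' @export
within_group_heritability <- function(vc, component = c("intercept",
                                        "linear", "quadratic"),
                                      include_technical = FALSE) {
  stopifnot(inherits(vc, "cort_vc"))
  component <- match.arg(component)
  den <- within_variance_draws(vc, component, include_technical)
  shares <- list(
    h2_genetic = ratio_draws(vc_get(vc, "genetic", component), den),
    m2_maternal = ratio_draws(vc_get(vc, "mother", component), den),
    p_group_year = ratio_draws(vc_get(vc, "group_year", component), den),
    p_individual = ratio_draws(vc_get(vc, "individual", component), den),
    p_id_year = ratio_draws(vc_get(vc, "id_year", component), den))
  if (include_technical)
    shares$p_project <- ratio_draws(vc_get(vc, "project", component), den)
  out <- lapply(shares, summarize_draws)
  out$draws <- shares
  out
}

#' Trait heritability including residual variance
#'
#' For the slope-free trait model only: narrow-sense heritability with the
#' unexplained residual in the denominator,
#' \eqn{V_{genetic} / (V_{genetic} + V_{mother} + V_{group\mbox{-}year} +
#' V_{individual} + V_{ID\mbox{-}year} + V_{residual})}. Calling this on a
#' reaction-norm fit is an error, because the residual there is not
#' partitioned on the same scale as the slope components.
#'
#' @param vc A \code{cort_vc} from a \code{trait_heritability} fit.
#' @return Summary list plus per-draw vector in \code{draws}.
#' @export
trait_heritability <- function(vc) {
  stopifnot(inherits(vc, "cort_vc"))
  if (any(vapply(vc$components, ncol, integer(1L)) > 1L))
    stop("trait heritability requires the slope-free trait model; ",
         "this fit has random slopes")
  den <- vc_get(vc, "genetic", "intercept") +
    vc_get(vc, "mother", "intercept") +
    vc_get(vc, "group_year", "intercept") +
    vc_get(vc, "individual", "intercept") +
    vc_get(vc, "id_year", "intercept") + vc$residual
  h2 <- ratio_draws(vc_get(vc, "genetic", "intercept"), den)
  c(summarize_draws(h2), list(draws = h2))
}

#' Full variance decomposition of an animal-model fit
#'
#' Convenience wrapper producing every between/within and within-community
#' share for each fitted reaction-norm component, in a long table.
#'
#' @param fit A \code{cort_fit} from an animal-model variant.
#' @param include_technical Passed through to the share calculations.
#' @return Data frame with columns component, quantity, median, lo, hi.
#' @export
decompose_fit <- function(fit, include_technical = FALSE) {
  vc <- variance_components(fit)
  comps <- colnames(vc$components$genetic)
  rows <- list()
  for (c_ in comps) {
    bw <- between_within_partition(vc, c_, include_technical)
    wg <- within_group_heritability(vc, c_, include_technical)
    for (q in c("between_group", "within_group"))
      rows[[length(rows) + 1L]] <- data.frame(
        component = c_, quantity = q, median = bw[[q]]$median,
        lo = bw[[q]]$lo, hi = bw[[q]]$hi)
    for (q in setdiff(names(wg), "draws"))
      rows[[length(rows) + 1L]] <- data.frame(
        component = c_, quantity = q, median = wg[[q]]$median,
        lo = wg[[q]]$lo, hi = wg[[q]]$hi)
  }
  do.call(rbind, rows)
}
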