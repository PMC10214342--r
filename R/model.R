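#' Sampler settings for model fitting
#'
#' Defaults follow the study conditions: four chains of 4000 iterations
#' with half devoted to warm-up. Reduce for calibration experiments and
#' permutation refits.
#'
#' @param chains Number of MCMC chains.
#' @param iterations Total iterations per chain (including warm-up).
#' @param warmup Iterations per chain discarded as warm-up (adaptation plus
#'   burn-in).
#' @param seed Integer seed; chain \code{i} uses \code{seed + i}.
#' @param monitor_mu Keep per-observation posterior means (needed for
#'   pointwise log-likelihoods and LOO).
#' @param block_sampler Use JAGS's \code{glm} module, which updates the
#'   latent Gaussian field in blocks. Much better mixing for the
#'   weakly-identified variance scales of the animal models at a higher
#'   cost per iteration; single-site slice sampling (\code{FALSE}) is
#'   faster per iteration and adequate for well-identified fits.
#' @param quiet Suppress JAGS progress output.
#' @return A list of class \code{sampler_settings}.
#' @export
sampler_settings <- function(chains = 4, iterations = 4000,
                             warmup = iterations / 2, seed = 1,
                             monitor_mu = TRUE, block_sampler = TRUE,
                             quiet = TRUE) {
  stopifnot(chains >= 1, iterations > warmup, warmup >= 200)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 monitor_mu = isTRUE(monitor_mu),
                 block_sampler = isTRUE(block_sampler),
                 quiet = isTRUE(quiet)),
            class = "sampler_settings")
}

## The glm module is session-global: ensure its state matches the request.
set_block_sampler <- function(on) {
  loaded <- "glm" %in% rjags::list.modules()
  if (on && !loaded) rjags::load.module("glm", quiet = TRUE)
  if (!on && loaded) rjags::unload.module("glm", quiet = TRUE)
  invisible(on)
}

## Named model variants: for each random-effect factor, the number of
## reaction-norm dimensions (1 = intercept only, 3 = intercept + linear +
## quadratic circadian slope).
variant_random_structure <- function(variant) {
  herit3 <- c(group = 3, group_year = 3, project = 3, individual = 3,
              id_year = 3, mother = 3, genetic = 3)
  switch(variant,
    null = c(group = 1, group_year = 1, project = 1),
    intercepts = c(group = 1, group_year = 1, project = 1,
                   individual = 1, id_year = 1),
    reaction_norms = ,
    demographic_adult_male = ,
    demographic_adult_female = ,
    demographic_immature = c(group = 1, group_year = 1, project = 1,
                             individual = 3, id_year = 3),
    full_heritability = ,
    tai_heritability = ,
    dominance_heritability = herit3,
    trait_heritability = c(group = 1, group_year = 1, project = 1,
                           individual = 1, id_year = 1, mother = 1,
                           genetic = 1),
    stop("unknown model variant: ", variant))
}

standard_fixed_covariates <- function() {
  c("demographic", "age_z", "season_sin", "season_cos", "sexratio_z",
    "groupsize_z", "lcms_method")
}

variant_fixed_covariates <- function(variant) {
  base <- standard_fixed_covariates()
  switch(variant,
    demographic_adult_male = c(setdiff(base, "demographic"), "dominance"),
    demographic_adult_female = c(setdiff(base, "demographic"),
                                 "reproductive_state"),
    demographic_immature = c(setdiff(base, "demographic"), "sex"),
    dominance_heritability = c(base, "dominance"),
    base)
}

variant_subset <- function(variant) {
  switch(variant,
    tai_heritability = list(site = "Tai"),
    demographic_adult_male = list(demographic = "adult male"),
    demographic_adult_female = list(demographic = c("cycling female",
                                                    "lactating female")),
    demographic_immature = list(demographic = c("immature male",
                                                "immature female")),
    list())
}

#' Declare a hierarchical cortisol model
#'
#' Builds the declarative specification of one of the named model variants:
#' the random-intercept \code{null}, \code{intercepts} and random-slope
#' \code{reaction_norms} repeatability models, the animal models
#' (\code{full_heritability}, \code{tai_heritability},
#' \code{dominance_heritability}) with genetic and maternal reaction-norm
#' terms, the slope-free \code{trait_heritability} model, and the
#' per-demographic reaction-norm variants. Every fixed covariate enters in
#' interaction with the linear and quadratic circadian terms. Priors are
#' Normal(0, 1) on fixed effects, half-Student-t(3, 0, 10) on random-effect
#' standard deviations, and uniform LKJ(1) on random-slope correlation
#' matrices.
#'
#' @param dataset A \code{cort_data} prepared dataset.
#' @param variant Variant name; see Details.
#' @param A Additive relatedness matrix; required for the animal-model
#'   variants (those with a \code{genetic} term).
#' @param fixed_covariates Optional override of the fixed-covariate set.
#' @return An object of class \code{cort_model_spec}.
#' @export
build_model <- function(dataset, variant = c("null", "intercepts",
                          "reaction_norms", "full_heritability",
                          "tai_heritability", "dominance_heritability",
                          "trait_heritability", "demographic_adult_male",
                          "demographic_adult_female",
                          "demographic_immature"),
                        A = NULL, fixed_covariates = NULL) {
  variant <- match.arg(variant)
  random <- variant_random_structure(variant)
  fixed <- if (is.null(fixed_covariates)) variant_fixed_covariates(variant)
           else fixed_covariates
  subset <- variant_subset(variant)

  miss <- setdiff(fixed, names(dataset))
  if (length(miss) > 0L)
    stop("dataset lacks fixed-covariate column(s): ",
         paste(miss, collapse = ", "))
  factors <- setdiff(names(random), "genetic")
  miss_f <- setdiff(factors, names(dataset))
  if (length(miss_f) > 0L)
    stop("dataset lacks grouping column(s): ",
         paste(miss_f, collapse = ", "))
  if ("genetic" %in% names(random)) {
    if (is.null(A))
      stop("variant '", variant,
           "' is an animal model and requires the relatedness matrix A")
    if (!"mother" %in% names(dataset) && "mother" %in% names(random))
      stop("dataset lacks the 'mother' column (prepare with a pedigree)")
  }
  if (length(subset) > 0L && !all(names(subset) %in% names(dataset)))
    stop("dataset lacks subset column(s): ",
         paste(setdiff(names(subset), names(dataset)), collapse = ", "))

  structure(list(variant = variant, response = "y", fixed = fixed,
                 random = random, subset = subset, A = A,
                 priors = list(fixed = c(mean = 0, sd = 1),
                               sd = c(df = 3, location = 0, scale = 10),
                               lkj = 1)),
            class = "cort_model_spec")
}

#' @export
print.cort_model_spec <- function(x, ...) {
  cat("Hierarchical cortisol model spec:", x$variant, "\n")
  cat("  fixed (each x {1, t, t2}):", paste(x$fixed, collapse = ", "), "\n")
  dims <- ifelse(x$random == 3, "intercept+slopes", "intercept")
  cat("  random:",
      paste(sprintf("%s (%s)", names(x$random), dims), collapse = ", "),
      "\n")
  invisible(x)
}

## Fixed-effect design matrix: every covariate interacted with t and t2.
## Constant factor columns (single observed level) are dropped with a
## warning rather than breaking small subsets.
fixed_design <- function(dataset, covariates) {
  df <- as.data.frame(dataset)
  keep <- character(0)
  for (cv in covariates) {
    x <- df[[cv]]
    if (is.character(x)) x <- df[[cv]] <- factor(x)
    if (is.factor(x)) {
      x <- droplevels(x)
      df[[cv]] <- x
      if (nlevels(x) < 2L) {
        warning("fixed covariate '", cv,
                "' is constant in this dataset; dropped")
        next
      }
    }
    keep <- c(keep, cv)
  }
  rhs <- if (length(keep) > 0L)
    sprintf("(%s) * (t + t2)", paste(keep, collapse = " + "))
  else "t + t2"
  stats::model.matrix(stats::as.formula(paste("~", rhs)), df)
}

## Apply a spec's row subset and drop unused factor levels.
apply_spec_subset <- function(dataset, spec) {
  df <- as.data.frame(dataset)
  for (col in names(spec$subset))
    df <- df[as.character(df[[col]]) %in% spec$subset[[col]], , drop = FALSE]
  if (nrow(df) == 0L) stop("model subset removed every row")
  df
}

## --- JAGS code generation -------------------------------------------------

jags_term_code <- function(f, d, genetic) {
  if (d == 1L && !genetic) {
    ## centered parameterization: with conditional (Gibbs/slice) updates
    ## this mixes better than the non-centered form for scalar intercept
    ## terms
    sprintf("
  for (j in 1:n_%1$s) { u_%1$s[j] ~ dnorm(0, 1 / (sd_%1$s * sd_%1$s)) }
  sd_%1$s ~ dt(0, 0.01, 3) T(0,)", f)
  } else if (d == 1L && genetic) {
    sprintf("
  for (j in 1:n_%1$s) { z_%1$s[j] ~ dnorm(0, 1) }
  ug_%1$s <- cholA %%*%% z_%1$s
  for (j in 1:n_%1$s) { u_%1$s[j] <- sd_%1$s * ug_%1$s[j] }
  sd_%1$s ~ dt(0, 0.01, 3) T(0,)", f)
  } else {
    corr <- sprintf("
  for (k in 1:3) { sd_%1$s[k] ~ dt(0, 0.01, 3) T(0,) }
  b12_%1$s ~ dbeta(1.5, 1.5)
  b23_%1$s ~ dbeta(1.5, 1.5)
  b13_%1$s ~ dbeta(1, 1)
  r12_%1$s <- 2 * b12_%1$s - 1
  r23_%1$s <- 2 * b23_%1$s - 1
  p13_%1$s <- 2 * b13_%1$s - 1
  s1_%1$s <- sqrt(1 - r12_%1$s * r12_%1$s)
  s2_%1$s <- sqrt(1 - r23_%1$s * r23_%1$s)
  r13_%1$s <- p13_%1$s * s1_%1$s * s2_%1$s + r12_%1$s * r23_%1$s
  L_%1$s[1, 1] <- sd_%1$s[1]
  L_%1$s[1, 2] <- 0
  L_%1$s[1, 3] <- 0
  L_%1$s[2, 3] <- 0
  L_%1$s[2, 1] <- sd_%1$s[2] * r12_%1$s
  L_%1$s[2, 2] <- sd_%1$s[2] * s1_%1$s
  L_%1$s[3, 1] <- sd_%1$s[3] * r13_%1$s
  L_%1$s[3, 2] <- sd_%1$s[3] * (r23_%1$s * s1_%1$s - p13_%1$s * r12_%1$s * s2_%1$s)
  L_%1$s[3, 3] <- sd_%1$s[3] * s2_%1$s * sqrt(1 - p13_%1$s * p13_%1$s)", f)
    latent <- if (genetic) sprintf("
  for (j in 1:n_%1$s) { for (k in 1:3) { z_%1$s[j, k] ~ dnorm(0, 1) } }
  ug_%1$s <- cholA %%*%% z_%1$s
  for (j in 1:n_%1$s) {
    for (k in 1:3) { u_%1$s[j, k] <- inprod(L_%1$s[k, ], ug_%1$s[j, ]) }
  }", f) else sprintf("
  for (j in 1:n_%1$s) {
    for (k in 1:3) { z_%1$s[j, k] ~ dnorm(0, 1) }
    for (k in 1:3) { u_%1$s[j, k] <- inprod(L_%1$s[k, 1:k], z_%1$s[j, 1:k]) }
  }", f)
    paste0(corr, latent)
  }
}

jags_model_code <- function(random) {
  contrib <- vapply(names(random), function(f) {
    if (random[[f]] == 1L) sprintf(" + u_%1$s[idx_%1$s[i]]", f)
    else sprintf(" + inprod(u_%1$s[idx_%1$s[i], ], W[i, ])", f)
  }, character(1L))
  terms <- vapply(names(random), function(f) {
    jags_term_code(f, random[[f]], genetic = identical(f, "genetic"))
  }, character(1L))
  sprintf("model {
  for (i in 1:N) {
    mu[i] <- inprod(X[i, ], beta)%s
    y[i] ~ dnorm(mu[i], tau)
  }
  for (k in 1:P) { beta[k] ~ dnorm(0, 1) }
%s
  sigma ~ dt(0, 0.01, 3) T(0,)
  tau <- 1 / (sigma * sigma)
}", paste(contrib, collapse = ""), paste(terms, collapse = "\n"))
}

## Lower Cholesky factor of A with a small diagonal jitter retry for
## numerically singular matrices (duplicated founder genotypes).
chol_lower_jitter <- function(A, jitter = 1e-8) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(A + diag(jitter, nrow(A))), error = function(e) NULL)
    if (is.null(ch))
      stop("relatedness matrix could not be factorized even after adding ",
           "diagonal jitter (", jitter, "); check A for validity")
  }
  t(ch)
}

#' Fit a hierarchical cortisol model with JAGS
#'
#' Fits the Gaussian hierarchical model described by a
#' \code{cort_model_spec} via MCMC. Random-slope terms carry unstructured
#' 3x3 covariance matrices (half-Student-t(3, 0, 10) standard deviations,
#' LKJ(1) correlations realized through the partial-correlation vine). The
#' genetic term is non-centered: independent standard normals are scaled by
#' the lower Cholesky factor of the additive relatedness matrix A and of
#' the genetic covariance, so the implied effects have covariance
#' \eqn{A \otimes \Sigma_{genetic}}. Convergence is summarized with
#' split-Rhat and effective sample sizes; a fit with any Rhat at or above
#' 1.1 is flagged (with a warning), never silently accepted.
#'
#' @param spec A \code{cort_model_spec} from [build_model()].
#' @param dataset The prepared dataset (\code{cort_data}).
#' @param settings A [sampler_settings()] object.
#' @return An object of class \code{cort_fit}: posterior draw matrices for
#'   fixed effects, residual sd, per-factor variance components (and
#'   correlations), optionally per-observation means, plus diagnostics.
#' @export
fit_model <- function(spec, dataset, settings = sampler_settings()) {
  stopifnot(inherits(spec, "cort_model_spec"),
            inherits(settings, "sampler_settings"))
  df <- apply_spec_subset(dataset, spec)
  y <- df[[spec$response]]
  if (any(!is.finite(y))) stop("non-finite response values in dataset")

  X <- fixed_design(df, spec$fixed)
  data <- list(N = nrow(df), P = ncol(X), X = X, y = y)
  levels_map <- list()
  for (f in names(spec$random)) {
    col <- if (identical(f, "genetic")) "individual" else f
    fac <- factor(as.character(df[[col]]))
    if (identical(f, "genetic")) {
      ids <- levels(fac)
      A <- spec$A
      missing_ids <- setdiff(ids, rownames(A))
      if (length(missing_ids) > 0L)
        stop("relatedness matrix lacks sampled individual(s): ",
             paste(missing_ids, collapse = ", "))
      Asub <- A[ids, ids, drop = FALSE]
      data$cholA <- chol_lower_jitter(Asub)
    }
    if (nlevels(fac) < 2L)
      stop("random-effect factor '", f, "' has a single level")
    data[[paste0("idx_", f)]] <- as.integer(fac)
    data[[paste0("n_", f)]] <- nlevels(fac)
    levels_map[[f]] <- levels(fac)
  }
  if (any(spec$random == 3L)) data$W <- cbind(1, df$t, df$t2)

  code <- jags_model_code(spec$random)
  inits <- lapply(seq_len(settings$chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = settings$seed + i)
  })
  monitors <- c("beta", "sigma",
                paste0("sd_", names(spec$random)),
                unlist(lapply(names(spec$random)[spec$random == 3L],
                              function(f) paste0(c("r12_", "r13_", "r23_"),
                                                 f))))
  if (settings$monitor_mu) monitors <- c(monitors, "mu")

  set_block_sampler(settings$block_sampler)
  n_adapt <- min(1000L, settings$warmup %/% 2L)
  run <- function() {
    jm <- rjags::jags.model(textConnection(code), data = data,
                            inits = inits, n.chains = settings$chains,
                            n.adapt = n_adapt, quiet = TRUE)
    stats::update(jm, n.iter = settings$warmup - n_adapt,
                  progress.bar = "none")
    rjags::coda.samples(jm, variable.names = monitors,
                        n.iter = settings$iterations - settings$warmup,
                        progress.bar = "none")
  }
  samp <- if (settings$quiet) suppressMessages(run()) else run()

  extract_fit(spec, settings, samp, X, y, levels_map)
}

extract_fit <- function(spec, settings, samp, X, y, levels_map) {
  vn <- colnames(samp[[1L]])
  pull <- function(pattern) {
    cols <- grep(pattern, vn, value = TRUE)
    m <- do.call(rbind, lapply(samp, function(ch) ch[, cols, drop = FALSE]))
    colnames(m) <- cols
    m
  }
  beta <- pull("^beta\\[")
  colnames(beta) <- colnames(X)
  sigma <- as.vector(pull("^sigma$"))

  comp_names <- c("intercept", "linear", "quadratic")
  vc <- list(); corr <- list()
  for (f in names(spec$random)) {
    d <- spec$random[[f]]
    if (d == 1L) {
      v <- pull(sprintf("^sd_%s$", f))^2
      colnames(v) <- "intercept"
    } else {
      v <- pull(sprintf("^sd_%s\\[", f))^2
      colnames(v) <- comp_names
      rc <- cbind(pull(sprintf("^r12_%s$", f)),
                  pull(sprintf("^r13_%s$", f)),
                  pull(sprintf("^r23_%s$", f)))
      colnames(rc) <- c("r12", "r13", "r23")
      corr[[f]] <- rc
    }
    vc[[f]] <- v
  }
  mu <- if (settings$monitor_mu) pull("^mu\\[") else NULL
  if (!is.null(mu)) {
    ord <- order(as.integer(sub("^mu\\[(\\d+)\\]$", "\\1", colnames(mu))))
    mu <- mu[, ord, drop = FALSE]
  }

  ## split-Rhat and ESS over hyperparameters and fixed effects
  diag_vars <- grep("^(beta\\[|sigma$|sd_|r1[23]_|r23_)", vn, value = TRUE)
  arr <- sapply(samp, function(ch) ch[, diag_vars, drop = FALSE],
                simplify = "array")
  rhat <- apply(arr, 2L, split_rhat)
  ess <- tryCatch(
    rowSums(as.matrix(sapply(samp, function(ch)
      coda::effectiveSize(ch[, diag_vars, drop = FALSE])))),
    error = function(e) rep(NA_real_, length(diag_vars)))
  diagnostics <- data.frame(parameter = diag_vars, rhat = rhat, ess = ess,
                            row.names = NULL)
  converged <- all(is.na(rhat) | rhat < 1.1)
  if (!converged)
    warning("convergence warning: max split-Rhat = ",
            signif(max(rhat, na.rm = TRUE), 4),
            " (threshold 1.1); treat estimates with caution")

  structure(list(spec = spec, settings = settings, beta = beta,
                 sigma = sigma, vc = vc, corr = corr, mu = mu, y = y,
                 levels = levels_map, diagnostics = diagnostics,
                 converged = converged),
            class = "cort_fit")
}

## Split-Rhat from an iterations x chains matrix of one scalar parameter.
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- n %/% 2L
  segs <- cbind(x[seq_len(half), , drop = FALSE],
                x[half + seq_len(half), , drop = FALSE])
  m <- ncol(segs)
  means <- colMeans(segs)
  vars <- apply(segs, 2L, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @export
print.cort_fit <- function(x, ...) {
  cat("Hierarchical cortisol model fit:", x$spec$variant, "\n")
  cat("  draws:", length(x$sigma), "(",
      x$settings$chains, "chain(s) x",
      x$settings$iterations - x$settings$warmup, ")\n")
  cat("  max split-Rhat:", signif(max(x$diagnostics$rhat, na.rm = TRUE), 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  for (f in names(x$vc)) {
    med <- apply(x$vc[[f]], 2L, stats::median)
    cat(sprintf("  V_%s: %s\n", f,
                paste(sprintf("%s=%.4g", colnames(x$vc[[f]]), med),
                      collapse = ", ")))
  }
  cat(sprintf("  residual sd (median): %.4g\n", stats::median(x$sigma)))
  invisible(x)
}
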