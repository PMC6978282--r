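#' Model specification for one response
#'
#' Captures the hierarchical model's fixed configuration: which response is
#' being fit, and the scale of the weakly informative Cauchy hyperpriors.
#' The prior structure is: flat prior on the grand intercept mean
#' `mu_alpha`; Cauchy(0, scale) on the population treatment effects
#' `mu_beta1..3`; half-Cauchy(0, scale) on the residual SD `sigma` and each
#' variance scale `gamma`; uniform on \[0, 1\] for each phylogenetic-signal
#' `lambda`.
#'
#' @param response `"biomass"` (log total biomass, g) or `"ratio"`
#'   (log root:shoot).
#' @param prior_scale Scale of the Cauchy / half-Cauchy hyperpriors
#'   (default 5).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response = c("biomass", "ratio"), prior_scale = 5) {
  response <- match.arg(response)
  if (prior_scale <= 0) stop("prior_scale must be positive")
  structure(list(response = response, prior_scale = prior_scale),
            class = "model_spec")
}

.response_column <- function(response) {
  switch(response,
         biomass = "log_total_biomass",
         ratio = "log_root_shoot",
         stop("unknown response: ", response))
}

.effect_names <- c("alpha", "beta1", "beta2", "beta3")

.check_effects <- function(effects, S = NULL) {
  if (!all(.effect_names %in% names(effects)))
    stop("effects must contain alpha, beta1, beta2, beta3")
  len <- lengths(effects[.effect_names])
  if (length(unique(len)) != 1L)
    stop("effect vectors must have equal length")
  if (!is.null(S) && len[[1]] != S)
    stop("effect vectors have length ", len[[1]], " but expected ", S)
  invisible(effects)
}

#' Expected log response for one species in one treatment cell
#'
#' The linear predictor alpha_s + beta1_s P + beta2_s N + beta3_s P N, with P
#' the flat-pot indicator and N the fertilized indicator.
#'
#' @param effects List with numeric vectors `alpha`, `beta1`, `beta2`,
#'   `beta3` aligned to the species order.
#' @param species_index Integer index (1-based) into the effect vectors.
#' @param P,N Treatment indicators in \{0, 1\}.
#' @return Expected response on the log scale.
#' @export
expected_response <- function(effects, species_index, P, N) {
  .check_effects(effects)
  S <- length(effects$alpha)
  if (any(species_index < 1L) || any(species_index > S))
    stop("species_index out of range 1..", S)
  if (!all(P %in% c(0, 1)) || !all(N %in% c(0, 1)))
    stop("P and N must be 0/1 indicators")
  effects$alpha[species_index] + effects$beta1[species_index] * P +
    effects$beta2[species_index] * N + effects$beta3[species_index] * P * N
}

#' Gaussian observation log likelihood
#'
#' Sum over plants of the Normal log density of the selected log response at
#' its species- and treatment-specific expectation with residual SD `sigma`.
#'
#' @param effects Species effects list (see [expected_response()]).
#' @param sigma Residual SD on the log scale, > 0.
#' @param prepared A `prepared_dataset`.
#' @param response `"biomass"` or `"ratio"`.
#' @return Scalar log likelihood (0 for an empty dataset).
#' @export
log_likelihood <- function(effects, sigma, prepared, response = c("biomass", "ratio")) {
  response <- match.arg(response)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single value > 0")
  d <- prepared$data
  if (nrow(d) == 0L) return(0)
  .check_effects(effects, S = length(prepared$species_order))
  mu <- expected_response(effects, d$species_index, d$P, d$N)
  sum(stats::dnorm(d[[.response_column(response)]], mean = mu, sd = sigma, log = TRUE))
}

# log density of MVN(x; mu, Sigma) via Cholesky
.dmvnorm_chol <- function(x, mean, Sigma) {
  L <- chol(Sigma)
  z <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

.dhalfcauchy <- function(x, scale) {
  ifelse(x > 0, log(2) + stats::dcauchy(x, 0, scale, log = TRUE), -Inf)
}

#' Hierarchical log prior
#'
#' Adds up, for the state of one response model: (i) one multivariate-normal
#' log density per species-parameter vector (alpha, beta1, beta2, beta3),
#' each with mean `mu_par * 1` and covariance
#' `gamma_par * pagel_transform(C, lambda_par)`; (ii) Cauchy(0, scale)
#' log densities for `mu_beta1..3`; (iii) half-Cauchy(0, scale) for `sigma`
#' and each `gamma_par`; (iv) nothing for the flat priors on `mu_alpha`
#' (uniform on the reals) and each `lambda_par` (uniform on \[0, 1\]).
#' Returns `-Inf` outside the support.
#'
#' @param state List with `effects` (see [expected_response()]), `mu`,
#'   `lambda`, `gamma` (each a named numeric vector over
#'   `alpha, beta1, beta2, beta3`) and scalar `sigma`.
#' @param C A `phylo_correlation` matrix.
#' @param spec A [model_spec()].
#' @return Scalar log prior density.
#' @export
log_prior <- function(state, C, spec = model_spec()) {
  lam <- state$lambda[.effect_names]
  gam <- state$gamma[.effect_names]
  mu <- state$mu[.effect_names]
  if (any(is.na(lam)) || any(is.na(gam)) || any(is.na(mu)))
    stop("state$mu, state$lambda, state$gamma must be named over alpha, beta1, beta2, beta3")
  if (any(lam < 0 | lam > 1) || any(gam <= 0) || state$sigma <= 0) return(-Inf)
  .check_effects(state$effects, S = nrow(C))
  lp <- 0
  for (k in .effect_names) {
    Sig <- scale_covariance(pagel_transform(C, lam[[k]]), gam[[k]])
    lp <- lp + .dmvnorm_chol(state$effects[[k]], rep(mu[[k]], nrow(C)), Sig)
  }
  lp <- lp + sum(stats::dcauchy(mu[c("beta1", "beta2", "beta3")], 0,
                                spec$prior_scale, log = TRUE))
  lp <- lp + sum(.dhalfcauchy(gam, spec$prior_scale))
  lp + .dhalfcauchy(state$sigma, spec$prior_scale)
}

#' Hierarchical log posterior (up to a constant)
#'
#' `log_prior(state) + log_likelihood(state)` for the selected response;
#' `-Inf` outside the parameter support.
#'
#' @inheritParams log_prior
#' @param prepared A `prepared_dataset`.
#' @return Scalar log posterior density.
#' @export
log_posterior <- function(state, prepared, C, spec = model_spec()) {
  lp <- log_prior(state, C, spec)
  if (!is.finite(lp)) return(lp)
  lp + log_likelihood(state$effects, state$sigma, prepared, spec$response)
}
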