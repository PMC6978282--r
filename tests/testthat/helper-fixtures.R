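# Shared fixtures and independent oracles. The oracle densities deliberately
# avoid the package's Cholesky code path: plain solve()/det() linear algebra
# and hand-written density formulas.

toy_tree <- function() read_newick(text = "((A:1,B:1):1,C:2);")

toy_records <- function() {
  data.frame(
    species_id = c("A", "A", "B", "B", "C", "C"),
    pot_type = c("regular", "flat", "regular", "flat", "regular", "flat"),
    nutrient = c("water", "fertilized", "fertilized", "water", "water", "fertilized"),
    root_mass_mg = c(10, 12, 0.03, 8, 20, 25),
    shoot_mass_mg = c(30, 45, 15, 22, 60, 80),
    stringsAsFactors = FALSE
  )
}

toy_prepared <- function() prepare_dataset(toy_records(), c("A", "B", "C"))

# prepared_dataset built directly from log responses (bypasses masses)
prepared_from_responses <- function(species_index, species_order, P, N,
                                    log_biomass, log_ratio = log_biomass) {
  structure(list(
    data = data.frame(species_index = species_index,
                      species_id = species_order[species_index],
                      P = P, N = N,
                      log_total_biomass = log_biomass,
                      log_root_shoot = log_ratio,
                      root_below_detection = FALSE),
    species_order = species_order), class = "prepared_dataset")
}

oracle_log_cauchy <- function(x, scale) log(scale / (pi * (x^2 + scale^2)))
oracle_log_half_cauchy <- function(x, scale) {
  ifelse(x > 0, log(2) + oracle_log_cauchy(x, scale), -Inf)
}

oracle_dmvnorm <- function(x, mean, Sigma) {
  k <- length(x)
  dev <- x - mean
  -0.5 * k * log(2 * pi) - 0.5 * log(det(Sigma)) -
    0.5 * drop(t(dev) %*% solve(Sigma) %*% dev)
}

# Pagel/gamma transform written out element by element
oracle_transformed_cov <- function(C, lambda, gamma) {
  S <- nrow(C)
  M <- matrix(0, S, S)
  for (i in seq_len(S)) for (j in seq_len(S))
    M[i, j] <- if (i == j) C[i, j] else lambda * C[i, j]
  gamma * M
}

# Full brute-force log posterior for one response model
oracle_log_posterior <- function(state, prepared, C, response, prior_scale = 5) {
  fam <- c("alpha", "beta1", "beta2", "beta3")
  if (any(state$lambda < 0 | state$lambda > 1) || any(state$gamma <= 0) ||
      state$sigma <= 0) return(-Inf)
  Cm <- unclass(C)
  lp <- 0
  for (k in fam) {
    Sig <- oracle_transformed_cov(Cm, state$lambda[[k]], state$gamma[[k]])
    lp <- lp + oracle_dmvnorm(state$effects[[k]],
                              rep(state$mu[[k]], nrow(Cm)), Sig)
    lp <- lp + oracle_log_half_cauchy(state$gamma[[k]], prior_scale)
  }
  for (k in c("beta1", "beta2", "beta3"))
    lp <- lp + oracle_log_cauchy(state$mu[[k]], prior_scale)
  lp <- lp + oracle_log_half_cauchy(state$sigma, prior_scale)
  d <- prepared$data
  y <- if (response == "biomass") d$log_total_biomass else d$log_root_shoot
  for (i in seq_len(nrow(d))) {
    s <- d$species_index[i]
    m <- state$effects$alpha[s] + state$effects$beta1[s] * d$P[i] +
      state$effects$beta2[s] * d$N[i] + state$effects$beta3[s] * d$P[i] * d$N[i]
    lp <- lp - 0.5 * log(2 * pi * state$sigma^2) -
      (y[i] - m)^2 / (2 * state$sigma^2)
  }
  lp
}

random_state <- function(S) {
  fam <- c("alpha", "beta1", "beta2", "beta3")
  list(
    effects = setNames(lapply(fam, function(k) rnorm(S, 0, 2)), fam),
    mu = setNames(rnorm(4, 0, 2), fam),
    lambda = setNames(runif(4), fam),
    gamma = setNames(exp(rnorm(4, 0, 0.5)), fam),
    sigma = exp(rnorm(1, 0, 0.5))
  )
}

random_ultrametric_tree <- function(S) {
  tr <- ape::rcoal(S)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}
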