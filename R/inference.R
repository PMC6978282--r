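# Univariate slice sampler (stepping out + shrinkage, Neal 2003).
# Returns the new point and its log density; exact for any 1-d target.
.slice_1d <- function(logf, x0, fx0, w = 1, max_steps = 50,
                      lower = -Inf, upper = Inf) {
  if (!is.finite(fx0)) stop("slice sampler started at a zero-density point")
  logy <- fx0 - stats::rexp(1)
  u <- stats::runif(1) * w
  L <- x0 - u
  R <- L + w
  j <- floor(stats::runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && L > lower && logf(L) > logy) { L <- L - w; j <- j - 1 }
  while (k > 0 && R < upper && logf(R) > logy) { R <- R + w; k <- k - 1 }
  L <- max(L, lower)
  R <- min(R, upper)
  for (i in 1:1000) {
    x1 <- stats::runif(1, L, R)
    fx1 <- logf(x1)
    if (fx1 >= logy) return(list(x = x1, fx = fx1))
    if (x1 < x0) L <- x1 else R <- x1
  }
  list(x = x0, fx = fx0) # shrinkage exhausted by floating-point ties
}

#' Construct a posterior-draws container
#'
#' @param draws Numeric array with dimensions (post-warmup iteration, chain,
#'   parameter); the third dimension must carry parameter names.
#' @param seed,chains,iterations,warmup Run metadata.
#' @return An object of class `posterior_draws`.
#' @export
posterior_draws <- function(draws, seed = NA_integer_, chains = dim(draws)[2],
                            iterations = NA_integer_, warmup = NA_integer_) {
  stopifnot(is.array(draws), length(dim(draws)) == 3L,
            !is.null(dimnames(draws)[[3]]))
  structure(list(draws = draws, parameters = dimnames(draws)[[3]],
                 seed = seed, chains = chains, iterations = iterations,
                 warmup = warmup),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("posterior_draws: %d chains x %d post-warmup draws x %d parameters (seed %s)\n",
              d[2], d[1], d[3], x$seed))
  invisible(x)
}

#' Extract pooled draws of one parameter
#'
#' @param draws A `posterior_draws` object.
#' @param parameter Parameter name.
#' @return Numeric vector of pooled post-warmup draws (all chains).
#' @export
extract_draws <- function(draws, parameter) {
  if (!parameter %in% draws$parameters)
    stop("unknown parameter: ", parameter)
  as.vector(draws$draws[, , parameter])
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Each chain is split in half, then the classic between/within variance
#' ratio is computed over the 2m half-chains. Values near 1 indicate that
#' the chains have mixed. When every half-chain is constant (zero within-
#' and between-chain variance) R-hat is defined as 1 by convention.
#'
#' @param draws A `posterior_draws` object.
#' @param parameter Parameter name.
#' @return Scalar R-hat.
#' @export
rhat <- function(draws, parameter) {
  x <- draws$draws[, , parameter, drop = FALSE]
  dim(x) <- dim(draws$draws)[1:2]
  .rhat_matrix(x)
}

# x: iterations x chains matrix
.rhat_matrix <- function(x) {
  n <- nrow(x)
  if (n < 4L || ncol(x) < 2L)
    stop("need at least 2 chains of at least 4 draws")
  half <- floor(n / 2)
  split <- cbind(x[seq_len(half), , drop = FALSE],
                 x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  nn <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (!is.finite(W) || W <= 0) {
    if (isTRUE(all.equal(max(split), min(split)))) return(1)
    return(Inf)
  }
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Convergence gate on split R-hat
#'
#' Computes R-hat for every stored parameter and passes only when all values
#' fall inside \[0.99, 1.01\]. Failure is a report state, not an error.
#'
#' @param draws A `posterior_draws` object.
#' @param interval Acceptance interval for R-hat.
#' @return A list of class `convergence_report`: `rhat` (named vector),
#'   `pass`, `worst` (parameter name), `failed` (names outside the interval).
#' @export
convergence_gate <- function(draws, interval = c(0.99, 1.01)) {
  rh <- vapply(draws$parameters, function(p) rhat(draws, p), numeric(1))
  dev <- abs(rh - 1)
  failed <- names(rh)[rh < interval[1] | rh > interval[2]]
  structure(list(rhat = rh, pass = length(failed) == 0L,
                 worst = names(rh)[which.max(dev)], failed = failed,
                 interval = interval),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("convergence: %s (max |R-hat - 1| at %s = %.4f)\n",
              if (x$pass) "PASS" else "FAIL", x$worst, x$rhat[x$worst]))
  if (length(x$failed))
    cat("  outside interval:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' Generic MCMC by coordinate-wise slice sampling
#'
#' A tuning-free sampler for arbitrary (low-dimensional) log densities, used
#' to validate the model-specific sampler against targets with known
#' moments. Each iteration updates every coordinate in turn with a
#' univariate slice move.
#'
#' @param logpost Function taking a numeric vector and returning its log
#'   density (may be `-Inf` outside the support).
#' @param init Numeric vector of starting values (names become parameter
#'   names).
#' @param chains,iterations,warmup,seed Run configuration; the post-warmup
#'   draws are stored.
#' @param w Slice step width (scalar or per-coordinate).
#' @param lower,upper Optional support bounds per coordinate.
#' @return A `posterior_draws` object.
#' @export
run_mcmc <- function(logpost, init, chains = 4, iterations = 2000,
                     warmup = floor(iterations / 2), seed = 1, w = 1,
                     lower = -Inf, upper = Inf) {
  stopifnot(warmup < iterations, chains >= 1)
  p <- length(init)
  pnames <- names(init)
  if (is.null(pnames)) pnames <- paste0("par", seq_len(p))
  w <- rep_len(w, p)
  lower <- rep_len(lower, p)
  upper <- rep_len(upper, p)
  kept <- iterations - warmup
  out <- array(NA_real_, c(kept, chains, p), dimnames = list(NULL, NULL, pnames))
  set.seed(seed)
  for (ch in seq_len(chains)) {
    x <- init + stats::rnorm(p, 0, 0.1 * pmax(w, 1e-3))
    x <- pmin(pmax(x, lower + 1e-9), upper - 1e-9)
    fx <- logpost(x)
    tries <- 0
    while (!is.finite(fx) && tries < 10) {
      x <- init + stats::rnorm(p, 0, 0.1 * pmax(w, 1e-3))
      x <- pmin(pmax(x, lower + 1e-9), upper - 1e-9)
      fx <- logpost(x)
      tries <- tries + 1
    }
    if (!is.finite(fx)) stop("could not find a finite starting point")
    for (it in seq_len(iterations)) {
      for (j in seq_len(p)) {
        res <- .slice_1d(function(v) { x[j] <- v; logpost(x) },
                         x[j], fx, w = w[j], lower = lower[j], upper = upper[j])
        x[j] <- res$x
        fx <- res$fx
      }
      if (it > warmup) out[it - warmup, ch, ] <- x
    }
  }
  posterior_draws(out, seed = seed, chains = chains,
                  iterations = iterations, warmup = warmup)
}

# ---- model-specific blocked Gibbs sampler --------------------------------

# Expand a `fixed` entry (scalar or named vector over the four effect
# families) to a full named vector, or NULL when not fixed.
.expand_fixed <- function(value, default_names = .effect_names) {
  if (is.null(value)) return(NULL)
  if (length(value) == 1L && is.null(names(value)))
    return(stats::setNames(rep(value, 4), default_names))
  v <- value[default_names]
  if (any(is.na(v))) stop("fixed vectors must be named over alpha, beta1, beta2, beta3")
  v
}

#' Fit the phylogenetic hierarchical model by MCMC
#'
#' Samples the posterior of one response model (log total biomass or log
#' root:shoot ratio) with a partially collapsed blocked Gibbs sampler: for
#' each effect family (alpha, beta1, beta2, beta3) the hyperparameters
#' `lambda`, `gamma` and the population mean `mu` are updated against the
#' likelihood with that family's species effects integrated out (exact
#' normal draw for the flat-prior `mu_alpha`; univariate slice sampling for
#' the rest, on \[0, 1\] for `lambda` and on the log scale for `gamma`),
#' the S species effects are then redrawn jointly from their exact
#' multivariate-normal conditional, and `sigma` is slice-sampled on the log
#' scale. All draws
#' respect the constraints (lambda in \[0, 1\]; gamma, sigma > 0), and runs
#' are bitwise reproducible for a fixed seed and configuration.
#'
#' @param prepared A `prepared_dataset`.
#' @param C A `phylo_correlation` matrix covering the dataset's species.
#' @param response `"biomass"` or `"ratio"`.
#' @param chains Number of chains (>= 2 so R-hat is defined).
#' @param iterations Total iterations per chain, including warmup.
#' @param warmup Warmup (discarded) iterations per chain.
#' @param seed Integer seed controlling all randomness of the run.
#' @param prior_scale Cauchy / half-Cauchy hyperprior scale.
#' @param fixed Optional named list pinning parameters instead of sampling
#'   them: `sigma` (scalar), `lambda` and/or `gamma` (scalar applied to all
#'   four families, or a named vector over alpha, beta1, beta2, beta3).
#'   Used for degenerate sub-models and validation.
#' @return An object of class `c("phlm_fit", "posterior_draws")` with the
#'   draws, run metadata, species order, model spec and a
#'   `convergence_report`.
#' @export
fit_phlm <- function(prepared, C, response = c("biomass", "ratio"),
                     chains = 4, iterations = 4000, warmup = 2000,
                     seed = 1, prior_scale = 5, fixed = list()) {
  response <- match.arg(response)
  stopifnot(inherits(prepared, "prepared_dataset"))
  if (chains < 2) stop("need at least 2 chains for the convergence gate")
  if (warmup >= iterations) stop("warmup must be smaller than iterations")

  sp <- prepared$species_order
  Cm <- unclass(C)
  lab <- rownames(Cm)
  if (is.null(lab)) stop("correlation matrix must carry species labels")
  missing <- setdiff(sp, lab)
  if (length(missing))
    stop("species missing from the correlation matrix: ",
         paste(missing, collapse = ", "))
  Cm <- Cm[sp, sp]
  S <- length(sp)

  d <- prepared$data
  y <- d[[.response_column(response)]]
  n <- length(y)
  if (n == 0L) stop("empty dataset")

  # per-family design blocks: species indicator times the 0/1 cell weight
  rows <- seq_len(n)
  weights <- list(rep(1, n), d$P, d$N, d$P * d$N)
  Xb <- lapply(weights, function(w) {
    M <- matrix(0, n, S)
    M[cbind(rows, d$species_index)] <- w
    M
  })
  counts <- lapply(Xb, function(M) colSums(M^2)) # diagonal of X'X (0/1 weights)
  X <- do.call(cbind, Xb)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  blocks <- lapply(0:3, function(b) b * S + seq_len(S))

  eig <- eigen(Cm, symmetric = TRUE)
  Q <- eig$vectors
  dvals <- pmax(eig$values, 1e-12)
  Qt1 <- drop(crossprod(Q, rep(1, S)))

  fixed_lambda <- .expand_fixed(fixed$lambda)
  fixed_gamma <- .expand_fixed(fixed$gamma)
  fixed_sigma <- fixed$sigma
  scale5 <- prior_scale

  hyper_names <- c("mu_alpha", "mu_beta1", "mu_beta2", "mu_beta3",
                   paste0("lambda_", .effect_names),
                   paste0("gamma_", .effect_names), "sigma")
  theta_names <- c(paste0("alpha[", sp, "]"), paste0("beta1[", sp, "]"),
                   paste0("beta2[", sp, "]"), paste0("beta3[", sp, "]"))
  pnames <- c(hyper_names, theta_names)
  kept <- iterations - warmup
  out <- array(NA_real_, c(kept, chains, length(pnames)),
               dimnames = list(NULL, NULL, pnames))

  # Sigma_k eigenvalues for family k: gamma * (lambda * d_i + 1 - lambda)
  eigvals_k <- function(lam, gam) gam * (lam * dvals + 1 - lam)

  set.seed(seed)
  for (ch in seq_len(chains)) {
    # init: data-centred mean with small jitter, mid-support shape parameters
    for (attempt in 1:10) {
      mu <- c(alpha = mean(y) + stats::rnorm(1, 0, 0.1),
              beta1 = stats::rnorm(1, 0, 0.1),
              beta2 = stats::rnorm(1, 0, 0.1),
              beta3 = stats::rnorm(1, 0, 0.1))
      lam <- if (is.null(fixed_lambda))
        stats::setNames(stats::runif(4, 0.3, 0.7), .effect_names) else fixed_lambda
      gam <- if (is.null(fixed_gamma))
        stats::setNames(exp(stats::rnorm(4, 0, 0.2)), .effect_names) else fixed_gamma
      sigma <- if (is.null(fixed_sigma))
        max(stats::sd(y), 0.1) * exp(stats::rnorm(1, 0, 0.2)) else fixed_sigma
      if (is.finite(sigma) && sigma > 0) break
    }
    effects <- lapply(1:4, function(k) rep(mu[k], S))
    fitted_blocks <- lapply(1:4, function(k) drop(Xb[[k]] %*% effects[[k]]))
    fitted <- Reduce(`+`, fitted_blocks)

    for (it in seq_len(iterations)) {
      s2 <- sigma^2

      # --- per family: partially collapsed updates ---
      # With the family's species effects integrated out, the residual is
      # r ~ N(mu_k * X_k 1, sigma^2 I + X_k Sigma_k X_k'). Woodbury in
      # species space turns both the marginal likelihood (for lambda_k,
      # gamma_k, mu_k updates) and the mu_k Gaussian coefficients into
      # S x S computations. Collapsing removes the slow random walk between
      # hyperparameters and their effects; the effects are redrawn exactly
      # from their full conditional afterwards, so the composition is a
      # valid partially collapsed Gibbs sweep. A family with no data
      # degenerates gracefully (a = 0: mu_k falls back to its prior).
      Sinv_list <- vector("list", 4)
      for (k in 1:4) {
        r <- y - fitted + fitted_blocks[[k]]
        q <- drop(crossprod(Xb[[k]], r))
        cnt <- counts[[k]]
        ds2 <- diag(cnt / s2, S)
        # lambda/gamma-varying part of the effects-marginalised log
        # likelihood, in the eigenbasis of C: with G = Q'DQ/s2 and
        # B = I + E^(1/2) G E^(1/2) it is -logdet(B)/2 + v'B^-1 v/(2 s2^2),
        # v = E^(1/2) Q'(q - mu c) — O(S^2) per evaluation
        G <- crossprod(Q, cnt * Q) / s2
        qt <- drop(crossprod(Q, q - mu[k] * cnt))
        marg <- function(lam_, gam_) {
          e <- gam_ * (lam_ * dvals + 1 - lam_)
          se <- sqrt(e)
          B <- diag(S) + (se %o% se) * G
          U <- chol(B)
          z <- backsolve(U, se * qt, transpose = TRUE)
          -sum(log(diag(U))) + sum(z^2) / (2 * s2^2)
        }
        if (is.null(fixed_lambda)) {
          logf <- function(l_) marg(l_, gam[k])
          lam[k] <- .slice_1d(logf, lam[k], logf(lam[k]), w = 0.25,
                              lower = 0, upper = 1)$x
        }
        if (is.null(fixed_gamma)) {
          logf <- function(lg) marg(lam[k], exp(lg)) +
            .dhalfcauchy(exp(lg), scale5) + lg
          gam[k] <- exp(.slice_1d(logf, log(gam[k]),
                                  logf(log(gam[k])), w = 1)$x)
        }
        e <- eigvals_k(lam[k], gam[k])
        Sinv <- Q %*% (t(Q) / e)
        Sinv_list[[k]] <- Sinv
        U <- chol(Sinv + ds2)
        Asolve <- function(v) backsolve(U, backsolve(U, v, transpose = TRUE))
        Aq <- Asolve(q)
        Ac <- Asolve(cnt)
        a <- sum(cnt) / s2 - sum(cnt * Ac) / s2^2
        b <- sum(q) / s2 - sum(cnt * Aq) / s2^2
        if (k == 1L) {
          # flat prior: Gaussian conditional
          mu[k] <- stats::rnorm(1, b / a, sqrt(1 / a))
        } else {
          logf <- function(m_) {
            -0.5 * a * m_^2 + b * m_ + stats::dcauchy(m_, 0, scale5, log = TRUE)
          }
          res <- .slice_1d(logf, mu[k], logf(mu[k]),
                           w = if (a > 0) max(0.5, 2 / sqrt(a)) else 5)
          mu[k] <- res$x
        }
        mean_k <- Asolve(q / s2 + drop(Sinv %*% rep(mu[k], S)))
        effects[[k]] <- mean_k + backsolve(U, stats::rnorm(S))
        fitted <- fitted - fitted_blocks[[k]]
        fitted_blocks[[k]] <- drop(Xb[[k]] %*% effects[[k]])
        fitted <- fitted + fitted_blocks[[k]]
      }

      # --- joint exact redraw of all species effects ---
      # The per-family draws above keep the sweep valid, but effects of
      # different families for the same species are strongly correlated
      # (alpha_s against its beta_s); one joint 4S-dimensional draw from the
      # exact multivariate-normal full conditional removes that coupling.
      A4 <- XtX / s2
      b4 <- Xty / s2
      for (k in 1:4) {
        idx <- blocks[[k]]
        A4[idx, idx] <- A4[idx, idx] + Sinv_list[[k]]
        b4[idx] <- b4[idx] + mu[k] * rowSums(Sinv_list[[k]])
      }
      U4 <- chol(A4)
      theta <- backsolve(U4, backsolve(U4, b4, transpose = TRUE)) +
        backsolve(U4, stats::rnorm(4 * S))
      for (k in 1:4) {
        effects[[k]] <- theta[blocks[[k]]]
        fitted_blocks[[k]] <- drop(Xb[[k]] %*% effects[[k]])
      }
      fitted <- Reduce(`+`, fitted_blocks)

      # --- cheap conditional refresh of lambda_k, gamma_k given effects ---
      # interleaving the effects-conditional kernel with the collapsed one
      # costs O(S) per slice evaluation (eigenbasis) and further decorrelates
      # the variance parameters
      for (k in 1:4) {
        z <- drop(crossprod(Q, effects[[k]])) - mu[k] * Qt1
        if (is.null(fixed_lambda)) {
          gk <- gam[k]
          logf <- function(l_) {
            e <- gk * (l_ * dvals + 1 - l_)
            -0.5 * sum(log(e)) - 0.5 * sum(z^2 / e)
          }
          lam[k] <- .slice_1d(logf, lam[k], logf(lam[k]), w = 0.25,
                              lower = 0, upper = 1)$x
        }
        if (is.null(fixed_gamma)) {
          shape <- lam[k] * dvals + 1 - lam[k]
          logf <- function(lg) {
            g <- exp(lg)
            e <- g * shape
            -0.5 * sum(log(e)) - 0.5 * sum(z^2 / e) +
              .dhalfcauchy(g, scale5) + lg
          }
          gam[k] <- exp(.slice_1d(logf, log(gam[k]),
                                  logf(log(gam[k])), w = 1)$x)
        }
      }

      # --- sigma: slice on log scale ---
      if (is.null(fixed_sigma)) {
        ssr <- sum((y - fitted)^2)
        logf <- function(ls) {
          s <- exp(ls)
          -n * ls - ssr / (2 * s^2) + .dhalfcauchy(s, scale5) + ls
        }
        res <- .slice_1d(logf, log(sigma), logf(log(sigma)), w = 0.5)
        sigma <- exp(res$x)
      }

      if (it > warmup)
        out[it - warmup, ch, ] <- c(mu, lam, gam, sigma, unlist(effects))
    }
  }

  fit <- posterior_draws(out, seed = seed, chains = chains,
                         iterations = iterations, warmup = warmup)
  fit$species_order <- sp
  fit$spec <- model_spec(response, prior_scale)
  fit$fixed <- fixed
  fit$convergence <- convergence_gate(fit)
  class(fit) <- c("phlm_fit", class(fit))
  fit
}

#' @export
print.phlm_fit <- function(x, ...) {
  cat(sprintf("phlm_fit (%s response): %d species, %d chains x %d draws, seed %s\n",
              x$spec$response, length(x$species_order), x$chains,
              dim(x$draws)[1], x$seed))
  print(x$convergence)
  invisible(x)
}

#' Persist draws as a long delimited table
#'
#' One row per (chain, iteration, parameter) triple, with a sidecar `.json`
#' holding the run configuration and per-parameter R-hat when `jsonlite` is
#' available.
#'
#' @param draws A `posterior_draws` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_draws_tsv <- function(draws, path) {
  d <- dim(draws$draws)
  long <- data.frame(
    chain = rep(seq_len(d[2]), each = d[1], times = d[3]),
    iteration = rep(seq_len(d[1]), times = d[2] * d[3]),
    parameter = rep(draws$parameters, each = d[1] * d[2]),
    value = as.vector(draws$draws)
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- list(seed = draws$seed, chains = draws$chains,
                 iterations = draws$iterations, warmup = draws$warmup,
                 rhat = as.list(convergence_gate(draws)$rhat))
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}
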