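#' Design of a 2x2 factorial pot experiment
#'
#' Captures the experimental layout the generator reproduces: S species, two
#' pot shapes (regular and flat) crossed with two nutrient levels (water and
#' fertilized), and per-species replicate counts drawn uniformly from a
#' range per pot type. Defaults mirror a 15-species experiment with 5-6
#' replicates per cell in regular pots and 5-13 in flat pots.
#'
#' @param S Number of species (>= 2).
#' @param reps_regular,reps_flat Integer ranges `c(min, max)` of replicates
#'   per species x nutrient cell for each pot type.
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(S = 15, reps_regular = c(5, 6), reps_flat = c(5, 13)) {
  stopifnot(S >= 2, length(reps_regular) == 2, length(reps_flat) == 2,
            reps_regular[1] >= 1, reps_flat[1] >= 1,
            reps_regular[1] <= reps_regular[2], reps_flat[1] <= reps_flat[2])
  structure(list(S = as.integer(S), reps_regular = as.integer(reps_regular),
                 reps_flat = as.integer(reps_flat)),
            class = "design_spec")
}

#' Ground-truth hyperparameters for simulation
#'
#' A full hyperparameter set usable as generative truth. The default
#' population treatment effects are realistic log-scale effect sizes for a
#' seedling pot experiment: a strong positive nutrient effect on total
#' biomass (about e^1.03 = 2.8-fold) with weak pot and interaction effects,
#' and a strong negative nutrient effect on the root:shoot ratio (about
#' 0.46-fold) with weak pot effects. Phylogenetic signal, variance scales,
#' grand intercepts and residual SDs are package defaults chosen to give
#' species-level spread and posterior interval widths typical of a
#' 15-species experiment; see the methods vignette.
#'
#' @param response `"biomass"` or `"ratio"`.
#' @param mu Named numeric vector over `alpha, beta1, beta2, beta3`.
#' @param lambda,gamma Named numeric vectors over the same four families.
#' @param sigma Residual SD on the log scale.
#' @return A list of class `truth_params`.
#' @export
truth_params <- function(response = c("biomass", "ratio"),
                         mu = NULL, lambda = NULL, gamma = NULL, sigma = NULL) {
  response <- match.arg(response)
  if (is.null(mu))
    mu <- if (response == "biomass")
      c(alpha = -4.6, beta1 = 0.2078, beta2 = 1.0323, beta3 = 0.3216)
    else
      c(alpha = -0.7, beta1 = 0.1131, beta2 = -0.7806, beta3 = -0.1039)
  if (is.null(lambda))
    lambda <- c(alpha = 0.5, beta1 = 0.5, beta2 = 0.5, beta3 = 0.5)
  if (is.null(gamma))
    gamma <- c(alpha = 1.0, beta1 = 0.25, beta2 = 0.25, beta3 = 0.25)
  if (is.null(sigma)) sigma <- if (response == "biomass") 0.7 else 0.5
  stopifnot(all(.effect_names %in% names(mu)),
            all(.effect_names %in% names(lambda)),
            all(.effect_names %in% names(gamma)),
            all(lambda >= 0 & lambda <= 1), all(gamma > 0), sigma > 0)
  structure(list(response = response, mu = mu[.effect_names],
                 lambda = lambda[.effect_names], gamma = gamma[.effect_names],
                 sigma = sigma),
            class = "truth_params")
}

#' Simulate a pure-birth ultrametric tree
#'
#' A Yule (pure-birth) tree with `S` tips, rescaled so that every
#' root-to-tip depth is exactly 1; tips are labelled `sp01, sp02, ...`.
#' Identical seeds give identical trees.
#'
#' @param S Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An [ape::phylo] tree.
#' @export
simulate_tree <- function(S, seed = 1) {
  if (S < 2) stop("need at least 2 species")
  set.seed(seed)
  tree <- ape::rphylo(S, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%02d", seq_len(S))
  tree
}

#' Draw phylogenetically correlated species effects
#'
#' Each family (alpha, beta1, beta2, beta3) is drawn once from its
#' multivariate normal prior: mean `mu_par` broadcast over species,
#' covariance `gamma_par * pagel_transform(C, lambda_par)`.
#'
#' @param tree An [ape::phylo] tree or a `phylo_correlation` matrix.
#' @param truth A [truth_params()] object.
#' @param seed Integer seed.
#' @return List of four named species-effect vectors (names = tip labels).
#' @export
simulate_species_effects <- function(tree, truth, seed = 1) {
  C <- if (inherits(tree, "phylo")) phylo_correlation(tree) else tree
  Cm <- unclass(C)
  S <- nrow(Cm)
  labels <- rownames(Cm)
  set.seed(seed)
  effects <- lapply(.effect_names, function(k) {
    Sig <- assert_positive_definite(
      scale_covariance(pagel_transform(Cm, truth$lambda[[k]]), truth$gamma[[k]]))
    U <- chol(Sig)
    stats::setNames(truth$mu[[k]] + drop(crossprod(U, stats::rnorm(S))), labels)
  })
  names(effects) <- .effect_names
  effects
}

#' Simulate a harvested 2x2 factorial experiment
#'
#' For every species x pot x nutrient cell a replicate count is drawn from
#' the design's range, then each plant's log total biomass (g) and log
#' root:shoot ratio are drawn from their Normal observation models. The two
#' responses are coupled back into one coherent mass pair per plant through
#' the bijection root = total * r / (1 + r), shoot = total / (1 + r), which
#' preserves both marginal models exactly. Masses are rounded to the 0.1 mg
#' balance resolution; root masses below the detection limit are stored as 0
#' with the below-detection flag set (the balance cannot read them), and
#' shoot masses are floored at the smallest recordable reading (0.1 mg).
#'
#' @param effects_biomass,effects_ratio Species-effect lists (see
#'   [simulate_species_effects()]) for the two responses, with identical
#'   species names.
#' @param design A [design_spec()].
#' @param sigma_biomass,sigma_ratio Residual SDs on the log scale (>= 0).
#' @param detection_limit_mg Balance detection limit in mg.
#' @param seed Integer seed.
#' @return A record data.frame passing [validate_biomass_records()] (flagged
#'   roots stored as 0 mg).
#' @export
simulate_experiment <- function(effects_biomass, effects_ratio, design,
                                sigma_biomass = 0.7, sigma_ratio = 0.5,
                                detection_limit_mg = 0.1, seed = 1) {
  stopifnot(inherits(design, "design_spec"),
            sigma_biomass >= 0, sigma_ratio >= 0, detection_limit_mg > 0)
  species <- names(effects_biomass$alpha)
  if (!identical(species, names(effects_ratio$alpha)))
    stop("the two effect sets must cover the same species in the same order")
  if (length(species) != design$S)
    stop("effects cover ", length(species), " species but the design expects ",
         design$S)
  set.seed(seed)
  rows <- list()
  for (s in seq_along(species)) {
    for (pot in .pot_levels) {
      P <- as.integer(pot == "flat")
      rng <- if (pot == "flat") design$reps_flat else design$reps_regular
      for (nut in .nutrient_levels) {
        N <- as.integer(nut == "fertilized")
        n_rep <- sample(rng[1]:rng[2], 1)
        eta_b <- expected_response(effects_biomass, s, P, N)
        eta_r <- expected_response(effects_ratio, s, P, N)
        log_total <- stats::rnorm(n_rep, eta_b, sigma_biomass)
        log_ratio <- stats::rnorm(n_rep, eta_r, sigma_ratio)
        total_mg <- 1000 * exp(log_total)
        r <- exp(log_ratio)
        root <- round(total_mg * r / (1 + r), 1)
        shoot <- pmax(round(total_mg / (1 + r), 1), 0.1)
        below <- root < detection_limit_mg
        root[below] <- 0
        rows[[length(rows) + 1L]] <- data.frame(
          species_id = species[s], pot_type = pot, nutrient = nut,
          root_mass_mg = root, shoot_mass_mg = shoot,
          root_below_detection = below, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Volume of a square-frustum pot
#'
#' A regular nursery pot is a truncated square pyramid; its volume is
#' h/3 * (a^2 + a*b + b^2) with top side a, bottom side b and height h.
#'
#' @param top_side_cm,bottom_side_cm,height_cm Dimensions in cm, > 0.
#' @return Volume in cm^3.
#' @examples
#' pot_volume_frustum(7, 5, 8) # 290.7 (to one decimal)
#' @export
pot_volume_frustum <- function(top_side_cm, bottom_side_cm, height_cm) {
  if (any(c(top_side_cm, bottom_side_cm, height_cm) <= 0))
    stop("all dimensions must be positive")
  height_cm / 3 * (top_side_cm^2 + top_side_cm * bottom_side_cm + bottom_side_cm^2)
}

#' Volume of a flat box pot (rhizobox)
#'
#' @param height_cm,width_cm,depth_cm Inner dimensions in cm, > 0.
#' @return Volume in cm^3.
#' @examples
#' pot_volume_box(19.5, 15, 1) # 292.5
#' @export
pot_volume_box <- function(height_cm, width_cm, depth_cm) {
  if (any(c(height_cm, width_cm, depth_cm) <= 0))
    stop("all dimensions must be positive")
  height_cm * width_cm * depth_cm
}

#' End-to-end parameter-recovery experiment
#'
#' Repeats, `n_sims` times: simulate a tree, species effects and a full
#' factorial experiment at the given ground truth, fit both response models,
#' and record each hyperparameter's posterior mean, 95% credible interval,
#' whether the interval covers the truth, and the convergence gate. Fits
#' that fail the gate are kept in the table but excluded from the aggregate
#' bias/coverage attributes (with a message).
#'
#' @param truth_biomass,truth_ratio [truth_params()] objects.
#' @param design A [design_spec()].
#' @param n_sims Number of simulated experiments.
#' @param seed Integer seed; simulation i uses seed + i.
#' @param chains,iterations,warmup Sampler configuration per fit.
#' @return A data.frame with one row per (simulation, response,
#'   hyperparameter); attributes `aggregate` (bias and empirical coverage
#'   per response x hyperparameter over converged fits) and `n_nonconverged`.
#' @export
recovery_experiment <- function(truth_biomass = truth_params("biomass"),
                                truth_ratio = truth_params("ratio"),
                                design = design_spec(),
                                n_sims = 5, seed = 1,
                                chains = 2, iterations = 1500, warmup = 750) {
  stopifnot(n_sims >= 1)
  truths <- list(biomass = truth_biomass, ratio = truth_ratio)
  rows <- list()
  for (i in seq_len(n_sims)) {
    s0 <- seed + i
    tree <- simulate_tree(design$S, seed = s0)
    C <- phylo_correlation(tree)
    eff <- list(
      biomass = simulate_species_effects(C, truth_biomass, seed = s0 + 10000L),
      ratio = simulate_species_effects(C, truth_ratio, seed = s0 + 20000L))
    records <- simulate_experiment(eff$biomass, eff$ratio, design,
                                   sigma_biomass = truth_biomass$sigma,
                                   sigma_ratio = truth_ratio$sigma,
                                   seed = s0 + 30000L)
    prepared <- prepare_dataset(records, species_order = tree$tip.label)
    for (resp in c("biomass", "ratio")) {
      fit <- fit_phlm(prepared, C, response = resp, chains = chains,
                      iterations = iterations, warmup = warmup,
                      seed = s0 + 40000L)
      tr <- truths[[resp]]
      truth_vec <- c(mu_alpha = unname(tr$mu["alpha"]),
                     mu_beta1 = unname(tr$mu["beta1"]),
                     mu_beta2 = unname(tr$mu["beta2"]),
                     mu_beta3 = unname(tr$mu["beta3"]),
                     stats::setNames(unname(tr$lambda), paste0("lambda_", .effect_names)),
                     stats::setNames(unname(tr$gamma), paste0("gamma_", .effect_names)),
                     sigma = tr$sigma)
      for (p in names(truth_vec)) {
        sm <- summarize_parameter(fit, p)
        rows[[length(rows) + 1L]] <- data.frame(
          sim = i, response = resp, parameter = p,
          truth = truth_vec[[p]], mean = sm[["mean"]],
          ci_low = sm[["ci_low"]], ci_high = sm[["ci_high"]],
          covers = truth_vec[[p]] >= sm[["ci_low"]] &
            truth_vec[[p]] <= sm[["ci_high"]],
          converged = fit$convergence$pass, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  conv <- out[out$converged, , drop = FALSE]
  n_bad <- length(unique(paste(out$sim, out$response)[!out$converged]))
  if (n_bad > 0)
    message(n_bad, " fit(s) failed the convergence gate and are excluded from aggregates")
  agg <- do.call(rbind, lapply(split(conv, list(conv$response, conv$parameter)),
    function(g) data.frame(response = g$response[1], parameter = g$parameter[1],
                           bias = mean(g$mean - g$truth),
                           coverage = mean(g$covers), n = nrow(g),
                           stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  attr(out, "aggregate") <- agg
  attr(out, "n_nonconverged") <- n_bad
  out
}

#' Write a miniature synthetic dataset to disk
#'
#' Emits the same CSV and Newick formats the real-data path consumes: a
#' record table and its matching ultrametric tree.
#'
#' @param dir Output directory (created if needed).
#' @param S,seed Passed to the generator.
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_synthetic_fixture <- function(dir, S = 15, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(S, seed = seed)
  design <- design_spec(S = S)
  tb <- truth_params("biomass")
  tr <- truth_params("ratio")
  eff_b <- simulate_species_effects(tree, tb, seed = seed + 1L)
  eff_r <- simulate_species_effects(tree, tr, seed = seed + 2L)
  records <- simulate_experiment(eff_b, eff_r, design,
                                 sigma_biomass = tb$sigma,
                                 sigma_ratio = tr$sigma, seed = seed + 3L)
  csv <- file.path(dir, "biomass_records.csv")
  nwk <- file.path(dir, "species_tree.nwk")
  utils::write.csv(records[, c("species_id", "pot_type", "nutrient",
                               "root_mass_mg", "shoot_mass_mg")],
                   csv, row.names = FALSE)
  ape::write.tree(tree, nwk)
  invisible(c(records = csv, tree = nwk))
}
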