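test_that("simulated trees are ultrametric, unit depth, and seed-reproducible", {
  tr <- simulate_tree(15, seed = 4)
  expect_equal(ape::Ntip(tr), 15)
  depths <- ape::node.depth.edgelength(tr)[1:15]
  expect_true(all(abs(depths - 1) < 1e-9))
  expect_identical(ape::write.tree(simulate_tree(15, seed = 4)),
                   ape::write.tree(tr))
  expect_false(identical(ape::write.tree(simulate_tree(15, seed = 5)),
                         ape::write.tree(tr)))
  expect_error(simulate_tree(1), "at least 2")
  # a basal split means two tips share nothing: identity correlation
  C2 <- phylo_correlation(simulate_tree(2, seed = 1))
  expect_equal(unclass(C2), diag(2), ignore_attr = TRUE)
})

test_that("species effects have the prescribed mean and covariance structure", {
  tr <- simulate_tree(6, seed = 10)
  C <- phylo_correlation(tr)
  truth <- truth_params("biomass")
  # gamma -> 0 limit: effects collapse to their mu
  tiny <- truth_params("biomass",
                       gamma = c(alpha = 1e-12, beta1 = 1e-12,
                                 beta2 = 1e-12, beta3 = 1e-12))
  eff0 <- simulate_species_effects(C, tiny, seed = 1)
  expect_equal(unname(eff0$alpha), rep(tiny$mu[["alpha"]], 6), tolerance = 1e-4)
  # Monte-Carlo moments: lambda = 0 -> Var(alpha_s) = gamma_alpha;
  # a correlated pair under lambda = 1 -> Cov = C_ij * gamma_alpha
  ind <- truth_params("biomass",
                      lambda = c(alpha = 0, beta1 = 0, beta2 = 0, beta3 = 0))
  bm <- truth_params("biomass",
                     lambda = c(alpha = 1, beta1 = 1, beta2 = 1, beta3 = 1))
  Cm <- unclass(C)
  off <- which(Cm == max(Cm[row(Cm) != col(Cm)]), arr.ind = TRUE)[1, ]
  n_mc <- 8000
  a_ind <- matrix(NA_real_, n_mc, 2)
  a_bm <- matrix(NA_real_, n_mc, 2)
  for (i in seq_len(n_mc)) {
    a_ind[i, ] <- simulate_species_effects(C, ind, seed = i)$alpha[c(off[1], off[2])]
    a_bm[i, ] <- simulate_species_effects(C, bm, seed = i)$alpha[c(off[1], off[2])]
  }
  g <- truth$gamma[["alpha"]]
  expect_equal(var(a_ind[, 1]), g, tolerance = 0.05)
  expect_lt(abs(cov(a_ind[, 1], a_ind[, 2])), 0.05)
  expect_equal(cov(a_bm[, 1], a_bm[, 2]), Cm[off[1], off[2]] * g,
               tolerance = 0.1)
})

test_that("simulated experiments honour the design and validate cleanly", {
  design <- design_spec(S = 8)
  tr <- simulate_tree(8, seed = 2)
  eb <- simulate_species_effects(tr, truth_params("biomass"), seed = 3)
  er <- simulate_species_effects(tr, truth_params("ratio"), seed = 4)
  rec <- simulate_experiment(eb, er, design, seed = 5)
  expect_no_error(validate_biomass_records(rec))
  counts <- table(rec$species_id, rec$pot_type, rec$nutrient)
  expect_equal(dim(counts), c(8, 2, 2))
  expect_true(all(counts[, "regular", ] >= 5 & counts[, "regular", ] <= 6))
  expect_true(all(counts[, "flat", ] >= 5 & counts[, "flat", ] <= 13))
  expect_true(all(rec$root_mass_mg[rec$root_below_detection] == 0))
})

test_that("noise-free simulation reproduces the cell expectations through the pipeline", {
  design <- design_spec(S = 4)
  tr <- simulate_tree(4, seed = 6)
  eb <- simulate_species_effects(tr, truth_params("biomass"), seed = 7)
  er <- simulate_species_effects(tr, truth_params("ratio"), seed = 8)
  rec <- simulate_experiment(eb, er, design, sigma_biomass = 0,
                             sigma_ratio = 0, seed = 9)
  prep <- prepare_dataset(rec, tr$tip.label)
  d <- prep$data
  exp_b <- expected_response(eb, d$species_index, d$P, d$N)
  exp_r <- expected_response(er, d$species_index, d$P, d$N)
  # only mass rounding at 0.1 mg separates recovered from simulated
  # responses; bound the log error by the rounding relative to each mass
  keep <- !d$root_below_detection
  total_mg <- 1000 * exp(d$log_total_biomass)
  root_mg <- total_mg * exp(d$log_root_shoot) / (1 + exp(d$log_root_shoot))
  shoot_mg <- total_mg / (1 + exp(d$log_root_shoot))
  tol_b <- 0.11 / total_mg + 1e-9
  tol_r <- 0.06 / root_mg + 0.06 / shoot_mg + 1e-9
  expect_true(all(abs(d$log_total_biomass - exp_b)[keep] <= tol_b[keep]))
  expect_true(all(abs(d$log_root_shoot - exp_r)[keep] <= tol_r[keep]))
})

test_that("round-trip recovery error is bounded by rounding and censoring", {
  design <- design_spec(S = 10)
  tr <- simulate_tree(10, seed = 11)
  eb <- simulate_species_effects(tr, truth_params("biomass"), seed = 12)
  er <- simulate_species_effects(tr, truth_params("ratio"), seed = 13)
  set.seed(14)
  rec <- simulate_experiment(eb, er, design, seed = 14)
  prep <- prepare_dataset(rec, tr$tip.label)
  total_back <- 1000 * exp(prep$data$log_total_biomass)
  stored <- apply_detection_limit(rec$root_mass_mg) + rec$shoot_mass_mg
  expect_equal(total_back, as.numeric(stored), tolerance = 1e-9)
})

test_that("lowering the detection limit never flags more records", {
  design <- design_spec(S = 6)
  tr <- simulate_tree(6, seed = 21)
  # small plants so that censoring actually occurs
  small <- truth_params("biomass",
                        mu = c(alpha = -7.5, beta1 = 0.2, beta2 = 1, beta3 = 0.3))
  lowratio <- truth_params("ratio",
                           mu = c(alpha = -3.5, beta1 = 0.1, beta2 = -0.8,
                                  beta3 = -0.1))
  eb <- simulate_species_effects(tr, small, seed = 22)
  er <- simulate_species_effects(tr, lowratio, seed = 23)
  flags <- vapply(c(0.05, 0.1, 0.5), function(lim) {
    sum(simulate_experiment(eb, er, design, detection_limit_mg = lim,
                            seed = 24)$root_below_detection)
  }, numeric(1))
  expect_true(all(diff(flags) >= 0))
  expect_gt(flags[3], 0)
})

test_that("pot volumes follow the frustum and box formulas", {
  expect_equal(round(pot_volume_frustum(7, 5, 8), 1), 290.7)
  expect_equal(pot_volume_box(19.5, 15, 1), 292.5)
  expect_equal(pot_volume_frustum(3, 3, 3), 27)
  a <- 4.2; h <- 2.5
  expect_equal(pot_volume_frustum(a, a, h), a^2 * h)
  expect_equal(pot_volume_box(2, 3, 4), 24)
  expect_error(pot_volume_frustum(0, 5, 8), "positive")
  expect_error(pot_volume_box(1, -1, 1), "positive")
})

test_that("generative density matches the model module on a 3-species toy", {
  tr <- toy_tree()
  C <- phylo_correlation(tr)
  truth <- truth_params("biomass")
  eff <- simulate_species_effects(C, truth, seed = 31)
  fam <- c("alpha", "beta1", "beta2", "beta3")
  st <- list(effects = lapply(eff, unname), mu = truth$mu,
             lambda = truth$lambda, gamma = truth$gamma, sigma = truth$sigma)
  er <- simulate_species_effects(C, truth_params("ratio"), seed = 32)
  rec <- simulate_experiment(eff, er, design_spec(S = 3), seed = 33)
  prep <- prepare_dataset(rec, attr(C, "species_order"))
  expect_equal(log_posterior(st, prep, C, model_spec("biomass")),
               oracle_log_posterior(st, prep, C, "biomass"), tolerance = 1e-8)
})

test_that("fixture writer emits consumable CSV and Newick files", {
  dir <- tempfile()
  paths <- write_synthetic_fixture(dir, S = 5, seed = 3)
  rec <- read_biomass_csv(paths[["records"]])
  tr <- read_newick(file = paths[["tree"]])
  expect_equal(sort(unique(rec$species_id)), sort(tr$tip.label))
  prep <- prepare_dataset(rec, tr$tip.label)
  expect_gt(nrow(prep$data), 0)
})
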