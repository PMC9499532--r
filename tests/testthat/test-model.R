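test_that("near-noiseless data recovers genotype lines to high precision", {
  obs <- simulate_trait_observations(n_geno = 10, n_rep = 3,
                                     var_g_int = 4, var_g_slope = 1e-4,
                                     var_rep = 0.5, var_resid = 1e-8,
                                     seed = 2)
  fit <- suppressMessages(fit_trait_model(obs))
  u_i <- attr(obs, "u_genoi")
  # deviations are centered within the fit; compare after centering truth
  expect_lt(max(abs(fit$u_genoi[names(u_i)] - (u_i - mean(u_i)))), 0.01)
  u_t <- attr(obs, "u_genot")
  expect_lt(max(abs(fit$u_genot[names(u_t)] - (u_t - mean(u_t)))), 1e-3)
  # the fixed intercept absorbs the mean genotype and replicate deviations
  u_r <- attr(obs, "u_rep")
  expect_lt(abs(fit$beta0 - (40 + mean(u_i) + mean(u_r))), 0.2)
  expect_lt(abs(fit$beta1 - (0.05 + mean(u_t))), 0.01)
})

test_that("inputs are validated", {
  obs <- simulate_trait_observations(n_geno = 4, n_rep = 2, seed = 1)
  one <- obs[obs$genotype == "g001", ]
  expect_error(fit_trait_model(one), "single genotype")
  bad <- obs; bad$y[1] <- NA
  expect_error(fit_trait_model(bad), "non-finite")
})

test_that("adding a constant shifts only the intercept", {
  obs <- simulate_trait_observations(n_geno = 8, n_rep = 3, seed = 3)
  f1 <- fit_trait_model(obs)
  obs2 <- obs; obs2$y <- obs2$y + 7
  f2 <- fit_trait_model(obs2)
  expect_equal(f2$beta0, f1$beta0 + 7, tolerance = 1e-6)
  expect_equal(f2$beta1, f1$beta1, tolerance = 1e-6)
  expect_equal(f2$u_genoi, f1$u_genoi, tolerance = 1e-5)
  expect_equal(f2$var_resid, f1$var_resid, tolerance = 1e-4)
})

test_that("fitted values are exactly linear per genotype", {
  fit <- structure(list(beta0 = 10, beta1 = 0.1,
                        u_genoi = c(gA = -1, gB = 0, gC = 1),
                        u_genot = c(gA = 0, gB = 0, gC = 0.1),
                        u_rep = c(r1 = 0),
                        var_geno_int = 1, var_geno_slope = 0,
                        var_rep = 0, var_resid = 1,
                        times = seq(0, 336, 48)),
                   class = "trait_model_fit")
  fv <- fitted_values(fit)
  expect_equal(fv$value_0h, fv$intercept)                 # t = 0
  expect_equal(fv$intercept, c(9, 10, 11))
  # all-zero slope deviations follow the population line
  expect_equal(fv$value_336h[fv$genotype == "gB"], 10 + 0.1 * 336)
  # +0.1/h slope deviation exceeds the population line by 33.6 at 336 h
  expect_equal(fv$value_336h[fv$genotype == "gC"] -
                 (fit$beta0 + fit$u_genoi[["gC"]] + fit$beta1 * 336), 33.6)
  # exact linearity for every genotype and grid point
  for (t in seq(0, 336, 48)) {
    expect_equal(fv[[sprintf("value_%gh", t)]],
                 fv$intercept + fv$slope * t)
  }
})

test_that("heritability follows the variance-component formula", {
  base <- list(var_geno_int = 2, var_geno_slope = 0, var_rep = 0,
               var_resid = 2, times = seq(0, 336, 48))
  expect_equal(broad_sense_heritability(base), 0.5)
  base$var_geno_int <- 0
  expect_equal(broad_sense_heritability(base), 0)
  base$var_resid <- 0
  expect_error(broad_sense_heritability(base), "zero total")
  # slope variance enters through mean(t^2)
  withslope <- list(var_geno_int = 1, var_geno_slope = 1e-4, var_rep = 1,
                    var_resid = 1, times = c(0, 10))
  g <- 1 + 1e-4 * mean(c(0, 100))
  expect_equal(broad_sense_heritability(withslope), g / (g + 2))
  # h2_components round-trips through the formula
  comp <- h2_components(0.45, slope_share = 0.3)
  rt <- broad_sense_heritability(list(var_geno_int = comp$var_g_int,
                                      var_geno_slope = comp$var_g_slope,
                                      var_rep = 1, var_resid = 4,
                                      times = seq(0, 336, 48)))
  expect_equal(rt, 0.45, tolerance = 1e-12)
})

test_that("permuting genotype labels collapses the genetic variance", {
  obs <- simulate_trait_observations(n_geno = 30, n_rep = 4,
                                     var_g_int = 9, var_g_slope = 0,
                                     var_rep = 0.5, var_resid = 1, seed = 5)
  fit <- fit_trait_model(obs)
  set.seed(6)
  perm <- obs
  perm$genotype <- sample(perm$genotype)
  fitp <- suppressMessages(fit_trait_model(perm))
  expect_gt(fit$var_geno_int, 5)
  expect_lt(fitp$var_geno_int, fit$var_geno_int / 5)
})

test_that("variance components are recovered across seeds", {
  ests <- vapply(1:8, function(s) {
    obs <- simulate_trait_observations(n_geno = 50, n_rep = 6,
                                       var_g_int = 4, var_g_slope = 0,
                                       var_rep = 1, var_resid = 1, seed = s)
    fit_trait_model(obs)$var_geno_int
  }, numeric(1))
  expect_lt(abs(mean(ests) - 4) / 4, 0.15)
})

test_that("trajectory clustering separates constructed archetypes", {
  m0 <- matrix(rep(c(50, 50, 50), each = 8), nrow = 3, byrow = TRUE)
  rownames(m0) <- paste0("g", 1:3)
  expect_equal(unique(as.integer(cluster_trajectories(m0 + 1e-9))), 1L)
  set.seed(9)
  days <- 8
  shallow <- matrix(75 + rnorm(10 * days, sd = 1.5), 10, days)
  deep <- matrix(15 + rnorm(10 * days, sd = 1.5), 10, days)
  drift <- matrix(rep(seq(40, 70, length.out = days), each = 10) +
                    rnorm(10 * days, sd = 1.5), 10, days)
  m <- rbind(shallow, deep, drift)
  rownames(m) <- sprintf("g%02d", 1:30)
  cl <- cluster_trajectories(m, cut_distance = 1.75)
  expect_equal(length(unique(cl)), 3)
  expect_equal(unname(unique(cl[1:10])), 1L)    # shallowest labelled first
  expect_equal(unname(unique(cl[11:20])), 3L)   # deepest last
  expect_equal(unname(unique(cl[21:30])), 2L)
  # a cut above the tree height leaves a single cluster
  expect_equal(unique(as.integer(cluster_trajectories(m, 1e6))), 1L)
  expect_error(cluster_trajectories(m[1, , drop = FALSE]), "at least 2")
  # missing cells are imputed by the genotype mean
  m2 <- m; m2[1, 3] <- NA
  cl2 <- cluster_trajectories(m2, 1.75)
  expect_equal(as.integer(cl2), as.integer(cl))
})
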