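# Variance components: standardization, ReML vs oracle, Gibbs, HMC, LRT.

test_that("standardize centres and scales, rejecting degenerate input", {
  v <- standardize(c(1, 2, 3))
  expect_equal(mean(v), 0)
  expect_equal(var(v), 1)
  expect_equal(standardize(v), v, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), "constant")
  expect_error(standardize(c(1, NA, 3)), "missing")
})

test_that("h2 is the genetic share of phenotypic variance", {
  expect_equal(h2_from_components(0.4, 0.6), 0.4)
  expect_equal(h2_from_components(0, 3), 0)
  expect_equal(h2_from_components(0.131, 0.426), 0.131 / 0.557)
  expect_equal(round(h2_from_components(0.131, 0.426), 5), 0.23519)
  expect_error(h2_from_components(0, 0), "undefined")
  expect_error(h2_from_components(-0.1, 0.5), "non-negative")
})

test_that("ReML maximises the restricted likelihood against a dense grid", {
  fx <- fixture_cohort(10, h2 = 0.5, seed = 31)
  keep <- fx$data
  y <- standardize(keep$trait)
  X <- cbind(1, standardize(keep$age))
  G <- grm(fx$pedigree)
  fit <- reml_fit(y, X, G)
  # coarse grid (the acceptance suite runs the full 200x200 version)
  sg <- seq(0.01, 2, length.out = 60)
  se <- seq(0.01, 2, length.out = 60)
  llg <- outer(sg, se, Vectorize(function(a, b) oracle_reml_ll(a, b, y, X, G)))
  expect_gte(fit$loglik, max(llg) - 1e-6)
  # consistency of the two likelihood routes at the optimum
  expect_equal(fit$loglik,
               oracle_reml_ll(fit$sigma_g2, fit$sigma_e2, y, X, G),
               tolerance = 1e-6)
})

test_that("ReML flags boundary estimates without fabricating SDs", {
  found <- FALSE
  for (s in 1:12) {
    set.seed(s)
    ped <- generate_pedigree(20, seed = s)
    y <- rnorm(60)                      # no genetic signal
    fit <- reml_fit(y, cbind(rep(1, 60)), grm(ped))
    expect_gte(fit$sigma_g2, 0)
    if (fit$boundary) {
      found <- TRUE
      expect_equal(fit$sigma_g2, 0)
      expect_true(is.na(fit$h2_sd))
      expect_true(is.na(fit$sigma_g2_sd))
    }
  }
  expect_true(found)
})

test_that("Gibbs chains keep n_iter - burnin draws with exact h2 identity", {
  fx <- fixture_cohort(20, h2 = 0.4, seed = 11)
  fit <- heritability(trait ~ age, fx$data, fx$pedigree, method = "gibbs",
                      niter = 3000, burnin = 500, seed = 2)
  dr <- fit$samples
  expect_equal(nrow(dr), 2500)
  expect_equal(dr$h2, dr$sigma_g2 / (dr$sigma_g2 + dr$sigma_e2))
  expect_true(all(dr$h2 >= 0 & dr$h2 <= 1))
  expect_true(all(dr$sigma_g2 > 0 & dr$sigma_e2 > 0))
  # bitwise reproducibility from the seed
  fit2 <- heritability(trait ~ age, fx$data, fx$pedigree, method = "gibbs",
                       niter = 3000, burnin = 500, seed = 2)
  expect_identical(fit$samples, fit2$samples)
})

test_that("posterior is insensitive to the non-informative prior scale", {
  fx <- fixture_cohort(40, h2 = 0.4, seed = 17)
  f1 <- heritability(trait ~ age, fx$data, fx$pedigree, method = "gibbs",
                     niter = 6000, burnin = 1000, seed = 3,
                     priors = h2_priors(s1 = 0.001, s2 = 0.001))
  f2 <- heritability(trait ~ age, fx$data, fx$pedigree, method = "gibbs",
                     niter = 6000, burnin = 1000, seed = 4,
                     priors = h2_priors(s1 = 0.01, s2 = 0.01))
  expect_lt(abs(f1$h2 - f2$h2), 0.05)
})

test_that("posterior h2 concentrates as families accumulate", {
  # average over replicate cohorts: any single small-cohort draw can land
  # near the boundary, where the posterior SD is not representative
  sd_at <- function(n_fam, seeds) {
    mean(vapply(seeds, function(s) {
      fx <- fixture_cohort(n_fam, h2 = 0.4, seed = s)
      heritability(trait ~ age, fx$data, fx$pedigree, method = "gibbs",
                   niter = 4000, burnin = 500, seed = s)$h2_sd
    }, numeric(1)))
  }
  expect_lt(sd_at(350, 26:28), sd_at(65, 23:25))
})

test_that("leapfrog integration conserves the Hamiltonian at tiny steps", {
  fx <- fixture_cohort(15, h2 = 0.4, seed = 41)
  y <- standardize(fx$data$trait)
  X <- cbind(1, standardize(fx$data$age))
  ed <- eigen(grm(fx$pedigree), symmetric = TRUE)
  yt <- drop(crossprod(ed$vectors, y)); Xt <- crossprod(ed$vectors, X)
  pr <- h2_priors()
  theta <- c(0.1, -0.2, log(0.5), log(0.5))
  set.seed(8); mom <- rnorm(4)
  H0 <- famh2:::hmc_logpost_grad(theta, yt, Xt, ed$values, pr)$lp -
    0.5 * sum(mom^2)
  lf <- famh2:::leapfrog(theta, mom, eps = 1e-4, n_steps = 10,
                         yt, Xt, ed$values, pr)
  H1 <- lf$lp - 0.5 * sum(lf$mom^2)
  expect_lt(abs(H1 - H0), 1e-6)
})

test_that("HMC adapts into the target acceptance band and matches Gibbs", {
  fx <- fixture_cohort(40, h2 = 0.4, seed = 19)
  fh <- heritability(trait ~ age, fx$data, fx$pedigree, method = "hmc",
                     niter = 3000, burnin = 1000, seed = 9)
  expect_equal(nrow(fh$samples), 2000)
  expect_gt(fh$accept_rate, 0.6)
  expect_lt(fh$accept_rate, 0.95)
  expect_equal(fh$samples$h2,
               fh$samples$sigma_g2 /
                 (fh$samples$sigma_g2 + fh$samples$sigma_e2))
  fg <- heritability(trait ~ age, fx$data, fx$pedigree, method = "gibbs",
                     niter = 8000, burnin = 1000, seed = 10)
  expect_lt(abs(fh$h2 - fg$h2), 0.06)
})

test_that("ReML bias vanishes as the cohort grows", {
  # at 10x the base design the estimator mean sits within 0.05 of truth
  # for every generating h2, including the boundary null
  ped <- generate_pedigree(650, seed = 2)
  G <- grm(ped, check_psd = FALSE)
  ed <- eigen(G, symmetric = TRUE)
  n <- nrow(ped)
  X <- cbind(rep(1, n))
  for (h2_true in c(0, 0.2, 0.4, 0.6)) {
    m <- mean(vapply(1:40, function(r) {
      g <- sample_breeding_values(ped, h2_true,
                                  seed = 40000 + 1000 * h2_true * 10 + r)
      set.seed(50000 + 1000 * h2_true * 10 + r)
      y <- g + rnorm(n, sd = sqrt(1 - h2_true))
      reml_fit(y, X, G, ed = ed)$h2
    }, numeric(1)))
    expect_lt(abs(m - h2_true), 0.05)
  }
})

test_that("boundary LRT: nonnegative statistic, valid p, null point mass", {
  stats_null <- vapply(1:60, function(s) {
    fx <- fixture_cohort(25, h2 = 0, seed = 500 + s, beta_age = 0)
    fit <- heritability(trait ~ age, fx$data, fx$pedigree, method = "reml")
    lr <- lrt_h2(fit)
    expect_gte(lr$statistic, 0)
    expect_true(lr$p >= 0 && lr$p <= 1)
    lr$statistic
  }, numeric(1))
  frac_zero <- mean(stats_null < 1e-8)
  expect_gt(frac_zero, 0.3)
  expect_lt(frac_zero, 0.7)
})

test_that("the heritability object supports the standard model methods", {
  fx <- fixture_cohort(30, h2 = 0.4, seed = 55)
  d <- fx$data
  d$trait[c(3, 10)] <- NA                       # dropped, G subset
  fit <- heritability(trait ~ age, d, fx$pedigree)
  expect_equal(fit$n, 88)
  expect_named(coef(fit), c("(Intercept)", "age"))
  expect_equal(dim(vcov(fit)), c(2, 2))
  expect_equal(fitted(fit) + residuals(fit), fit$y, tolerance = 1e-12)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(88, 3))
  expect_s3_class(summary(fit), "summary.heritability")
  expect_output(print(fit), "heritability")
  expect_error(logLik(heritability(trait ~ age, d, fx$pedigree,
                                   method = "gibbs", niter = 200,
                                   burnin = 50, seed = 1)),
               "ReML")
})
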