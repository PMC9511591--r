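# Random family method: OLS slope, derangement null, empirical p, scan.

test_that("OLS slope recovers exact and hand-computed coefficients", {
  pairs <- data.frame(z = c(1, 2, 3, 4, 5, 6), y = 2 * c(1, 2, 3, 4, 5, 6))
  expect_equal(fit_tau(pairs, character())$tau, 2, tolerance = 1e-12)

  # n = 6 fixture with one covariate, against the normal equations
  pairs <- data.frame(z = c(0.3, -1.2, 0.8, 2.1, -0.4, 1.0),
                      y = c(1.0, -0.7, 0.2, 2.5, 0.1, 0.9),
                      age = c(5, 9, 7, 4, 8, 6))
  fit <- fit_tau(pairs, "age")
  X <- cbind(1, pairs$z, pairs$age)
  expect_equal(fit$tau, oracle_ols(X, pairs$y)[2], tolerance = 1e-10)

  const_z <- data.frame(z = rep(1, 6), y = rnorm(6))
  expect_error(fit_tau(const_z, character()), "z")
  const_cov <- data.frame(z = rnorm(6), y = rnorm(6), c1 = 1)
  expect_error(fit_tau(const_cov, "c1"), "c1")
})

test_that("derangement resampling has no fixed points and is reproducible", {
  set.seed(1)
  for (n in c(3, 5, 12, 65)) {
    for (r in 1:50) {
      p <- famh2:::rderange(n)
      expect_true(all(p != seq_len(n)))
      expect_equal(sort(p), seq_len(n))
    }
  }
  expect_error(famh2:::rderange(2), "3 pairs")

  pairs <- data.frame(z = rnorm(20), y = rnorm(20))
  a <- resample_null(pairs, 200, seed = 7, covariates = character())
  b <- resample_null(pairs, 200, seed = 7, covariates = character())
  expect_identical(a, b)
  c2 <- resample_null(pairs, 200, seed = 8, covariates = character())
  expect_false(identical(a, c2))
  # unrestricted permutations are available behind the flag
  u <- resample_null(pairs, 50, seed = 7, covariates = character(),
                     restricted = FALSE)
  expect_length(u, 50)
})

test_that("empirical p equals c/n exactly with ties as exceedances", {
  ep <- empirical_p(1, c(rep(1.5, 83), rep(0.5, 4917)))
  expect_equal(ep$c, 83)
  expect_equal(ep$n, 5000)
  expect_equal(ep$p, 0.0166)
  expect_equal(empirical_p(10, rnorm(100))$p, 0)          # obs beyond all
  expect_equal(empirical_p(1, rep(-1, 50))$p, 1)          # ties all count
  expect_error(empirical_p(1, numeric(0)), "empty")
})

test_that("affine rescaling of the trait leaves c, n, p invariant", {
  set.seed(42)
  pairs <- data.frame(z = rnorm(40, 120, 15), y = rnorm(40, 110, 12),
                      age = runif(40, 4, 10))
  f1 <- random_family(pairs = pairs, n_resamples = 300, seed = 5)
  pairs2 <- pairs
  pairs2$z <- 7.5 * pairs$z - 40   # e.g. a unit change
  pairs2$y <- 7.5 * pairs$y - 40
  f2 <- random_family(pairs = pairs2, n_resamples = 300, seed = 5)
  expect_identical(c(f1$c, f1$n), c(f2$c, f2$n))
  expect_identical(f1$p, f2$p)
  expect_equal(f2$tau_obs, f1$tau_obs, tolerance = 1e-10)
})

test_that("median empirical p falls as transmission strengthens", {
  meds <- vapply(c(0, 0.45), function(eff) {
    ps <- vapply(1:25, function(r) {
      set.seed(1000 + r)
      z <- rnorm(65)
      y <- eff * z + rnorm(65, sd = sqrt(1 - eff^2))
      random_family(pairs = data.frame(z = z, y = y), n_resamples = 150,
                    seed = 2000 + r)$p
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_lt(meds[2], meds[1])
  expect_lt(meds[2], 0.05)
})

test_that("pairs are extracted pairwise-complete per generation pairing", {
  sim <- generate_dataset(synthetic_config(n_families = 8, seed = 21,
                                           missingness = NULL))
  d <- sim$data
  # one family's child loses PWV: drops from child pairings only
  child3 <- which(d$generation == "child" & d$family_id == "F0003")
  d$pwv[child3] <- NA
  expect_equal(nrow(extract_pairs(d, "pwv", "GC_on_P")), 7)
  expect_equal(nrow(extract_pairs(d, "pwv", "GC_on_GP")), 7)
  expect_equal(nrow(extract_pairs(d, "pwv", "P_on_GP")), 8)
  # covariates come from the offspring row
  pp <- extract_pairs(d, "pwv", "GC_on_P")
  kid <- d[match(pp$offspring_id, d$individual_id), ]
  expect_equal(pp$age, kid$age)
  expect_true(all(kid$generation == "child"))
  # all offspring missing the trait -> insufficient data
  d2 <- sim$data
  d2$cimt_left[d2$generation == "child"] <- NA
  expect_error(extract_pairs(d2, "cimt_left", "GC_on_P"), "insufficient")
})

test_that("stage-1 scan emits one row per trait and pairing", {
  sim <- generate_dataset(synthetic_config(n_families = 30, seed = 13))
  scan <- run_stage1(sim$data, n_resamples = 60, seed = 77)
  expect_equal(nrow(scan), 21)
  ok <- scan$status == "ok"
  expect_true(all(ok))
  expect_equal(scan$p[ok], scan$c[ok] / scan$n[ok])
  expect_equal(scan$significant[ok], scan$p[ok] < 0.05)
  expect_true(all(scan$n[ok] == 60))
  # reproducible from the master seed
  scan2 <- run_stage1(sim$data, n_resamples = 60, seed = 77)
  expect_identical(as.data.frame(scan), as.data.frame(scan2))
  # a two-family dataset cannot form a null: every row flagged
  tiny <- sim$data[sim$data$family_id %in% c("F0001", "F0002"), ]
  scan3 <- run_stage1(tiny, n_resamples = 20, seed = 1)
  expect_true(all(scan3$status != "ok"))
})

test_that("kernel density of the null integrates to one", {
  set.seed(9)
  draws <- rnorm(4000)
  kd <- kde_tau(draws, tau_obs = 1.2)
  expect_equal(kd$tau_obs, 1.2)
  expect_true(all(kd$y >= 0))
  area <- sum(diff(kd$x) * (head(kd$y, -1) + tail(kd$y, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-3)
  expect_equal(kd$y[which.min(abs(kd$x))], dnorm(0), tolerance = 0.03)
  expect_error(kde_tau(rep(1, 10)), "degenerate")
})
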