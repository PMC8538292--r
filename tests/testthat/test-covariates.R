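test_that("Janmahasatian fat-free mass matches direct evaluation", {
  expect_equal(compute_ffm(70, 1.69, "male"), 54.2, tolerance = 1e-3)
  expect_equal(compute_ffm(70, 1.69, "female"), 44.0, tolerance = 1e-3)
  bmi <- 70 / 1.69^2
  expect_equal(compute_ffm(70, 1.69, "male"), 9270 * 70 / (6680 + 216 * bmi))
  w <- runif(50, 40, 130); h <- runif(50, 1.5, 2.0)
  ffm <- compute_ffm(w, h, rep(c("male", "female"), 25))
  expect_true(all(ffm > 0 & ffm < w))
  expect_error(compute_ffm(0, 1.69, "male"), "positive")
  expect_error(compute_ffm(70, 1.69, "other"), "sex")
})

test_that("covariate equations return the typical values at the reference", {
  p <- individual_parameters(pop_params(), reference_covariates())
  expect_identical(p$cl, 0.277)
  expect_identical(p$vc, 3.57)
  expect_identical(p$vp, 3.30)
  expect_identical(p$ksyn, 9.86e-9)
  expect_identical(p$f, 0.710)
  expect_identical(p$fc0, 213)
  expect_equal(p$r0, 9.86e-9 / 9.26e-10)
})

test_that("covariate effects match hand-evaluated equations", {
  pop <- pop_params()
  bio <- individual_parameters(pop, reference_covariates(bio_naive = TRUE))
  expect_equal(bio$cl, 0.277 * (1 - 0.227))
  expect_equal(bio$cl, 0.214, tolerance = 1e-3)
  big <- individual_parameters(pop, reference_covariates(ffm = 90))
  expect_equal(big$cl, 0.277 * 2^0.598)
  expect_equal(big$cl, 0.419, tolerance = 1e-3)
  expect_equal(big$vc, 3.57 * 2^0.590)
  expect_equal(big$vc, 5.37, tolerance = 1e-3)
  expect_equal(big$vp, 3.30 * 2^0.586)
  crp <- individual_parameters(pop, reference_covariates(crp = 11))
  expect_equal(crp$ksyn, 9.86e-9 * (1 + 0.0846 * 8))
  expect_equal(crp$ksyn, 1.653e-8, tolerance = 1e-3)
  vv <- individual_parameters(pop, reference_covariates(fcgr3a_vv = TRUE))
  expect_identical(vv$f, 0.888)
  noulc <- individual_parameters(pop,
                                 reference_covariates(ulcers_baseline = FALSE))
  expect_identical(noulc$fc0, 102)
})

test_that("clearance is monotone in FFM and albumin; F higher for V/V", {
  pop <- pop_params()
  ffm_grid <- seq(30, 90, by = 10)
  cl_ffm <- vapply(ffm_grid, function(x) {
    individual_parameters(pop, reference_covariates(ffm = x))$cl
  }, numeric(1))
  expect_true(all(diff(cl_ffm) > 0))
  alb_grid <- seq(30, 55, by = 5)
  cl_alb <- vapply(alb_grid, function(x) {
    individual_parameters(pop, reference_covariates(albumin = x))$cl
  }, numeric(1))
  expect_true(all(diff(cl_alb) < 0))
  expect_gt(individual_parameters(pop, reference_covariates(fcgr3a_vv = TRUE))$f,
            individual_parameters(pop, reference_covariates())$f)
})

test_that("extreme albumin making the CL multiplier non-positive errors", {
  expect_error(
    individual_parameters(pop_params(), reference_covariates(albumin = 104)),
    "albumin")
})

test_that("sampled IIV reproduces the published CV magnitudes", {
  pop <- pop_params()
  set.seed(99)
  n <- 1e5
  eta <- sample_random_effects(pop, n)
  cov <- reference_covariates()[rep(1, n), ]
  pars <- individual_parameters(pop, cov, eta)
  cv <- function(x) sd(x) / mean(x)
  expect_equal(cv(pars$cl / 0.277), 0.180, tolerance = 0.02)
  expect_equal(cv(pars$fc0 / 213), 0.990, tolerance = 0.03)
  expect_equal(cv(pars$ksyn / 9.86e-9), 0.992, tolerance = 0.03)
  # logit-scale SD on F
  expect_equal(sd(qlogis(pars$f) - qlogis(0.710)), 0.173, tolerance = 0.02)
  # median preservation under exponential IIV
  expect_equal(median(pars$cl), 0.277, tolerance = 0.005)
  expect_equal(median(pars$fc0), 213, tolerance = 0.02)
  # direct-SD reading differs materially only for the large magnitudes
  set.seed(99)
  eta2 <- sample_random_effects(pop, n, scale = "direct-sd")
  expect_equal(sd(eta2$eta_cl), 0.180, tolerance = 0.02)
  expect_gt(cv(exp(eta2$eta_ksyn)), 1.2)  # 0.992 log-SD implies CV ~ 1.3
})

test_that("all-zero random effects give the typical subject", {
  eta0 <- data.frame(eta_cl = 0, eta_vc = 0, eta_vp = 0, eta_f = 0,
                     eta_ksyn = 0, eta_fc0 = 0)
  p0 <- individual_parameters(pop_params(), reference_covariates(), eta0)
  expect_identical(p0$cl, 0.277)
  expect_identical(p0$f, 0.710)
})
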