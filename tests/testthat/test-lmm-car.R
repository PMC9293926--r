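# The air-water mixed model: design construction, CAR correlation,
# likelihood against a dense oracle, reductions, inference and LRT.

test_that("continuous AR(1) correlation has its closed form and decays", {
  expect_equal(car_correlation(0.37, 0), 1)
  expect_equal(car_correlation(0.5, 2), 0.25)
  expect_equal(car_correlation(0.962, 1), 0.962)
  # strictly decreasing in the gap for phi in (0,1)
  for (phi in c(0.1, 0.5, 0.962)) {
    v <- car_correlation(phi, seq(0, 10, by = 0.5))
    expect_true(all(diff(v) < 0))
  }
  expect_error(car_correlation(0.5, -1), "non-negative")
  expect_error(car_correlation(1.2, 1), "phi")
})

test_that("design matrix lays out intercept, air, catchment dummies, covariates", {
  sites <- generate_sites(12, 4, seed = 2)
  truth <- truth_params("day")
  sim <- simulate_paired_obs(12, 6, truth, seed = 2)
  d <- build_design(sim$paired, sim$sites, lmm_spec(env_covariates(), "day"))
  expect_equal(colnames(d$X),
               c("(Intercept)", "air", "catchmentKiso", "catchmentSorachi",
                 "catchmentTeshio", env_covariates()))
  expect_equal(ncol(d$X), 10)           # 1 + 1 + 3 dummies + 5 covariates
  expect_equal(d$col_class,
               c("within", "within", rep("between", 8)))

  # single catchment: no dummy columns
  sim1 <- simulate_paired_obs(6, 6, truth, n_catchments = 1, seed = 3)
  d1 <- build_design(sim1$paired, sim1$sites, lmm_spec("elevation", "day"))
  expect_equal(colnames(d1$X), c("(Intercept)", "air", "elevation"))

  # site without covariates is a data error
  expect_error(build_design(sim$paired, sim$sites[-1, ],
                            lmm_spec(character(0))), "without covariates")
  dup <- rbind(sim$paired, sim$paired[1, ])
  expect_error(build_design(dup, sim$sites, lmm_spec(character(0))),
               "duplicated time")
})

test_that("block likelihood equals the dense stacked evaluation", {
  for (seed in c(101, 202)) {
    inst <- random_small_instance(seed)
    for (corr in c("car1", "none")) {
      d <- build_design(inst$paired, inst$sites,
                        lmm_spec("elevation", "day", corr, "ML"))
      D <- matrix(c(0.9, 0.03, 0.03, 0.04), 2, 2)
      phi <- if (corr == "car1") 0.85 else 0
      expect_equal(lmm_loglik(d, D, 1.1, phi, method = "ML"),
                   dense_loglik(d, D, 1.1, phi, method = "ML"),
                   tolerance = 1e-10)
      expect_equal(lmm_loglik(d, D, 1.1, phi, method = "REML"),
                   dense_loglik(d, D, 1.1, phi, method = "REML"),
                   tolerance = 1e-10)
    }
  }
})

test_that("two standard-normal points at zero residual give -log(2*pi)", {
  p2 <- data.frame(site_id = c("A", "A"), t = 1:2, Ta = c(0, 0),
                   Tw = c(0, 0))
  s2 <- data.frame(site_id = "A", catchment = "H")
  d2 <- build_design(p2, s2, lmm_spec(character(0), "day", "none", "ML"))
  ll <- lmm_loglik(d2, matrix(0, 2, 2), sigma = 1, beta = c(0, 0),
                   method = "ML")
  expect_equal(ll, -log(2 * pi), tolerance = 1e-12)
})

test_that("phi = 0 CAR likelihood equals the independent-error likelihood", {
  inst <- random_small_instance(77)
  d_car <- build_design(inst$paired, inst$sites,
                        lmm_spec("elevation", "day", "car1", "ML"))
  d_none <- build_design(inst$paired, inst$sites,
                         lmm_spec("elevation", "day", "none", "ML"))
  D <- matrix(c(0.5, 0, 0, 0.01), 2, 2)
  expect_equal(lmm_loglik(d_car, D, 1.2, phi = 0),
               lmm_loglik(d_none, D, 1.2), tolerance = 1e-12)
})

test_that("without random effects and correlation the ML fit is OLS", {
  truth <- truth_params("day", tau00 = 0, tau11 = 0, phi = 0, sigma = 1)
  sim <- simulate_paired_obs(10, 12, truth, seed = 5)
  spec <- lmm_spec(c("elevation", "riparian_forest"), "day", "none", "ML",
                   random = FALSE)
  f <- fit_lmm(sim$paired, sim$sites, spec)
  d <- f$design
  ols <- lm.fit(d$X, d$y)
  expect_equal(unname(f$beta), unname(ols$coefficients), tolerance = 1e-8)
  expect_equal(f$sigma^2, sum(ols$residuals^2) / d$N, tolerance = 1e-8)
  expect_equal(f$tau00, 0)
  expect_equal(f$tau11, 0)

  # the full random-effects ML fit on the same no-group-effect data agrees
  # with OLS closely (D collapses towards zero)
  ffree <- fit_lmm(sim$paired, sim$sites,
                   lmm_spec(c("elevation", "riparian_forest"), "day",
                            "none", "ML"))
  expect_equal(unname(ffree$beta), unname(ols$coefficients),
               tolerance = 1e-3)
  expect_lt(ffree$tau00, 0.15)
})

test_that("row order of the input does not change the fit", {
  truth <- truth_params("day", phi = 0.5)
  sim <- simulate_paired_obs(8, 10, truth, seed = 6)
  spec <- lmm_spec("elevation", "day", "car1", "REML")
  f1 <- fit_lmm(sim$paired, sim$sites, spec)
  set.seed(1)
  shuffled <- sim$paired[sample(nrow(sim$paired)), ]
  f2 <- fit_lmm(shuffled, sim$sites[sample(nrow(sim$sites)), ], spec)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  expect_equal(f1$phi, f2$phi, tolerance = 1e-7)
})

test_that("estimates agree with the reference mixed-model implementation", {
  skip_if_not_installed("nlme")
  truth <- truth_params("day", phi = 0.6, tau00 = 1, tau11 = 0.08, sigma = 1)
  sim <- simulate_paired_obs(25, 40, truth, seed = 11)
  spec <- lmm_spec(c("elevation", "riparian_forest"), "day", "car1", "REML")
  f <- fit_lmm(sim$paired, sim$sites, spec)
  dat <- merge(sim$paired, sim$sites, by = "site_id")
  g <- nlme::lme(Tw ~ Ta + catchment + elevation + riparian_forest,
                 random = ~Ta | site_id,
                 correlation = nlme::corCAR1(form = ~t | site_id),
                 data = dat, method = "REML",
                 control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                            msMaxIter = 200))
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-5)
  expect_equal(unname(f$beta), unname(nlme::fixef(g)), tolerance = 1e-3)
  vc <- nlme::VarCorr(g)
  expect_equal(f$sigma, as.numeric(vc["Residual", "StdDev"]),
               tolerance = 1e-2)
  expect_equal(f$tau00, as.numeric(vc["(Intercept)", "StdDev"]),
               tolerance = 1e-2)
  expect_equal(f$phi,
               as.numeric(coef(g$modelStruct$corStruct,
                               unconstrained = FALSE)),
               tolerance = 1e-2)
})

test_that("duplicated covariate columns are a data error", {
  truth <- truth_params("day")
  sim <- simulate_paired_obs(6, 8, truth, seed = 8)
  sim$sites$elevation2 <- sim$sites$elevation
  expect_error(fit_lmm(sim$paired, sim$sites,
                       lmm_spec(c("elevation", "elevation2"), "day")),
               "collinear")
})

test_that("between-within inference table has the documented structure", {
  truth <- truth_params("month")
  sim <- simulate_paired_obs(30, 8, truth, seed = 9)
  f <- fit_lmm(sim$paired, sim$sites,
               lmm_spec(env_covariates(), "month", "none", "REML"))
  tab <- fixed_inference(f)
  expect_equal(tab$term, colnames(f$design$X))
  expect_equal(tab$t, tab$coef / tab$se, tolerance = 1e-12)
  # df rule: 8 between-site terms (3 dummies + 5 covariates)
  expect_equal(tab$df[tab$term == "elevation"], 30 - 8 - 1)
  expect_equal(tab$df[tab$term == "air"], f$n_obs - 30 - 1)
  expect_equal(tab$df[tab$term == "(Intercept)"], f$n_obs - 30 - 1)
  expect_equal(tab$p, 2 * pt(-abs(tab$t), tab$df), tolerance = 1e-12)
  # the air term's df is in the thousands, so its p is normal-limit close
  i <- tab$term == "air"
  expect_equal(tab$p[i], 2 * pnorm(-abs(tab$t[i])), tolerance = 1e-3)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})

test_that("likelihood-ratio comparison refits with ML and counts parameters", {
  truth <- truth_params("month")
  sim <- simulate_paired_obs(100, 10, truth, seed = 10)
  spec_full <- lmm_spec(env_covariates(), "month", "none", "REML")
  spec_base <- lmm_spec(character(0), "month", "none", "REML")
  f1 <- fit_lmm(sim$paired, sim$sites, spec_full)
  f0 <- fit_lmm(sim$paired, sim$sites, spec_base)
  out <- lrt_compare(f0, f1)
  expect_equal(out$df, 5)
  # injected covariate effects at the study's site count: strong evidence
  expect_lt(out$p, 1e-4)

  same <- lrt_compare(f1, f1)
  expect_equal(same$chi2, 0, tolerance = 1e-6)
  expect_equal(same$p, 1)

  spec_car <- lmm_spec(character(0), "month", "car1", "REML")
  f0c <- fit_lmm(sim$paired, sim$sites, spec_car)
  expect_error(lrt_compare(f0c, f1), "structure")
})
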