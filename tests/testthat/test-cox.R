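# Cox partial likelihood, Newton fitting, stage-wise hazard models.

test_that("partial log-likelihood matches hand enumeration and the
           brute-force oracle", {
  # two subjects, distinct event times, beta = 0: risk sets {1,2},{2}
  expect_equal(cox_partial_loglik(c(1, 2), c(1, 1), matrix(c(0, 1)), 0),
               -log(2))
  # Efron = Breslow when no event times are tied
  tt <- c(1, 2, 3, 5, 8)
  ev <- c(1, 0, 1, 1, 1)
  x <- matrix(c(0, 1, 1, 0, 1))
  for (b in c(-1, 0, 0.7)) {
    expect_equal(cox_partial_loglik(tt, ev, x, b, "efron"),
                 cox_partial_loglik(tt, ev, x, b, "breslow"))
  }
  # brute-force risk-set oracle across fixtures, methods and betas
  for (fx in cox_fixtures()) {
    for (m in c("efron", "breslow")) {
      for (b in c(-0.8, 0, 1.3)) {
        expect_equal(cox_partial_loglik(fx$time, fx$event,
                                        matrix(fx$x), b, m),
                     brute_cox_loglik(fx$time, fx$event,
                                      matrix(fx$x), b, m),
                     tolerance = 1e-12)
      }
    }
  }
  # duplicating every subject: Breslow value from the duplicated data
  # equals the brute-force recomputation on the enlarged risk sets
  fx <- cox_fixtures()[[2]]
  t2 <- rep(fx$time, 2)
  e2 <- rep(fx$event, 2)
  x2 <- matrix(rep(fx$x, 2))
  expect_equal(cox_partial_loglik(t2, e2, x2, 0.4, "breslow"),
               brute_cox_loglik(t2, e2, x2, 0.4, "breslow"),
               tolerance = 1e-12)
  expect_error(cox_partial_loglik(c(1, 2), c(0, 0), matrix(c(0, 1)), 0),
               "no events")
})

test_that("Newton fit maximizes the partial likelihood (grid-search
           oracle on all small fixtures)", {
  for (m in c("efron", "breslow")) {
    for (fx in cox_fixtures()) {
      fit <- cox_fit(fx$time, fx$event, matrix(fx$x), tie_method = m)
      oracle <- brute_cox_gridfit(fx$time, fx$event, fx$x, method = m)
      expect_lt(abs(unname(fit$coef) - oracle), 1e-3)
      # likelihood at the optimum never below the null value
      expect_gte(fit$loglik, fit$loglik_null)
    }
  }
})

test_that("symmetric data give a zero coefficient and separation is
           flagged as monotone likelihood", {
  # mirror-image event/time patterns across groups
  fit <- cox_fit(c(1, 2, 1, 2), c(1, 0, 1, 0), matrix(c(0, 0, 1, 1)))
  expect_lt(abs(unname(fit$coef)), 1e-6)
  # events only in one group: monotone likelihood
  fit2 <- cox_fit(c(1, 2, 3, 4), c(1, 1, 0, 0), matrix(c(0, 0, 1, 1)))
  expect_false(fit2$converged)
  expect_true(fit2$monotone)
  # all-event data where one group's events all precede the other's is
  # also monotone: the partial likelihood rises without bound
  fit3 <- cox_fit(c(1, 2, 3, 4), c(1, 1, 1, 1), matrix(c(0, 0, 1, 1)))
  expect_true(fit3$monotone)
  expect_error(cox_fit(c(1, 2), c(1, 1), matrix(c(1, 1))), "degenerate")
})

test_that("fits are invariant to time rescaling and agree with the
           survival package", {
  skip_if_not_installed("survival")
  set.seed(21)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  tt <- sample(5:25, n, replace = TRUE)
  ev <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  fit <- cox_fit(tt, ev, matrix(x, dimnames = list(NULL, "x")))
  fit_scaled <- cox_fit(tt * 3.7, ev, matrix(x))
  expect_equal(unname(fit$coef), unname(fit_scaled$coef),
               tolerance = 1e-10)
  for (m in c("efron", "breslow")) {
    ours <- cox_fit(tt, ev, matrix(x), tie_method = m)
    ref <- survival::coxph(survival::Surv(tt, ev) ~ x, ties = m)
    expect_equal(unname(ours$coef), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(ours$se),
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  }
})

test_that("stage-wise fitting subsets correctly, skips degenerate stages
           and is reparameterization-consistent", {
  tab <- degenerate_table()
  set.seed(22)
  rec <- simulate_experiment(design_config(8L, 5:60, seed = 23L))
  imp <- impute_stages(rec, tab)
  # all records forced to L4: one fitted stage, four skipped markers
  one <- imp
  one$stage_at_parasitism <- "L4"
  fits <- fit_stage_hazards(one)
  expect_s3_class(fits[["L4"]], "cox_fit")
  skipped <- vapply(fits[setdiff(names(fits), "L4")], inherits,
                    logical(1), "skipped_stage")
  expect_true(all(skipped))
  # exchanging the roles of 90 and 100 (reference moved to 90) negates
  # the corresponding contrast: a pure reparameterization of the model
  f1 <- fit_stage_hazards(imp, reference = "100")
  f2 <- fit_stage_hazards(imp, reference = "90")
  expect_equal(unname(f1[["L4"]]$coef["90 vs 100"]),
               -unname(f2[["L4"]]$coef["100 vs 90"]), tolerance = 1e-6)
  expect_error(fit_stage_hazards(rec), "unstaged")
})

test_that("null-effect generator yields coefficients consistent with
           zero across seeded runs", {
  dev0 <- null_dev_params()
  cover <- 0
  tries <- 0
  for (s in 1:25) {
    cfg <- design_config(3L, 5:60, seed = 400L + s)
    rec <- simulate_experiment(cfg, dev = dev0)
    ref <- generate_reference_table(dev0, cfg, n_per_cell = 30L,
                                    seed = 500L + s)
    tab <- estimate_stage_distribution(ref)
    set.seed(600L + s)
    imp <- impute_stages(rec, tab)
    fits <- fit_stage_hazards(imp, stages = c("L3", "L4", "P"))
    for (f in fits) {
      if (inherits(f, "skipped_stage") || !f$converged) next
      tries <- tries + length(f$coef)
      cover <- cover + sum(abs(f$coef) <= 2 * f$se)
    }
  }
  expect_gte(cover / tries, 0.90)
})
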