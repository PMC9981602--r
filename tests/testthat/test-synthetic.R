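# Synthetic exposure-experiment generator.

test_that("design enumeration follows the factorial product rule", {
  d <- build_design(design_config(54L, 5:60, c("90", "95", "100")))
  expect_equal(nrow(d), 9072L)
  expect_equal(length(unique(d$host_id)), 9072L)
  expect_true(all(is.na(d$parasitized)))

  expect_equal(nrow(build_design(design_config(1L, 5L, "100"))), 1L)
  expect_equal(nrow(build_design(design_config(2L, 5:7, c("a", "b")))), 12L)

  set.seed(41)
  for (i in 1:10) {
    nr <- sample(1:20, 1)
    ages <- sort(sample(1:80, sample(2:30, 1)))
    nq <- sample(1:4, 1)
    cfg <- design_config(nr, ages, paste0("q", seq_len(nq)))
    expect_equal(nrow(build_design(cfg)), nr * length(ages) * nq)
  }
})

test_that("invalid designs are rejected", {
  expect_error(design_config(0L), "n_replicates")
  expect_error(design_config(1L, integer(0)), "ages")
  expect_error(design_config(1L, c(5L, 5L)), "ages")
  expect_error(design_config(1L, 5:10, character(0)), "qualities")
  expect_error(design_config(1L, 5:10, c("90", "90")), "qualities")
})

test_that("development trajectories respect quality-scaled boundaries", {
  p <- host_dev_params(transition_noise_sd = 0)
  # pre-first-molt: stage L1 at age 0 whatever the parameters
  tr <- simulate_development_trajectory(p, "100")
  expect_equal(parastage:::stage_at_age(tr$boundaries, 0), "L1")
  # a 22% delay scales a 20 d boundary to 24.4 d multiplicatively
  p2 <- host_dev_params(
    baseline_transition_ages = c(L2 = 5, L3 = 9, L4 = 13, P = 20, A = 28),
    delay_factor = c("90" = 1.22, "95" = 1.014, "100" = 1),
    transition_noise_sd = 0)
  tr2 <- simulate_development_trajectory(p2, "90")
  expect_equal(unname(tr2$boundaries[["P"]]), 24.4)
  expect_error(simulate_development_trajectory(p, "85"), "unknown treatment")
  # biomass nondecreasing and saturating below the quality asymptote
  b <- tr$biomass(0:60)
  expect_true(all(diff(b) >= 0))
  expect_lt(max(b), p$biomass_asymptote)
})

test_that("stage occupancy over many trajectories matches the configured
           lognormal boundary distribution", {
  p <- host_dev_params(transition_noise_sd = 0.1)
  set.seed(7)
  n <- 10000
  noise <- rlnorm(n, 0, 0.1)
  # Monte-Carlo oracle computed directly from the boundary model: at age
  # a the host is past boundary k iff a >= b_k * noise
  for (a in c(10, 18, 25)) {
    mc_frac <- colMeans(outer(noise, p$baseline_transition_ages,
                              function(z, b) a >= b * z))
    # package path: reference table cell frequencies at large n
    cfg <- design_config(1L, a, "100")
    ref <- generate_reference_table(p, cfg, n_per_cell = 10000, seed = 8)
    past <- vapply(2:6, function(k) {
      mean(match(ref$stage, parastage::stage_levels()) >= k)
    }, numeric(1))
    expect_equal(past, unname(mc_frac), tolerance = 0.02)
  }
})

test_that("exposure outcomes follow the configured attack probabilities", {
  skel <- build_design(design_config(1L, 18L, "100"))
  pp0 <- parasitism_params(attack_success = setNames(rep(0, 6),
                                                     stage_levels()))
  pp1 <- parasitism_params(attack_success = setNames(rep(1, 6),
                                                     stage_levels()))
  set.seed(1)
  expect_equal(simulate_exposure_outcome(skel, "L4", pp0)$parasitized, 0L)
  out1 <- simulate_exposure_outcome(skel, "L4", pp1)
  expect_equal(out1$parasitized, 1L)
  expect_equal(out1$stage_at_parasitism, "L4")
  expect_gte(out1$n_eggs, 1L)
  # binomial expectation oracle at p = 0.6
  pp <- parasitism_params(attack_success = c(L1 = 0, L2 = 0, L3 = 0,
                                             L4 = 0.6, P = 0, A = 0))
  set.seed(2)
  hits <- replicate(10000, simulate_exposure_outcome(skel, "L4",
                                                     pp)$parasitized)
  expect_equal(mean(hits), 0.6, tolerance = 3 * sqrt(0.6 * 0.4 / 10000) / 0.6)
  expect_error(simulate_exposure_outcome(out1, "L4", pp), "skeleton")
  expect_error(parasitism_params(attack_success = c(L1 = -0.1, L2 = 0,
                                                    L3 = 0, L4 = 0, P = 0,
                                                    A = 0)), "\\[0, 1\\]")
})

test_that("parasitoid traits reproduce the configured sex and
           development-time structure", {
  tp <- parasitoid_trait_params()
  rec <- build_design(design_config(1L, 30L, "100"))
  rec$parasitized <- 1L
  rec$stage_at_parasitism <- "L4"
  rec$n_eggs <- 1L
  # degenerate sex allocation: midpoint far below any age => all female
  tp_f <- parasitoid_trait_params(p_female_midpoint = -1000)
  set.seed(3)
  out <- simulate_parasitoid_traits(rec, tp_f)
  expect_equal(out$sex, "female")
  # configured-mean recovery: female dev-time excess
  set.seed(4)
  n <- 10000
  ages <- rep(30L, n)
  draws <- vapply(seq_len(n), function(i) {
    r <- simulate_parasitoid_traits(rec, tp)
    c(female = r$sex == "female", dt = r$development_time)
  }, numeric(2))
  dt <- draws[2, ]
  fem <- draws[1, ] == 1
  expect_equal(mean(dt[fem]) - mean(dt[!fem]), tp$devtime_female_excess,
               tolerance = 0.1)
  # plateau: expected tibia equal at two ages beyond the plateau age
  mu <- function(a) tp$tibia_base + tp$tibia_gain *
    min(a, tp$tibia_plateau_age) / tp$tibia_plateau_age
  expect_equal(mu(30), mu(55))
  expect_error(simulate_parasitoid_traits(build_design(
    design_config(1L, 30L, "100")), tp), "parasitized")
})

test_that("reference tables reflect the trajectory distribution", {
  p0 <- host_dev_params(transition_noise_sd = 0)
  cfg <- design_config(1L, c(10L, 20L), c("90", "100"))
  r1 <- generate_reference_table(p0, cfg, n_per_cell = 1L, seed = 5)
  expect_equal(nrow(r1), 4L)
  # zero noise: every record in a cell has the identical stage
  r2 <- generate_reference_table(p0, cfg, n_per_cell = 25L, seed = 6)
  per_cell <- tapply(r2$stage, paste(r2$quality, r2$age),
                     function(s) length(unique(s)))
  expect_true(all(per_cell == 1L))
  expect_error(generate_reference_table(p0, cfg, n_per_cell = 0L), ">= 1")
})

test_that("stage is missing exactly when unparasitized, and generation is
           seed-reproducible", {
  cfg <- design_config(6L, 5:60, seed = 11L)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a, b)
  expect_identical(is.na(a$stage_at_parasitism), a$parasitized == 0L)
  expect_identical(!is.na(a$n_eggs), a$parasitized == 1L)
  # parasitoid traits only on parasitized hosts
  expect_true(all(is.na(a$sex[a$parasitized == 0L])))
  cfg2 <- cfg
  cfg2$seed <- 12L
  expect_false(identical(a, simulate_experiment(cfg2)))
})

test_that("with no quality effect the treatments are exchangeable", {
  # permutation check on boundary-age surrogates: stage index at a fixed
  # age across treatments, n = 500 hosts
  p <- null_dev_params()
  cfg <- design_config(1L, 20L, c("90", "100"))
  ref <- generate_reference_table(p, cfg, n_per_cell = 250L, seed = 13)
  si <- match(ref$stage, stage_levels())
  grp <- ref$quality == "90"
  obs <- mean(si[grp]) - mean(si[!grp])
  set.seed(14)
  perm <- replicate(500, {
    g <- sample(grp)
    mean(si[g]) - mean(si[!g])
  })
  pval <- mean(abs(perm) >= abs(obs) - 1e-12)
  expect_gt(pval, 0.01)
})
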