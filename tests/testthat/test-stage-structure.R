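# Head-capsule staging, probability tables, imputation.

test_that("head-capsule counts map deterministically to stages", {
  expect_equal(stage_from_head_capsules(0), "L1")
  expect_equal(stage_from_head_capsules(3), "L4")
  expect_equal(stage_from_head_capsules(4), "P")
  expect_equal(stage_from_head_capsules(4, TRUE), "A")
  expect_equal(stage_from_head_capsules(0:4),
               c("L1", "L2", "L3", "L4", "P"))
  expect_error(stage_from_head_capsules(5), "0..4")
  expect_error(stage_from_head_capsules(-1), "0..4")
})

test_that("stage distributions are cellwise relative frequencies that
           sum to one", {
  ref <- data.frame(quality = "95", age = 9L,
                    stage = c("L2", "L2", "L3", "L3"), dry_biomass = 1)
  tab <- estimate_stage_distribution(ref)
  expect_equal(unname(unlist(tab[1, paste0("p_", stage_levels())])),
               c(0, 0.5, 0.5, 0, 0, 0))
  ref2 <- data.frame(quality = "90", age = 20L, stage = rep("L4", 7),
                     dry_biomass = 1)
  tab2 <- estimate_stage_distribution(ref2)
  expect_equal(tab2$p_L4, 1)
  expect_equal(tab2$n, 7L)
  expect_error(estimate_stage_distribution(ref[0, ]), "empty")

  # row normalization within 1e-12 on a generated table
  ref3 <- generate_reference_table(host_dev_params(),
                                   design_config(1L, 5:60), 40L, seed = 2)
  tab3 <- estimate_stage_distribution(ref3)
  sums <- rowSums(tab3[, paste0("p_", stage_levels())])
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("a zero-noise generator yields degenerate cells everywhere", {
  tab <- estimate_stage_distribution(
    generate_reference_table(host_dev_params(transition_noise_sd = 0),
                             design_config(1L, 5:60), 20L, seed = 3))
  pm <- as.matrix(tab[, paste0("p_", stage_levels())])
  expect_true(all(apply(pm, 1, max) == 1))
})

test_that("imputation preserves observed stages, row order and all other
           fields", {
  rec <- toy_records()
  tab <- degenerate_table()
  set.seed(5)
  imp <- impute_stages(rec, tab)
  expect_false(anyNA(imp$stage_at_parasitism))
  obs <- rec$parasitized == 1L
  expect_identical(imp$stage_at_parasitism[obs],
                   rec$stage_at_parasitism[obs])
  expect_identical(imp[, setdiff(names(imp), "stage_at_parasitism")],
                   rec[, setdiff(names(rec), "stage_at_parasitism")])
  # degenerate cells: repeated imputation is deterministic
  imp2 <- impute_stages(rec, tab)
  expect_identical(imp, imp2)
})

test_that("imputation errors loudly on missing cells, with optional
           nearest-age fallback", {
  rec <- toy_records()
  tab <- degenerate_table(ages = c(5:14, 16:60))  # drop age 15
  expect_error(impute_stages(rec, tab), "age = 15")
  imp <- impute_stages(rec, tab, nearest_age = TRUE)
  expect_false(anyNA(imp$stage_at_parasitism))
  # fallback tie-break toward the younger age: ages 14 and 16 both at
  # distance 1 from 15; age 14 wins, whose degenerate stage is L3
  expect_equal(unique(imp$stage_at_parasitism[rec$age_at_exposure == 15 &
                                                rec$parasitized == 0L]),
               "L3")
})

test_that("imputed-stage frequencies converge to the cell probabilities", {
  # binomial oracle on a single cell (0, 0.2, 0.8, 0, 0, 0)
  ref <- data.frame(quality = "90", age = 10L,
                    stage = c(rep("L2", 2), rep("L3", 8)), dry_biomass = 1)
  tab <- estimate_stage_distribution(ref)
  rec <- toy_records()[rep(2L, 100000L), ]
  rec$quality <- "90"
  rec$age_at_exposure <- 10L
  set.seed(6)
  imp <- impute_stages(rec, tab)
  freq <- table(factor(imp$stage_at_parasitism, stage_levels())) / nrow(rec)
  expect_equal(unname(freq[["L3"]]), 0.8, tolerance = 0.01)
  # Kolmogorov distance between imputed frequencies and the cell vector
  expect_lt(max(abs(cumsum(as.numeric(freq)) -
                      cumsum(c(0, 0.2, 0.8, 0, 0, 0)))), 0.01)
})

test_that("stage tables round-trip through their text serialization", {
  tab <- estimate_stage_distribution(
    generate_reference_table(host_dev_params(), design_config(2L, 5:20),
                             10L, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_stage_distribution(tab, path)
  back <- read_stage_distribution(path)
  expect_equal(as.data.frame(tab), as.data.frame(back),
               tolerance = 1e-12, ignore_attr = TRUE)
  write.csv(data.frame(a = 1), path, row.names = FALSE)
  expect_error(read_stage_distribution(path), "missing")
})
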