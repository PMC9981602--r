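# Independent oracles and small fixture builders.

# Brute-force Cox partial log-likelihood by direct risk-set enumeration,
# written independently of the package implementation (plain loops over
# distinct event times; no shared code).
brute_cox_loglik <- function(time, event, x, beta, method = "efron") {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(eta[D])
    for (r in seq_len(d) - 1L) {
      f <- if (method == "efron") r / d else 0
      ll <- ll - log(sum(w[R]) - f * sum(w[D]))
    }
  }
  ll
}

# 1-D grid-search maximizer of the brute-force partial likelihood,
# vectorized over the grid (beta in [-5, 5], step 1e-4)
brute_cox_gridfit <- function(time, event, x, method = "efron",
                              grid = seq(-5, 5, by = 1e-4)) {
  x <- drop(as.matrix(x))
  eta <- outer(x, grid)          # n x G
  w <- exp(eta)
  ll <- numeric(length(grid))
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + colSums(eta[D, , drop = FALSE])
    sR <- colSums(w[R, , drop = FALSE])
    sD <- colSums(w[D, , drop = FALSE])
    for (r in seq_len(d) - 1L) {
      f <- if (method == "efron") r / d else 0
      ll <- ll - log(sR - f * sD)
    }
  }
  grid[which.max(ll)]
}

# small two-group survival fixtures (<= 8 subjects) exercising ties,
# censoring and unbalanced groups
cox_fixtures <- function() {
  list(
    list(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1),
         x = c(0, 1, 0, 1)),
    list(time = c(1, 1, 2, 2, 3), event = c(1, 1, 1, 0, 1),
         x = c(0, 1, 0, 1, 1)),
    list(time = c(2, 2, 2, 5, 5, 7), event = c(1, 0, 1, 1, 1, 0),
         x = c(1, 1, 0, 0, 1, 0)),
    list(time = c(1, 1, 1, 1, 2, 2, 3, 3), event = c(1, 0, 1, 1, 1, 1, 0, 1),
         x = c(0, 0, 1, 1, 0, 1, 0, 1)),
    list(time = c(3, 3, 3, 3, 3, 3), event = c(1, 1, 1, 0, 1, 0),
         x = c(0, 1, 0, 1, 0, 1))
  )
}

# exchangeable-treatment generator settings (no quality effect)
null_dev_params <- function(...) {
  host_dev_params(delay_factor = c("90" = 1, "95" = 1, "100" = 1),
                  size_reduction = c("90" = 0, "95" = 0, "100" = 0), ...)
}

# a tiny staged exposure table built by hand
toy_records <- function() {
  data.frame(
    host_id = sprintf("T%02d", 1:12),
    replicate = rep(1:2, each = 6),
    quality = rep(c("90", "95", "100"), 4),
    age_at_exposure = rep(c(10L, 12L, 15L, 18L), each = 3),
    parasitized = c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 1L),
    stage_at_parasitism = c("L3", NA, "L3", NA, "L3", NA,
                            "L4", "L4", NA, NA, NA, "L4"),
    n_eggs = c(1L, NA, 1L, NA, 2L, NA, 1L, 1L, NA, NA, NA, 1L),
    host_died = FALSE,
    host_emerged = FALSE,
    sex = NA_character_,
    parasitoid_emerged = NA_integer_,
    development_time = NA_real_,
    emergence_mass = NA_real_,
    hind_tibia_length = NA_real_,
    stringsAsFactors = FALSE)
}

# degenerate stage-distribution table: every cell a point mass on a
# fixed stage per age band
degenerate_table <- function(qualities = c("90", "95", "100"),
                             ages = 5:60) {
  ref <- expand.grid(quality = qualities, age = ages,
                     stringsAsFactors = FALSE)
  ref$stage <- ifelse(ref$age < 12, "L2",
                      ifelse(ref$age < 16, "L3",
                             ifelse(ref$age < 22, "L4",
                                    ifelse(ref$age < 29, "P", "A"))))
  ref$dry_biomass <- 1
  estimate_stage_distribution(ref)
}
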