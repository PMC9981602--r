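# Synthetic exposure experiment.
#
# Emulates the cross-sectional design of the seed-beetle / pteromalid
# study the package analyses: single-egg artificial seeds along a
# flour-dilution quality gradient, one seed per host age per replicate
# removed daily and exposed to a mated female parasitoid for 24 h.
# Quality dilutes development rate and asymptotic biomass; parasitism
# success depends on the developmental stage the host occupies on its
# exposure day; parasitoid life-history traits depend on host stage/age
# and parasitoid sex.

#' Experimental design configuration
#'
#' @param n_replicates Number of replicate exposure series per treatment.
#' @param ages Integer host ages (days since oviposition) at exposure;
#'   must be strictly increasing. Default the study design `5:60`.
#' @param qualities Treatment labels, percent flour in the artificial
#'   seed. Default `c("90", "95", "100")`.
#' @param seed RNG seed for dataset generation.
#' @return A `design_config` list.
#' @export
design_config <- function(n_replicates = 54L, ages = 5:60,
                          qualities = c("90", "95", "100"), seed = 1L) {
  n_replicates <- as.integer(n_replicates)
  ages <- as.integer(ages)
  qualities <- as.character(qualities)
  if (length(n_replicates) != 1L || is.na(n_replicates) || n_replicates < 1L)
    stop("invalid design: n_replicates must be a positive integer")
  if (length(ages) == 0L || any(diff(ages) <= 0))
    stop("invalid design: ages must be nonempty and strictly increasing")
  if (length(qualities) == 0L || anyDuplicated(qualities))
    stop("invalid design: qualities must be nonempty and distinct")
  structure(list(n_replicates = n_replicates, ages = ages,
                 qualities = qualities, seed = as.integer(seed)),
            class = "design_config")
}

#' Host development parameters
#'
#' Stage-boundary ages at 100% quality, a per-quality development delay
#' multiplier, a per-quality asymptotic biomass reduction, and lognormal
#' individual variation in boundary ages. The default delays compound
#' the two reported contrasts along the gradient: 95% hosts develop
#' 1.4% slower than 100% hosts, and 90% hosts a further 22% slower than
#' 95% hosts; sizes shrink 15% and a further 46% at the same steps.
#'
#' @param baseline_transition_ages Named numeric: ages (days) of the
#'   L1/L2, L2/L3, L3/L4, L4/P and P/A boundaries at 100% quality,
#'   strictly increasing.
#' @param delay_factor Named per-quality multiplier on all boundary
#'   ages; must be >= 1 with the 100% entry equal to 1.
#' @param size_reduction Named per-quality fractional reduction of the
#'   asymptotic dry biomass, in `[0, 1)`; 0 at 100%.
#' @param transition_noise_sd SD (log scale) of the shared per-host
#'   lognormal multiplier on boundary ages.
#' @param mortality_rate Named per-quality daily death probability
#'   before exposure (default 0; the study left quality-specific
#'   mortality unquantified).
#' @param emergence_delay Days an adult host remains in its seed after
#'   the P/A boundary before emerging (emerged adults are unattackable).
#' @param biomass_asymptote Asymptotic host dry biomass (mg) at 100%.
#' @param biomass_rate Growth-rate constant of the saturating biomass
#'   curve (per effective day).
#' @return A `host_dev_params` list.
#' @export
host_dev_params <- function(
    baseline_transition_ages = c(L2 = 7, L3 = 11, L4 = 15, P = 21, A = 28),
    delay_factor = c("90" = 1.014 * 1.22, "95" = 1.014, "100" = 1),
    size_reduction = c("90" = 1 - 0.85 * 0.54, "95" = 0.15, "100" = 0),
    transition_noise_sd = 0.08,
    mortality_rate = c("90" = 0, "95" = 0, "100" = 0),
    emergence_delay = 5,
    biomass_asymptote = 3,
    biomass_rate = 0.15) {
  if (length(baseline_transition_ages) != 5L ||
      any(diff(baseline_transition_ages) <= 0) ||
      any(baseline_transition_ages <= 0))
    stop("baseline_transition_ages must be 5 strictly increasing positive ages")
  if (any(delay_factor < 1)) stop("delay_factor must be >= 1")
  if ("100" %in% names(delay_factor) && delay_factor[["100"]] != 1)
    stop("delay_factor must be 1 at 100% quality")
  if (any(size_reduction < 0 | size_reduction >= 1))
    stop("size_reduction must lie in [0, 1)")
  if (transition_noise_sd < 0) stop("transition_noise_sd must be >= 0")
  if (any(mortality_rate < 0 | mortality_rate > 1))
    stop("mortality_rate must lie in [0, 1]")
  structure(list(baseline_transition_ages = baseline_transition_ages,
                 delay_factor = delay_factor,
                 size_reduction = size_reduction,
                 transition_noise_sd = transition_noise_sd,
                 mortality_rate = mortality_rate,
                 emergence_delay = emergence_delay,
                 biomass_asymptote = biomass_asymptote,
                 biomass_rate = biomass_rate),
            class = "host_dev_params")
}

#' Parasitism outcome parameters
#'
#' @param attack_success Per-stage probability a 24-h exposure results
#'   in parasitism. The default profile rises through the larval
#'   instars, peaks at L4 and falls for pupae and (pre-emergence)
#'   adults, mirroring the qualitative efficacy pattern of the study.
#'   May also be a quality-named list of such vectors.
#' @param superparasitism_rate Probability a parasitized host receives
#'   more than one egg.
#' @param emergence_success Per-stage probability a parasitized host
#'   yields an emerged adult parasitoid; 0 at L1 (parasitized first
#'   instars never produced adult parasitoids).
#' @return A `parasitism_params` list.
#' @export
parasitism_params <- function(
    attack_success = c(L1 = 0.001, L2 = 0.05, L3 = 0.35, L4 = 0.55,
                       P = 0.35, A = 0.08),
    superparasitism_rate = 0.01,
    emergence_success = c(L1 = 0, L2 = 0.7, L3 = 0.85, L4 = 0.9,
                          P = 0.9, A = 0.8)) {
  chk <- function(p, what) {
    if (any(p < 0 | p > 1)) stop(what, " probabilities must lie in [0, 1]")
  }
  if (is.list(attack_success)) {
    lapply(attack_success, chk, what = "attack_success")
    lapply(attack_success, function(p) {
      if (!all(STAGE_LEVELS %in% names(p)))
        stop("attack_success must name all six stages")
    })
  } else {
    chk(attack_success, "attack_success")
    if (!all(STAGE_LEVELS %in% names(attack_success)))
      stop("attack_success must name all six stages")
  }
  chk(superparasitism_rate, "superparasitism_rate")
  chk(emergence_success, "emergence_success")
  structure(list(attack_success = attack_success,
                 superparasitism_rate = superparasitism_rate,
                 emergence_success = emergence_success),
            class = "parasitism_params")
}

# stage-specific attack probability, honouring optional per-quality lists
attack_prob <- function(params, stage, quality) {
  a <- params$attack_success
  if (is.list(a)) {
    if (!quality %in% names(a)) stop("unknown treatment: ", quality)
    a <- a[[quality]]
  }
  unname(a[stage])
}

#' Parasitoid life-history trait parameters
#'
#' Sex allocation shifts female on older/later-stage hosts; females
#' take about a day longer to develop; hind tibia length saturates with
#' host age at exposure (default plateau 25 d) with a female size
#' offset; emergence mass follows a per-sex allometry on log tibia.
#'
#' @param p_female_midpoint,p_female_scale Host age (days) of even sex
#'   allocation and logistic scale of the female-probability curve.
#' @param devtime_mean_male Mean male development time (days).
#' @param devtime_female_excess Extra mean female development time
#'   (days); default 1.
#' @param devtime_shape Gamma shape of development-time noise (larger =
#'   tighter).
#' @param tibia_base,tibia_gain Hind tibia length (mm) at age 0 and the
#'   gain to the plateau.
#' @param tibia_plateau_age Host age (days) beyond which expected tibia
#'   length is flat; default 25.
#' @param tibia_sex_offset Additive female tibia offset (mm).
#' @param tibia_noise_sd SD (mm) of tibia measurement/individual noise.
#' @param mass_allometry Per-sex `intercept` and `slope` of log
#'   emergence mass (mg) on log tibia length (mm), plus `noise_sd` on
#'   the log scale.
#' @return A `parasitoid_trait_params` list.
#' @export
parasitoid_trait_params <- function(
    p_female_midpoint = 22, p_female_scale = 4,
    devtime_mean_male = 12.5, devtime_female_excess = 1,
    devtime_shape = 80,
    tibia_base = 0.35, tibia_gain = 0.30, tibia_plateau_age = 25,
    tibia_sex_offset = 0.05, tibia_noise_sd = 0.03,
    mass_allometry = list(
      female = list(intercept = 0.40, slope = 3.0),
      male = list(intercept = 0.25, slope = 2.8),
      noise_sd = 0.10)) {
  if (devtime_mean_male <= 0 || devtime_female_excess < 0)
    stop("development times must be positive")
  if (devtime_shape <= 0) stop("devtime_shape must be positive")
  if (tibia_plateau_age <= 0) stop("tibia_plateau_age must be positive")
  structure(list(p_female_midpoint = p_female_midpoint,
                 p_female_scale = p_female_scale,
                 devtime_mean_male = devtime_mean_male,
                 devtime_female_excess = devtime_female_excess,
                 devtime_shape = devtime_shape,
                 tibia_base = tibia_base, tibia_gain = tibia_gain,
                 tibia_plateau_age = tibia_plateau_age,
                 tibia_sex_offset = tibia_sex_offset,
                 tibia_noise_sd = tibia_noise_sd,
                 mass_allometry = mass_allometry),
            class = "parasitoid_trait_params")
}

#' Enumerate the exposure design grid
#'
#' Expands the factorial design (replicate x age x quality) into
#' skeleton exposure records with unique host ids and unset outcome
#' fields. The study design of 54 replicates, daily ages 5--60 and 3
#' treatments enumerates 9072 exposure units.
#'
#' @param config A [design_config()].
#' @return Data frame of skeleton records: `host_id`, `replicate`,
#'   `quality`, `age_at_exposure`, with outcome columns (`parasitized`,
#'   `stage_at_parasitism`, `n_eggs`, `host_died`, `host_emerged`, and
#'   the parasitoid trait columns) present but `NA`.
#' @export
build_design <- function(config) {
  stopifnot(inherits(config, "design_config"))
  g <- expand.grid(age_at_exposure = config$ages,
                   replicate = seq_len(config$n_replicates),
                   quality = config$qualities,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(g)
  data.frame(
    host_id = sprintf("H%s_r%03d_a%02d", g$quality, g$replicate,
                      g$age_at_exposure),
    replicate = g$replicate,
    quality = g$quality,
    age_at_exposure = g$age_at_exposure,
    parasitized = NA_integer_,
    stage_at_parasitism = NA_character_,
    n_eggs = NA_integer_,
    host_died = NA,
    host_emerged = NA,
    sex = NA_character_,
    parasitoid_emerged = NA_integer_,
    development_time = NA_real_,
    emergence_mass = NA_real_,
    hind_tibia_length = NA_real_,
    stringsAsFactors = FALSE)
}

#' Simulate one host development trajectory
#'
#' Draws the five stage-boundary ages for a single host: baseline
#' boundaries scaled by the treatment's delay factor and one shared
#' per-host lognormal multiplier (which preserves boundary ordering
#' exactly), plus the derived seed-emergence age and the saturating
#' dry-biomass curve.
#'
#' @param params A [host_dev_params()].
#' @param quality Treatment label; must be named in the parameters.
#' @return List with `boundaries` (named, days), `emergence_age`, and
#'   `biomass(age)`, a nondecreasing function returning mg.
#' @export
simulate_development_trajectory <- function(params, quality) {
  stopifnot(inherits(params, "host_dev_params"))
  quality <- as.character(quality)
  if (!quality %in% names(params$delay_factor))
    stop("unknown treatment: ", quality)
  delay <- params$delay_factor[[quality]]
  noise <- if (params$transition_noise_sd > 0) {
    rlnorm(1L, meanlog = 0, sdlog = params$transition_noise_sd)
  } else 1
  b <- params$baseline_transition_ages * delay * noise
  asym <- params$biomass_asymptote * (1 - params$size_reduction[[quality]])
  rate <- params$biomass_rate
  list(
    boundaries = b,
    emergence_age = unname(b[["A"]] + params$emergence_delay),
    biomass = function(age) asym * (1 - exp(-rate * age / delay))^3
  )
}

# stage occupied at a given age, from boundary ages (vectorized in age)
stage_at_age <- function(boundaries, age) {
  idx <- vapply(age, function(a) sum(a >= boundaries), integer(1L)) + 1L
  STAGE_LEVELS[idx]
}

#' Complete a skeleton record's parasitism outcome
#'
#' Draws the parasitism event for one exposure given the host's stage
#' on its exposure day, and the egg count (>= 2 with the configured
#' superparasitism probability).
#'
#' @param record One-row skeleton from [build_design()].
#' @param stage_at_exposure Stage the host occupies at exposure.
#' @param params A [parasitism_params()].
#' @param attackable Logical; `FALSE` for emerged adult hosts, which
#'   cannot be attacked.
#' @return The record with `parasitized`, `stage_at_parasitism` and
#'   `n_eggs` filled (stage recorded only when parasitized).
#' @export
simulate_exposure_outcome <- function(record, stage_at_exposure, params,
                                      attackable = TRUE) {
  stopifnot(inherits(params, "parasitism_params"))
  if (!is.na(record$parasitized))
    stop("record is not a skeleton: outcome already set")
  stage_at_exposure <- match.arg(stage_at_exposure, STAGE_LEVELS)
  p <- if (attackable) {
    attack_prob(params, stage_at_exposure, record$quality)
  } else 0
  hit <- rbinom(1L, 1L, p)
  record$parasitized <- hit
  if (hit == 1L) {
    record$stage_at_parasitism <- stage_at_exposure
    multi <- rbinom(1L, 1L, params$superparasitism_rate) == 1L
    record$n_eggs <- if (multi) 1L + 1L + stats::rpois(1L, 0.3) else 1L
  } else {
    record$stage_at_parasitism <- NA_character_
    record$n_eggs <- NA_integer_
  }
  record
}

#' Simulate parasitoid life-history traits for a parasitized host
#'
#' @param record One-row parasitized exposure record.
#' @param params A [parasitoid_trait_params()].
#' @param emergence_success Per-stage probability of yielding an emerged
#'   adult parasitoid (from [parasitism_params()]).
#' @return The record with `sex`, `parasitoid_emerged`,
#'   `development_time`, `emergence_mass` and `hind_tibia_length`
#'   filled for emerged parasitoids.
#' @export
simulate_parasitoid_traits <- function(record, params,
                                       emergence_success = NULL) {
  stopifnot(inherits(params, "parasitoid_trait_params"))
  if (is.na(record$parasitized) || record$parasitized != 1L)
    stop("simulate_parasitoid_traits() requires a parasitized record")
  stage <- record$stage_at_parasitism
  age <- record$age_at_exposure
  p_em <- if (is.null(emergence_success)) 1 else
    unname(emergence_success[stage])
  emerged <- rbinom(1L, 1L, p_em)
  record$parasitoid_emerged <- emerged
  if (emerged != 1L) return(record)
  p_f <- plogis((age - params$p_female_midpoint) / params$p_female_scale)
  female <- rbinom(1L, 1L, p_f) == 1L
  record$sex <- if (female) "female" else "male"
  mu_dt <- params$devtime_mean_male +
    if (female) params$devtime_female_excess else 0
  record$development_time <- rgamma(1L, shape = params$devtime_shape,
                                    rate = params$devtime_shape / mu_dt)
  mu_tibia <- params$tibia_base + params$tibia_gain *
    min(age, params$tibia_plateau_age) / params$tibia_plateau_age +
    if (female) params$tibia_sex_offset else 0
  tibia <- max(rnorm(1L, mu_tibia, params$tibia_noise_sd), 0.05)
  record$hind_tibia_length <- tibia
  al <- params$mass_allometry[[record$sex]]
  record$emergence_mass <- exp(rnorm(1L, al$intercept +
                                       al$slope * log(tibia),
                                     params$mass_allometry$noise_sd))
  record
}

#' Generate a complete synthetic exposure experiment
#'
#' Runs the full generator: enumerates the design, simulates each
#' host's development, exposure outcome and (when parasitized) the
#' parasitoid's life-history traits. All randomness flows through R's
#' RNG seeded from `config$seed`, with hosts processed in fixed design
#' order, so a given configuration reproduces byte-identical tables.
#'
#' @param config A [design_config()].
#' @param dev A [host_dev_params()].
#' @param par A [parasitism_params()].
#' @param traits A [parasitoid_trait_params()].
#' @return Exposure record data frame (see [build_design()] for the
#'   schema), fully populated.
#' @export
simulate_experiment <- function(config = design_config(),
                                dev = host_dev_params(),
                                par = parasitism_params(),
                                traits = parasitoid_trait_params()) {
  stopifnot(inherits(config, "design_config"))
  recs <- build_design(config)
  n <- nrow(recs)
  set.seed(config$seed)

  # vectorized trajectory draws: one shared lognormal multiplier per host
  noise <- if (dev$transition_noise_sd > 0) {
    rlnorm(n, 0, dev$transition_noise_sd)
  } else rep(1, n)
  delay <- dev$delay_factor[recs$quality]
  bmat <- outer(delay * noise, dev$baseline_transition_ages)  # n x 5
  stage_idx <- rowSums(recs$age_at_exposure >= bmat) + 1L
  stage <- STAGE_LEVELS[stage_idx]
  emergence_age <- bmat[, 5L] + dev$emergence_delay

  # pre-exposure mortality (geometric waiting time, default off)
  mort <- dev$mortality_rate[recs$quality]
  died <- rep(FALSE, n)
  if (any(mort > 0)) {
    u <- runif(n)
    # P(survive a days) = (1 - m)^a
    died <- u > (1 - mort)^recs$age_at_exposure
  }
  emerged_host <- stage == "A" & recs$age_at_exposure >= emergence_age
  recs$host_died <- died
  recs$host_emerged <- emerged_host

  attackable <- !died & !emerged_host
  pa <- vapply(seq_len(n), function(i) {
    attack_prob(par, stage[i], recs$quality[i])
  }, numeric(1L))
  pa[!attackable] <- 0
  hit <- rbinom(n, 1L, pa)
  recs$parasitized <- hit
  recs$stage_at_parasitism[hit == 1L] <- stage[hit == 1L]

  para <- which(hit == 1L)
  if (length(para)) {
    multi <- rbinom(length(para), 1L, par$superparasitism_rate) == 1L
    eggs <- rep(1L, length(para))
    eggs[multi] <- 2L + stats::rpois(sum(multi), 0.3)
    recs$n_eggs[para] <- eggs

    em <- rbinom(length(para), 1L,
                 unname(par$emergence_success[stage[para]]))
    recs$parasitoid_emerged[para] <- em
    emi <- para[em == 1L]
    if (length(emi)) {
      age <- recs$age_at_exposure[emi]
      p_f <- plogis((age - traits$p_female_midpoint) / traits$p_female_scale)
      female <- rbinom(length(emi), 1L, p_f) == 1L
      recs$sex[emi] <- ifelse(female, "female", "male")
      mu_dt <- traits$devtime_mean_male +
        ifelse(female, traits$devtime_female_excess, 0)
      recs$development_time[emi] <- rgamma(length(emi),
                                           shape = traits$devtime_shape,
                                           rate = traits$devtime_shape / mu_dt)
      mu_tib <- traits$tibia_base + traits$tibia_gain *
        pmin(age, traits$tibia_plateau_age) / traits$tibia_plateau_age +
        ifelse(female, traits$tibia_sex_offset, 0)
      tib <- pmax(rnorm(length(emi), mu_tib, traits$tibia_noise_sd), 0.05)
      recs$hind_tibia_length[emi] <- tib
      ic <- ifelse(female, traits$mass_allometry$female$intercept,
                   traits$mass_allometry$male$intercept)
      sl <- ifelse(female, traits$mass_allometry$female$slope,
                   traits$mass_allometry$male$slope)
      recs$emergence_mass[emi] <- exp(rnorm(length(emi),
                                            ic + sl * log(tib),
                                            traits$mass_allometry$noise_sd))
    }
  }
  recs
}

#' Generate a reference host-development table
#'
#' Simulates independent host trajectories to stand in for the earlier
#' rearing dataset from which the age-by-stage probability tables are
#' built: for every (quality, age) cell of the design, `n_per_cell`
#' hosts with their stage on that day and dry biomass. This is a
#' synthetic stand-in, not the study's deposited data.
#'
#' @param params A [host_dev_params()].
#' @param config A [design_config()] supplying the quality and age grid.
#' @param n_per_cell Hosts simulated per (quality, age) cell.
#' @param seed RNG seed.
#' @return Data frame with columns `quality`, `age`, `stage`,
#'   `dry_biomass`.
#' @export
generate_reference_table <- function(params = host_dev_params(),
                                     config = design_config(),
                                     n_per_cell = 50L, seed = 1L) {
  stopifnot(inherits(params, "host_dev_params"),
            inherits(config, "design_config"))
  n_per_cell <- as.integer(n_per_cell)
  if (n_per_cell < 1L) stop("n_per_cell must be >= 1")
  set.seed(seed)
  cells <- expand.grid(age = config$ages, quality = config$qualities,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(cells) * n_per_cell
  quality <- rep(cells$quality, each = n_per_cell)
  age <- rep(cells$age, each = n_per_cell)
  noise <- if (params$transition_noise_sd > 0) {
    rlnorm(n, 0, params$transition_noise_sd)
  } else rep(1, n)
  delay <- params$delay_factor[quality]
  bmat <- outer(delay * noise, params$baseline_transition_ages)
  stage <- STAGE_LEVELS[rowSums(age >= bmat) + 1L]
  asym <- params$biomass_asymptote * (1 - params$size_reduction[quality])
  biomass <- asym * (1 - exp(-params$biomass_rate * age / delay))^3
  data.frame(quality = quality, age = age, stage = stage,
             dry_biomass = pmax(biomass, 1e-6), stringsAsFactors = FALSE)
}
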