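#' Configuration for a synthetic gnotobiotic calorimetry study
#'
#' Generative parameters for cohorts of germ-free (GF), gnotobiotic
#' (OLIGO) and conventionally colonized (SPF) mice. Defaults encode the
#' study conditions the pipeline is designed for: cecal masses of about
#' 3 / 1.5 / 0.5 g (GF / OLIGO / SPF), GF food intake 15 % above colonized
#' animals (within the reported 10-20 % band), fecal energy densities of
#' 3.7 (GF) versus 4.0 kcal/g (colonized), a daily energy expenditure near
#' 9 kcal/day driven linearly by lean mass with a circadian modulation
#' peaking in the dark phase, RER profiles ordered GF < OLIGO < SPF in the
#' light phase with OLIGO rising to SPF level in the dark phase, hydrogen
#' production proportional to cecal mass in colonized animals only, and
#' cecal bacterial densities of 1.1e11 (OLIGO) and 1.6e11 (SPF) cells/g.
#'
#' @param n_per_group named integer vector, mice per group.
#' @param days full recording days per mouse.
#' @param cadence_min recording cadence (minutes).
#' @param flow_lpm extraction flow (L/min).
#' @param lights_on lights-on clock time anchoring timestamps.
#' @param lean_mean_g,lean_sd_g lean-mass distribution (g), shared across
#'   groups (the study found no lean-mass group difference).
#' @param fat_depot_means_g,fat_depot_sds_g named (iBAT/iWAT/vWAT) depot
#'   distributions (g).
#' @param fat_group_multiplier per-group multiplier on depot means (the
#'   gnotobiotic group accumulates more fat).
#' @param residual_mass_mean_g,residual_mass_sd_g mass not in lean, fat or
#'   cecum (g).
#' @param cecal_mean_g,cecal_sd_g per-group cecal mass (tissue plus
#'   luminal content, g).
#' @param ee_intercept,ee_slope_lean daily EE model (kcal/day):
#'   `intercept + slope * lean + group effect`.
#' @param ee_group_effect per-group additive EE effect (kcal/day);
#'   all zero by default (no true group difference).
#' @param ee_mouse_sd between-mouse EE noise around the model (kcal/day).
#' @param ee_circ_amplitude relative circadian EE modulation
#'   (`1 - a cos(2 pi zt / 24)`: trough at ZT 0, peak at ZT 12-24 mean
#'   above 1 in the dark phase).
#' @param rer_light,rer_dark per-group RER by phase.
#' @param rer_noise_sd pointwise RER noise.
#' @param h2_peak_ppm_per_g dark-phase hydrogen peak per gram cecal mass
#'   (ppm/g); zero for GF. The gnotobiotic community ferments at a higher
#'   per-gram rate than the SPF community.
#' @param h2_noise_ppm analyser blank noise (ppm).
#' @param gas_noise sensor noise SD on the O2/CO2 differentials
#'   (volume fraction).
#' @param intake_daily_g colonized daily food intake (g/day).
#' @param gf_intake_multiplier GF intake relative to colonized (1.10-1.20).
#' @param intake_cv within-bout intake coefficient of variation.
#' @param eat_prob_light,eat_prob_dark per-interval probability of a
#'   feeding bout by phase (feeding concentrates in the dark phase).
#' @param water_daily_g daily water intake (g/day).
#' @param fecal_per_g_intake per-group dry fecal output per gram intake
#'   (tuned so all groups extract about 9 kcal/day).
#' @param fecal_energy_mean,fecal_energy_sd per-group fecal energy density
#'   (kcal/g dry feces).
#' @param fecal_cv day-to-day CV of fecal dry mass.
#' @param cell_density_per_g per-group cecal bacterial density (cells/g);
#'   `NA` for GF (blank-level events are generated instead).
#' @param cell_density_cv between-mouse density CV.
#' @param blank_events mean gated event count for a germ-free (blank)
#'   cytometry sample.
#' @param metabolites named list of per-metabolite group means (umol/g);
#'   drawn with `metabolite_cv` noise. Simple group-mean draws only.
#' @param metabolite_cv between-mouse metabolite CV.
#' @param fault_rates named per-record probabilities for injected faults
#'   (`food_sentinel`, `negative_gas`, `intake_outlier`, `gas_dropout`).
#' @param constants a [gas_constants()] used to invert the Haldane
#'   transformation when synthesising raw differentials.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(GF = 10, OLIGO = 10, SPF = 10),
                          days = 4,
                          cadence_min = 24,
                          flow_lpm = 0.4,
                          lights_on = "07:00",
                          lean_mean_g = 20, lean_sd_g = 1.5,
                          fat_depot_means_g = c(iBAT = 0.15, iWAT = 0.25, vWAT = 0.35),
                          fat_depot_sds_g = c(iBAT = 0.03, iWAT = 0.06, vWAT = 0.08),
                          fat_group_multiplier = c(GF = 1, OLIGO = 1.4, SPF = 1.1),
                          residual_mass_mean_g = 5, residual_mass_sd_g = 0.5,
                          cecal_mean_g = c(GF = 3.0, OLIGO = 1.5, SPF = 0.5),
                          cecal_sd_g = c(GF = 0.4, OLIGO = 0.25, SPF = 0.1),
                          ee_intercept = 1.0, ee_slope_lean = 0.4,
                          ee_group_effect = c(GF = 0, OLIGO = 0, SPF = 0),
                          ee_mouse_sd = 0.35,
                          ee_circ_amplitude = 0.3,
                          rer_light = c(GF = 0.74, OLIGO = 0.75, SPF = 0.85),
                          rer_dark = c(GF = 0.80, OLIGO = 0.92, SPF = 0.95),
                          rer_noise_sd = 0.02,
                          h2_peak_ppm_per_g = c(GF = 0, OLIGO = 25, SPF = 12),
                          h2_noise_ppm = 0.4,
                          gas_noise = 5e-5,
                          intake_daily_g = 3.2,
                          gf_intake_multiplier = 1.15,
                          intake_cv = 0.5,
                          eat_prob_light = 0.2, eat_prob_dark = 0.6,
                          water_daily_g = 4.5,
                          fecal_per_g_intake = c(GF = 0.40, OLIGO = 0.29, SPF = 0.27),
                          fecal_energy_mean = c(GF = 3.7, OLIGO = 4.0, SPF = 4.0),
                          fecal_energy_sd = c(GF = 0.15, OLIGO = 0.15, SPF = 0.15),
                          fecal_cv = 0.15,
                          cell_density_per_g = c(GF = NA, OLIGO = 1.1e11, SPF = 1.6e11),
                          cell_density_cv = 0.15,
                          blank_events = 50,
                          metabolites = list(
                            acetate = c(GF = 0.5, OLIGO = 25, SPF = 60),
                            propionate = c(GF = 0.1, OLIGO = 4, SPF = 12),
                            butyrate = c(GF = 0.1, OLIGO = 2, SPF = 10),
                            lactate = c(GF = 3, OLIGO = 18, SPF = 4),
                            succinate = c(GF = 0.5, OLIGO = 8, SPF = 2)),
                          metabolite_cv = 0.3,
                          fault_rates = c(food_sentinel = 0, negative_gas = 0,
                                          intake_outlier = 0, gas_dropout = 0),
                          constants = gas_constants()) {
  groups <- c("GF", "OLIGO", "SPF")
  stopifnot(all(names(n_per_group) %in% groups), all(n_per_group >= 1),
            days >= 1, cadence_min > 0, flow_lpm > 0,
            lean_sd_g >= 0, all(fat_depot_sds_g >= 0),
            all(cecal_sd_g >= 0), ee_mouse_sd >= 0,
            ee_circ_amplitude >= 0, ee_circ_amplitude < 1,
            rer_noise_sd >= 0, h2_noise_ppm >= 0, gas_noise >= 0,
            gf_intake_multiplier > 0, intake_cv >= 0,
            eat_prob_light > 0, eat_prob_light <= 1,
            eat_prob_dark > 0, eat_prob_dark <= 1,
            all(fault_rates >= 0), sum(fault_rates) <= 1)
  cfg <- as.list(environment())
  cfg$groups <- groups
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  mice:", paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                       collapse = ", "), "\n")
  cat("  ", x$days, " day(s) at ", x$cadence_min, "-min cadence, flow ",
      x$flow_lpm, " L/min\n", sep = "")
  cat("  cecal mass (g):",
      paste(sprintf("%s=%.1f", names(x$cecal_mean_g), x$cecal_mean_g),
            collapse = ", "), "\n")
  cat("  fault rates:", sum(x$fault_rates), "\n")
  invisible(x)
}

circ_modulation <- function(zt, amplitude) {
  1 - amplitude * cos(2 * pi * zt / 24)
}

#' Generate a complete synthetic study
#'
#' Draws per-mouse body compositions, synthesises gas-differential traces
#' at the configured cadence (latent energy expenditure and RER are pushed
#' backwards through the Weir equation and the inverse Haldane
#' transformation, so the analysis pipeline's forward computation is
#' exercised end to end), and produces intake, fecal-output, cytometry and
#' cecal-metabolite tables. Ground-truth per-mouse parameters are returned
#' alongside for parameter-recovery tests. Output is bitwise-reproducible
#' for a fixed seed.
#'
#' @param cfg a [cohort_config()].
#' @param seed integer seed for all randomness.
#' @return list with tibbles `profiles`, `traces`, `intake`, `fecal`,
#'   `assays`, `metabolites`, `truth`, plus `fault_log` (empty unless
#'   `cfg$fault_rates` are nonzero) and the `dialect` the traces follow.
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = 1) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(seed)
  groups <- rep(names(cfg$n_per_group), cfg$n_per_group)
  n <- length(groups)
  mouse_id <- sprintf("%s_%02d", groups, unlist(lapply(cfg$n_per_group, seq_len)))

  lean <- stats::rnorm(n, cfg$lean_mean_g, cfg$lean_sd_g)
  fat <- sapply(names(cfg$fat_depot_means_g), function(dep) {
    pmax(0.01, stats::rnorm(n, cfg$fat_depot_means_g[dep] *
                               cfg$fat_group_multiplier[groups],
                            cfg$fat_depot_sds_g[dep]))
  })
  cecal <- pmax(0.05, stats::rnorm(n, cfg$cecal_mean_g[groups],
                                   cfg$cecal_sd_g[groups]))
  residual <- pmax(0.5, stats::rnorm(n, cfg$residual_mass_mean_g,
                                     cfg$residual_mass_sd_g))
  total <- lean + rowSums(fat) + residual + cecal
  profiles <- tibble::tibble(
    mouse_id = mouse_id, group = groups,
    total_mass_g = total,
    total_mass_nocecum_g = total - cecal,
    lean_mass_g = lean,
    fat_ibat_g = fat[, "iBAT"], fat_iwat_g = fat[, "iWAT"],
    fat_vwat_g = fat[, "vWAT"],
    cecal_mass_g = cecal
  )

  daily_ee <- cfg$ee_intercept + cfg$ee_slope_lean * lean +
    cfg$ee_group_effect[groups] + stats::rnorm(n, 0, cfg$ee_mouse_sd)

  cadence_h <- cfg$cadence_min / 60
  t_grid <- seq(0, cfg$days * 24 - cadence_h, by = cadence_h)
  start <- as.POSIXct(paste("2022-03-01", cfg$lights_on), tz = "UTC")
  n_day <- length(t_grid) / cfg$days

  intake_scale <- ifelse(groups == "GF", cfg$gf_intake_multiplier, 1)
  daily_intake_target <- cfg$intake_daily_g * intake_scale

  traces <- vector("list", n)
  for (i in seq_len(n)) {
    zt <- t_grid %% 24
    dark <- zt >= 12
    ee_rate <- daily_ee[i] / 1440 * circ_modulation(zt, cfg$ee_circ_amplitude)
    rer_t <- ifelse(dark, cfg$rer_dark[groups[i]], cfg$rer_light[groups[i]]) +
      stats::rnorm(length(zt), 0, cfg$rer_noise_sd)
    vo2 <- ee_rate / (cfg$constants$weir_o2 + cfg$constants$weir_co2 * rer_t)
    vco2 <- rer_t * vo2
    d <- haldane_invert(vo2, vco2, cfg$flow_lpm, cfg$constants)
    d_o2 <- d$d_o2 + stats::rnorm(length(zt), 0, cfg$gas_noise)
    d_co2 <- d$d_co2 + stats::rnorm(length(zt), 0, cfg$gas_noise)

    h2_bump <- pmax(0, sin(pi * (zt - 12) / 12))
    d_h2 <- cfg$h2_peak_ppm_per_g[groups[i]] * cecal[i] * h2_bump +
      stats::rnorm(length(zt), 0, cfg$h2_noise_ppm)

    eat_p <- ifelse(dark, cfg$eat_prob_dark, cfg$eat_prob_light)
    # per-bout mean chosen so expected daily intake hits the target with
    # the configured dark-phase share implied by the bout probabilities
    exp_bouts_day <- n_day / 2 * (cfg$eat_prob_dark + cfg$eat_prob_light)
    bout_mean <- daily_intake_target[i] / exp_bouts_day
    eats <- stats::rbinom(length(zt), 1, eat_p)
    amount <- if (cfg$intake_cv > 0) {
      stats::rgamma(length(zt), shape = 1 / cfg$intake_cv^2,
                    scale = bout_mean * cfg$intake_cv^2)
    } else rep(bout_mean, length(zt))
    food <- eats * amount
    w_mean <- cfg$water_daily_g / exp_bouts_day
    drinks <- stats::rbinom(length(zt), 1, eat_p)
    w_amount <- if (cfg$intake_cv > 0) {
      stats::rgamma(length(zt), shape = 1 / cfg$intake_cv^2,
                    scale = w_mean * cfg$intake_cv^2)
    } else rep(w_mean, length(zt))
    water <- drinks * w_amount

    traces[[i]] <- tibble::tibble(
      mouse_id = mouse_id[i],
      cage_id = sprintf("cage_%d", (i - 1) %% 8 + 1),
      timestamp = start + t_grid * 3600,
      zt = zt,
      d_o2 = d_o2, d_co2 = d_co2, d_h2 = d_h2,
      food_g = food, water_g = water,
      flow_lpm = cfg$flow_lpm,
      qc_flags = ""
    )
  }
  traces <- dplyr::bind_rows(traces)

  fault_log <- tibble::tibble(row = integer(0), mouse_id = character(0),
                              fault = character(0))
  if (sum(cfg$fault_rates) > 0) {
    f <- inject_faults(traces, cfg$fault_rates,
                       seed = seed + 104729L)
    traces <- f$records
    fault_log <- f$fault_log
  }

  intake <- dplyr::summarise(
    dplyr::group_by(traces, .data$mouse_id,
                    day = floor((as.numeric(.data$timestamp) - as.numeric(start)) / 86400)),
    intake_g = sum(.data$food_g), .groups = "drop")
  intake$day <- as.integer(intake$day)

  fecal <- intake
  g_of <- stats::setNames(groups, mouse_id)
  fecal$fecal_dry_g <- cfg$fecal_per_g_intake[g_of[fecal$mouse_id]] *
    fecal$intake_g *
    (if (cfg$fecal_cv > 0) stats::rgamma(nrow(fecal), 1 / cfg$fecal_cv^2,
                                         scale = cfg$fecal_cv^2) else 1)
  fecal$energy_kcal_per_g <- stats::rnorm(
    nrow(fecal), cfg$fecal_energy_mean[g_of[fecal$mouse_id]],
    cfg$fecal_energy_sd[g_of[fecal$mouse_id]])
  fecal <- fecal[, c("mouse_id", "day", "fecal_dry_g", "energy_kcal_per_g")]

  true_density <- ifelse(
    is.na(cfg$cell_density_per_g[groups]), NA_real_,
    cfg$cell_density_per_g[groups] *
      (1 + stats::rnorm(n, 0, cfg$cell_density_cv)))
  true_density <- pmax(true_density, 0)
  sample_mass <- stats::runif(n, 0.02, 0.05)
  bead_events <- stats::rpois(n, 4550)
  expected_events <- ifelse(
    is.na(true_density), cfg$blank_events,
    true_density * (2 / 200) * (sample_mass / 1000) * (bead_events / 4550))
  assays <- tibble::tibble(
    mouse_id = mouse_id, group = groups,
    bacterial_events = stats::rpois(n, expected_events),
    bead_events = bead_events,
    bead_conc_per_ul = 4.55e3, mix_volume_ul = 200,
    sample_volume_ul = 2, homogenate_volume_ul = 1000,
    sample_mass_g = sample_mass
  )

  metabolites <- dplyr::bind_rows(lapply(names(cfg$metabolites), function(m) {
    mu <- cfg$metabolites[[m]][groups]
    tibble::tibble(mouse_id = mouse_id, group = groups, metabolite = m,
                   conc_umol_per_g = pmax(0, stats::rnorm(
                     n, mu, cfg$metabolite_cv * mu)))
  }))

  truth <- tibble::tibble(
    mouse_id = mouse_id, group = groups,
    lean_mass_g = lean, cecal_mass_g = cecal,
    daily_ee_kcal = daily_ee,
    rer_light = cfg$rer_light[groups], rer_dark = cfg$rer_dark[groups],
    h2_peak_ppm = cfg$h2_peak_ppm_per_g[groups] * cecal,
    daily_intake_target_g = daily_intake_target,
    cell_density_per_g = true_density
  )

  list(profiles = profiles, traces = traces, intake = intake, fecal = fecal,
       assays = assays, metabolites = metabolites, truth = truth,
       fault_log = fault_log,
       dialect = study_dialect(lights_on = cfg$lights_on,
                               cadence_min = cfg$cadence_min),
       config = cfg, seed = seed)
}

#' Inject sensor and husbandry faults into trace records
#'
#' Each record independently receives at most one fault, drawn with the
#' stated per-type probabilities. Fault types mirror the failure modes the
#' QC rules target: `food_sentinel` (balance noise reported as a 0.01 g
#' food event), `negative_gas` (negative differential from a sensor
#' excursion), `intake_outlier` (leaky water bottle / dropped food pellet:
#' an implausibly large intake), `gas_dropout` (cage seal leak or clogged
#' filter: differentials collapse towards zero). A ground-truth fault log
#' is returned so rule recall can be measured exactly.
#'
#' @param records trace records.
#' @param rates named probabilities (see [cohort_config()]`$fault_rates`).
#' @param seed integer seed.
#' @return list with `records` (faulted) and `fault_log` (tibble `row`,
#'   `mouse_id`, `fault`).
#' @export
inject_faults <- function(records, rates, seed = 1) {
  known <- c("food_sentinel", "negative_gas", "intake_outlier", "gas_dropout")
  rates <- rates[intersect(names(rates), known)]
  stopifnot(all(rates >= 0), sum(rates) <= 1)
  set.seed(seed)
  n <- nrow(records)
  u <- stats::runif(n)
  cum <- cumsum(rates)
  fault <- rep(NA_character_, n)
  for (j in seq_along(rates)) {
    lo <- if (j == 1) 0 else cum[j - 1]
    fault[u >= lo & u < cum[j]] <- names(rates)[j]
  }
  per_mouse_max_water <- tapply(records$water_g, records$mouse_id, max)
  per_mouse_max_food <- tapply(records$food_g, records$mouse_id, max)
  for (i in which(!is.na(fault))) {
    switch(fault[i],
      food_sentinel = { records$food_g[i] <- 0.01 },
      negative_gas = {
        records$d_o2[i] <- -abs(records$d_o2[i]) - 1e-4
      },
      intake_outlier = {
        if (stats::runif(1) < 0.5) {
          records$water_g[i] <- 10 * per_mouse_max_water[records$mouse_id[i]] + 1
        } else {
          records$food_g[i] <- 10 * per_mouse_max_food[records$mouse_id[i]] + 1
        }
      },
      gas_dropout = {
        records$d_o2[i] <- records$d_o2[i] * 0.02
        records$d_co2[i] <- records$d_co2[i] * 0.02
      })
  }
  log <- tibble::tibble(row = which(!is.na(fault)),
                        mouse_id = records$mouse_id[!is.na(fault)],
                        fault = fault[!is.na(fault)])
  list(records = records, fault_log = log)
}

#' Simulate per-mouse daily energy-expenditure summaries
#'
#' A light-weight generator at the per-mouse summary level (no traces) for
#' parameter-recovery and Type-I-error simulations over many seeds: lean
#' mass drives EE linearly, an optional additive group effect is injected,
#' and Gaussian mouse-level noise is added.
#'
#' @param n_per_group named integer vector of group sizes.
#' @param intercept,slope_lean EE model (kcal/day).
#' @param group_effect named per-group additive effect (kcal/day).
#' @param lean_mean_g,lean_sd_g lean-mass distribution.
#' @param noise_sd mouse-level EE noise (kcal/day).
#' @param seed integer seed.
#' @return tibble with `mouse_id`, `group`, `lean_mass_g`, `ee_kcal`.
#' @export
simulate_ee_summaries <- function(n_per_group = c(GF = 10, OLIGO = 10, SPF = 10),
                                  intercept = 1.0, slope_lean = 0.4,
                                  group_effect = c(GF = 0, OLIGO = 0, SPF = 0),
                                  lean_mean_g = 20, lean_sd_g = 1.5,
                                  noise_sd = 0.35, seed = 1) {
  set.seed(seed)
  groups <- rep(names(n_per_group), n_per_group)
  n <- length(groups)
  lean <- stats::rnorm(n, lean_mean_g, lean_sd_g)
  ee <- intercept + slope_lean * lean + group_effect[groups] +
    stats::rnorm(n, 0, noise_sd)
  tibble::tibble(
    mouse_id = sprintf("%s_%02d", groups, unlist(lapply(n_per_group, seq_len))),
    group = groups, lean_mass_g = lean, ee_kcal = as.numeric(ee))
}
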