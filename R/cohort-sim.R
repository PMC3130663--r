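#' Configuration for the synthetic xenograft cohort generator
#'
#' Defines the study conditions emulated by [simulate_cohort()]: four
#' treatment arms (untreated control, single-dose radiotherapy, androgen
#' deprivation by castration, and the combination), longitudinal tumor
#' volume (V), serum PSA, tumor-mean ADC and Ktrans at days 0, 1 and 9,
#' and the day-30 endpoint volume V30.
#'
#' The day-30 group means default to the calibrated relative changes of the
#' emulated experiment: +940% (control), +60% (RT), -40% (ADT) and -64%
#' (ADT+RT) of baseline volume.
#'
#' Each animal carries four modality latents (one per parameter) that
#' perturb both its biomarker trajectories and its outcome, so that early
#' biomarker changes are genuinely predictive of V30 and the ADC and Ktrans
#' channels carry complementary information. The combined latent enters the
#' outcome multiplicatively as `(1 + s*u)` with `u` standardized and bounded
#' (see [simulate_cohort()]); residual outcome noise is a mean-one lognormal
#' multiplier, which preserves group means of `V30/V0` exactly and keeps
#' volumes positive.
#'
#' @param n_per_group Animals per treatment group (>= 2). Default 8.
#' @param group_names Labels of the four arms, in order.
#' @param day30_mean_relchange Named per-group mean of `V30/V0 - 1`.
#' @param day30_sd_relchange Named per-group dispersion of `V30/V0 - 1` as
#'   printed for the emulated experiment; retained for reference and
#'   reporting. The generator's within-group spread is governed by
#'   `latent_outcome_scale` and `outcome_noise_sd` instead (see Details).
#' @param biomarker_effect 4 x 4 x 2 array `[group, parameter, day]` of mean
#'   multiplicative changes of V, PSA, ADC, Ktrans at days 1 and 9 relative
#'   to day 0.
#' @param latent_weights Named weights (V, PSA, ADC, Ktrans) linking the
#'   modality latents to the outcome latent `u`.
#' @param latent_outcome_scale Scale `s` of the multiplicative latent
#'   outcome effect `(1 + s*u)`; dimensionless.
#' @param latent_trunc Symmetric truncation bound for the raw outcome latent
#'   (standard-normal scale) guaranteeing `1 + s*u > 0`.
#' @param biomarker_coupling Named day-9 log-scale couplings of each
#'   parameter's trajectory to its modality latent.
#' @param coupling_sign Named signs (+1/-1): response of each parameter to
#'   the growth latent (ADC falls, the rest rise).
#' @param day1_fraction Fraction of the day-9 coupling/effect realized by
#'   day 1 (applied to the latent coupling only).
#' @param measurement_sd Lognormal measurement jitter sd on each biomarker
#'   ratio.
#' @param outcome_noise_sd Log-scale sd of the lognormal outcome noise
#'   multiplier, or `"auto"` (default) to solve for the sd at which the
#'   generative-oracle correlation equals `oracle_target_r` (see
#'   [calibrate_outcome_sigma()]).
#' @param oracle_target_r Pooled Pearson correlation between the generative
#'   oracle `E[V30/V0 | latents]` and the realized outcome that `"auto"`
#'   calibration targets. Default 0.90.
#' @param baseline List of baseline distributions: lognormal meanlog/sdlog
#'   for V0 (mm^3) and PSA0 (ng/ml); normal mean/sd for ADC0 (mm^2/s) and
#'   Ktrans0 (1/s).
#'
#' @details
#' With group factors `g = 1 + mean relchange`, latent factor `P = 1 + s*u`
#' (`E[P] = 1`, `Var[P] = s^2`) and noise multiplier `L` (`E[L] = 1`,
#' `Var[L] = vL`), the outcome is `V30/V0 = g * P * L`, so
#' `E[V30/V0] = g` per group and the oracle correlation has the closed form
#' used by [calibrate_outcome_sigma()].
#'
#' @return An object of class `generator_config`.
#' @seealso [simulate_cohort()], [calibrate_outcome_sigma()]
#' @export
generator_config <- function(n_per_group = 8,
                             group_names = c("control", "RT", "ADT", "ADT+RT"),
                             day30_mean_relchange = c(control = 9.40, RT = 0.60,
                                                      ADT = -0.40, `ADT+RT` = -0.64),
                             day30_sd_relchange = c(control = 0.91, RT = 0.25,
                                                    ADT = 0.09, `ADT+RT` = 0.05),
                             biomarker_effect = default_biomarker_effect(group_names),
                             latent_weights = c(V = 0.3, PSA = 0.3, ADC = 1, Ktrans = 1),
                             latent_outcome_scale = 0.40,
                             latent_trunc = 2.2,
                             biomarker_coupling = c(V = 0.15, PSA = 0.25,
                                                    ADC = 0.12, Ktrans = 0.15),
                             coupling_sign = c(V = 1, PSA = 1, ADC = -1, Ktrans = 1),
                             day1_fraction = 0.4,
                             measurement_sd = 0.04,
                             outcome_noise_sd = "auto",
                             oracle_target_r = 0.90,
                             baseline = list(V = c(meanlog = log(256), sdlog = 0.15),
                                             PSA = c(meanlog = log(30), sdlog = 0.30),
                                             ADC = c(mean = 8e-4, sd = 5e-5),
                                             Ktrans = c(mean = 3e-3, sd = 4e-4))) {
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L ||
      n_per_group < 2 || n_per_group != round(n_per_group)) {
    stop_validation("n_per_group must be an integer >= 2")
  }
  if (length(group_names) != 4L || anyDuplicated(group_names)) {
    stop_validation("exactly 4 distinct treatment groups are required")
  }
  if (length(day30_mean_relchange) != 4L) {
    stop_validation("day30_mean_relchange must have one entry per group")
  }
  if (any(day30_sd_relchange < 0) || measurement_sd < 0) {
    stop_validation("standard deviations must be non-negative")
  }
  if (any(1 + day30_mean_relchange <= 0)) {
    stop_validation("day30 mean relative changes must keep V30 positive")
  }
  params <- c("V", "PSA", "ADC", "Ktrans")
  stopifnot(identical(dim(biomarker_effect), c(4L, 4L, 2L)),
            all(biomarker_effect > 0))
  assert_scalar_number(latent_outcome_scale, "latent_outcome_scale", lower = 0)
  assert_scalar_number(latent_trunc, "latent_trunc", lower = 0)
  if (latent_outcome_scale * latent_trunc / sqrt(truncnorm_sym_var(latent_trunc)) >= 1) {
    stop_validation("latent_outcome_scale * standardized truncation bound must be < 1")
  }
  stopifnot(identical(names(latent_weights), params),
            all(latent_weights >= 0))
  cfg <- structure(list(
    n_per_group = as.integer(n_per_group),
    group_names = group_names,
    parameters = params,
    day30_mean_relchange = stats::setNames(day30_mean_relchange, group_names),
    day30_sd_relchange = stats::setNames(day30_sd_relchange, group_names),
    biomarker_effect = biomarker_effect,
    latent_weights = latent_weights,
    latent_outcome_scale = latent_outcome_scale,
    latent_trunc = latent_trunc,
    biomarker_coupling = biomarker_coupling,
    coupling_sign = coupling_sign,
    day1_fraction = day1_fraction,
    measurement_sd = measurement_sd,
    outcome_noise_sd = outcome_noise_sd,
    oracle_target_r = oracle_target_r,
    baseline = baseline
  ), class = "generator_config")
  if (identical(outcome_noise_sd, "auto")) {
    cfg$outcome_noise_sd <- calibrate_outcome_sigma(cfg, oracle_target_r)
  } else {
    assert_scalar_number(outcome_noise_sd, "outcome_noise_sd", lower = 0)
  }
  cfg
}

#' Default mean multiplicative biomarker changes per arm
#'
#' Mean day-1 and day-9 changes of V, PSA, ADC and Ktrans relative to
#' baseline for the four arms. Effective therapy raises ADC (falling
#' cellularity) and lowers Ktrans (anti-vascular effect) by day 9; tumor
#' volume and PSA track growth or regression, with PSA collapsing under
#' androgen deprivation.
#'
#' @param group_names Group labels (order: control, RT, ADT, combined).
#' @return A 4 x 4 x 2 array `[group, parameter, day]`.
#' @export
default_biomarker_effect <- function(group_names = c("control", "RT", "ADT", "ADT+RT")) {
  params <- c("V", "PSA", "ADC", "Ktrans")
  eff <- array(NA_real_, dim = c(4L, 4L, 2L),
               dimnames = list(group_names, params, c("d1", "d9")))
  #                      V      PSA    ADC   Ktrans
  eff[1, , "d1"] <- c(1.20, 1.15, 1.00, 1.00)
  eff[1, , "d9"] <- c(2.00, 1.90, 0.95, 1.05)
  eff[2, , "d1"] <- c(1.10, 1.05, 1.05, 0.95)
  eff[2, , "d9"] <- c(1.30, 1.20, 1.15, 0.85)
  eff[3, , "d1"] <- c(0.95, 0.60, 1.10, 0.90)
  eff[3, , "d9"] <- c(0.80, 0.30, 1.25, 0.75)
  eff[4, , "d1"] <- c(0.92, 0.55, 1.12, 0.85)
  eff[4, , "d9"] <- c(0.70, 0.25, 1.35, 0.65)
  eff
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  %d animals per group; groups: %s\n",
              x$n_per_group, paste(x$group_names, collapse = ", ")))
  cat("  mean day-30 relative volume change per group:\n")
  cat(sprintf("    %s: %+.2f\n", names(x$day30_mean_relchange),
              x$day30_mean_relchange), sep = "")
  cat(sprintf("  latent outcome scale s = %.2f; outcome noise sdlog = %.4f\n",
              x$latent_outcome_scale, x$outcome_noise_sd))
  invisible(x)
}

#' Solve for the outcome-noise level giving a target oracle correlation
#'
#' The generator's outcome is `V30/V0 = g * P * L` with per-group factor
#' `g = 1 + mean relchange`, latent factor `P = 1 + s*u` (`u` standardized)
#' and an independent mean-one lognormal noise multiplier `L` with variance
#' `vL = exp(sigma^2) - 1`. The generative oracle predicts `g * P`, so the
#' pooled squared correlation between oracle and outcome is
#' `r^2 = (A - B) / (A*(1 + vL) - B)` with `A = E[g^2]*(1 + s^2)` and
#' `B = E[g]^2` (groups equally sized). This function inverts that relation
#' and returns the log-scale sd `sigma` at which the oracle correlation
#' equals `target_r`.
#'
#' @param config A [generator_config()] (its `outcome_noise_sd` is ignored).
#' @param target_r Desired oracle Pearson correlation, in (0, 1).
#' @return The calibrated lognormal sd (log scale), a scalar.
#' @export
calibrate_outcome_sigma <- function(config, target_r = 0.90) {
  assert_scalar_number(target_r, "target_r", lower = 1e-6, upper = 1 - 1e-9)
  g <- 1 + config$day30_mean_relchange
  s <- config$latent_outcome_scale
  A <- mean(g^2) * (1 + s^2)
  B <- mean(g)^2
  vL <- (A - B) * (1 / target_r^2 - 1) / A
  sqrt(log(1 + vL))
}

#' Simulate a longitudinal treatment-response cohort
#'
#' Draws a cohort of xenograft-bearing animals in four treatment arms with
#' tumor volume, PSA, tumor-mean ADC and Ktrans at days 0, 1, 9 and the
#' day-30 endpoint volume. Each animal has four modality latents
#' `zeta_p ~ N(0,1)` (V, PSA, ADC, Ktrans); its biomarker day-`d` ratio is
#' `effect[group, p, d] * exp(sign_p * gamma_p * c_d * zeta_p + jitter)`
#' and its outcome is
#' `V30/V0 = (1 + mu_group) * (1 + s*u) * L`, where `u` is the
#' weight-combined, truncated and standardized latent, and `L` is mean-one
#' lognormal noise. The conditional mean `(1 + mu_group) * (1 + s*u)` is
#' attached as the `oracle` attribute for calibration checks.
#'
#' @param config A [generator_config()].
#' @param seed Integer master seed; all randomness derives from it.
#' @return A `data.frame` of class `mri_cohort`, one row per animal, with
#'   columns `id`, `group`, `<p>_d0/_d1/_d9` for p in V, PSA, ADC, Ktrans,
#'   and `V_d30`; attributes `config`, `seed` and `oracle`.
#' @examples
#' coh <- simulate_cohort(generator_config(), seed = 1)
#' aggregate(V_d30 / V_d0 - 1 ~ group, data = coh, FUN = mean)
#' @export
simulate_cohort <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  n_g <- config$n_per_group
  n <- 4L * n_g
  group <- factor(rep(config$group_names, each = n_g),
                  levels = config$group_names)
  params <- config$parameters
  w <- config$latent_weights
  s <- config$latent_outcome_scale
  a <- config$latent_trunc
  sigma <- config$outcome_noise_sd

  with_seed(substream_seed(seed, 1L), {
    # modality latents; reject joint draws whose combined latent exceeds the
    # truncation bound so that 1 + s*u stays strictly positive
    zeta <- matrix(stats::rnorm(n * 4L), n, 4L, dimnames = list(NULL, params))
    if (sum(w^2) > 0) {
      wn <- w / sqrt(sum(w^2))
      u_raw <- drop(zeta %*% wn)
      bad <- which(abs(u_raw) > a)
      while (length(bad)) {
        zeta[bad, ] <- stats::rnorm(length(bad) * 4L)
        u_raw[bad] <- drop(zeta[bad, , drop = FALSE] %*% wn)
        bad <- bad[abs(u_raw[bad]) > a]
      }
      u <- u_raw / sqrt(truncnorm_sym_var(a))
    } else {
      u <- numeric(n)   # no latent-outcome link
    }

    bl <- config$baseline
    V0 <- stats::rlnorm(n, bl$V["meanlog"], bl$V["sdlog"])
    PSA0 <- stats::rlnorm(n, bl$PSA["meanlog"], bl$PSA["sdlog"])
    ADC0 <- pmax(stats::rnorm(n, bl$ADC["mean"], bl$ADC["sd"]), 1e-5)
    K0 <- pmax(stats::rnorm(n, bl$Ktrans["mean"], bl$Ktrans["sd"]), 1e-5)
    base <- cbind(V = V0, PSA = PSA0, ADC = ADC0, Ktrans = K0)

    gi <- as.integer(group)
    day_frac <- c(d1 = config$day1_fraction, d9 = 1)
    traj <- list()
    for (p in params) {
      pj <- match(p, params)
      for (d in c("d1", "d9")) {
        eff <- config$biomarker_effect[gi, pj, d]
        coupling <- config$coupling_sign[p] * config$biomarker_coupling[p] *
          day_frac[d]
        jitter <- stats::rnorm(n, sd = config$measurement_sd)
        traj[[paste0(p, "_", d)]] <-
          base[, p] * eff * exp(coupling * zeta[, p] + jitter)
      }
    }

    mu <- config$day30_mean_relchange[gi]
    oracle <- (1 + mu) * (1 + s * u)
    L <- exp(stats::rnorm(n, sd = sigma) - sigma^2 / 2)
    V30 <- pmax(V0 * oracle * L, 1e-3)
  })

  coh <- data.frame(
    id = sprintf("animal_%03d", seq_len(n)),
    group = group,
    V_d0 = V0, V_d1 = traj$V_d1, V_d9 = traj$V_d9,
    PSA_d0 = PSA0, PSA_d1 = traj$PSA_d1, PSA_d9 = traj$PSA_d9,
    ADC_d0 = ADC0, ADC_d1 = traj$ADC_d1, ADC_d9 = traj$ADC_d9,
    Ktrans_d0 = K0, Ktrans_d1 = traj$Ktrans_d1, Ktrans_d9 = traj$Ktrans_d9,
    V_d30 = V30,
    stringsAsFactors = FALSE
  )
  structure(coh, config = config, seed = as.integer(seed),
            oracle = unname(oracle),
            class = c("mri_cohort", "data.frame"))
}

#' @export
print.mri_cohort <- function(x, ...) {
  cat(sprintf("<mri_cohort> %d animals in %d groups (seed %d)\n",
              nrow(x), nlevels(x$group), attr(x, "seed")))
  rel <- tapply(x$V_d30 / x$V_d0 - 1, x$group, mean)
  cat("  mean V30/V0 - 1 per group:\n")
  cat(sprintf("    %s: %+.3f\n", names(rel), rel), sep = "")
  invisible(x)
}

#' Write / read a cohort as CSV plus a JSON config sidecar
#'
#' The CSV holds one row per animal (all measurement columns); the sidecar
#' `<path>.json` records the generator configuration and master seed so a
#' cohort on disk is self-describing.
#'
#' @param cohort An `mri_cohort`.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns an
#'   `mri_cohort` (the config snapshot is restored from the sidecar; the
#'   in-memory `oracle` attribute is not persisted).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "mri_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  cfg <- unclass(attr(cohort, "config"))
  # flatten the [group, parameter, day] array column-major for JSON; write
  # named vectors as JSON objects so names survive the round trip
  cfg$biomarker_effect <- as.vector(cfg$biomarker_effect)
  for (nm in c("day30_mean_relchange", "day30_sd_relchange", "latent_weights",
               "biomarker_coupling", "coupling_sign")) {
    cfg[[nm]] <- as.list(cfg[[nm]])
  }
  cfg$baseline <- lapply(cfg$baseline, as.list)
  side <- list(seed = attr(cohort, "seed"), config = cfg)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  coh <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- side$config
  cfg$biomarker_effect <- array(
    as.numeric(cfg$biomarker_effect), dim = c(4L, 4L, 2L),
    dimnames = list(cfg$group_names, cfg$parameters, c("d1", "d9")))
  for (nm in c("day30_mean_relchange", "day30_sd_relchange", "latent_weights",
               "biomarker_coupling", "coupling_sign")) {
    cfg[[nm]] <- unlist(cfg[[nm]])
  }
  cfg$baseline <- lapply(cfg$baseline, unlist)
  class(cfg) <- "generator_config"
  coh$group <- factor(coh$group, levels = cfg$group_names)
  structure(coh, config = cfg, seed = as.integer(side$seed),
            class = c("mri_cohort", "data.frame"))
}
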