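test_that("noise-free degenerate config yields exactly the group means", {
  cfg <- generator_config(n_per_group = 4,
                          latent_outcome_scale = 0,
                          outcome_noise_sd = 0,
                          latent_weights = c(V = 0, PSA = 0, ADC = 0, Ktrans = 0),
                          measurement_sd = 0)
  coh <- simulate_cohort(cfg, seed = 5)
  rel <- coh$V_d30 / coh$V_d0 - 1
  expected <- cfg$day30_mean_relchange[as.character(coh$group)]
  expect_equal(unname(rel), unname(expected), tolerance = 1e-12)
})

test_that("simulation is deterministic given the seed", {
  cfg <- generator_config(n_per_group = 6)
  a <- simulate_cohort(cfg, seed = 42)
  b <- simulate_cohort(cfg, seed = 42)
  expect_identical(a, b)
  c <- simulate_cohort(cfg, seed = 43)
  expect_false(identical(a$V_d30, c$V_d30))
})

test_that("group means converge to the configured day-30 relative changes", {
  cfg <- generator_config(n_per_group = 500)
  coh <- simulate_cohort(cfg, seed = 2)
  rel <- coh$V_d30 / coh$V_d0 - 1
  for (g in levels(coh$group)) {
    vals <- rel[coh$group == g]
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - cfg$day30_mean_relchange[g]), 3 * se)
  }
})

test_that("outcome-noise calibration hits the generative-oracle correlation", {
  cfg <- generator_config(n_per_group = 1500)
  coh <- simulate_cohort(cfg, seed = 8)
  r <- pearson_cor(attr(coh, "oracle"), coh$V_d30 / coh$V_d0)$r
  expect_lt(abs(r - cfg$oracle_target_r), 0.02)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_per_group = 1), "n_per_group")
  expect_error(generator_config(day30_sd_relchange = c(control = -0.1, RT = 0.2,
                                                       ADT = 0.1, `ADT+RT` = 0.1)),
               "non-negative")
  expect_error(generator_config(group_names = c("a", "b", "c")), "4 distinct")
  expect_error(generator_config(latent_outcome_scale = 0.9), "must be < 1")
})

test_that("volumes and biomarkers stay positive", {
  coh <- simulate_cohort(generator_config(n_per_group = 300), seed = 3)
  num <- vapply(coh[, !(names(coh) %in% c("id", "group"))], min, numeric(1))
  expect_true(all(num > 0))
})

test_that("more outcome noise cannot strengthen biomarker-outcome coupling", {
  sig <- c(0.1, 0.4, 1.0)
  cors <- sapply(sig, function(s) {
    cfg <- generator_config(n_per_group = 250, outcome_noise_sd = s)
    mean(sapply(1:3, function(k) {
      coh <- simulate_cohort(cfg, seed = 100 + k)
      abs(pearson_cor(coh$ADC_d9 / coh$ADC_d0, coh$V_d30 / coh$V_d0)$r)
    }))
  })
  expect_true(all(diff(cors) < 0.02))  # non-increasing up to Monte-Carlo jitter
})

test_that("cohort CSV + JSON sidecar round trip preserves data and config", {
  cfg <- generator_config(n_per_group = 3)
  coh <- simulate_cohort(cfg, seed = 9)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_cohort(coh, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_cohort(path)
  plain <- function(d) data.frame(lapply(d, identity), stringsAsFactors = FALSE)
  expect_equal(plain(coh), plain(back), tolerance = 1e-12)
  cfg2 <- attr(back, "config")
  expect_equal(cfg2$day30_mean_relchange, cfg$day30_mean_relchange)
  expect_equal(cfg2$biomarker_effect, cfg$biomarker_effect)
  expect_equal(cfg2$outcome_noise_sd, cfg$outcome_noise_sd, tolerance = 1e-12)
  expect_equal(attr(back, "seed"), 9L)
})
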