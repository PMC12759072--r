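test_that("identical (config, seed) give byte-identical tables", {
  cfg <- medium_config("glu-aa", n = 5L, reps = 2L)
  a <- simulate_condition(cfg, "CIP", seed = 9)
  b <- simulate_condition(cfg, "CIP", seed = 9)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
})

test_that("input validation: lineage count and condition labels", {
  cfg <- medium_config("glu-aa", n = 0L)
  expect_error(simulate_condition(cfg, "CIP", seed = 1), "n_lineages")
  cfg$n_lineages <- 2L
  expect_error(simulate_condition(cfg, "CIP+AMP", seed = 1), "CIP\\+AMP")
  expect_error(simulate_lineage(cfg, "CIP+AMP", seed = 1), "CIP\\+AMP")
})

test_that("observation tables satisfy their structural invariants", {
  sim <- sim_cached("glu-aa", "CIP", n = 60L, seed = 11L)
  obs <- sim$observations
  expect_true(all(obs$length_um > 0))
  expect_true(all(obs$area_um2 > 0))
  expect_silent(validate_observations(obs))
  ## time is frame * dt
  expect_equal(obs$time_h, obs$frame * 5 / 60, tolerance = 1e-12)
  ## generation ids never decrease, and each boundary is a ~50% length drop
  by_lin <- split(obs, obs$lineage_id)
  for (lin in by_lin) {
    expect_true(all(diff(lin$generation_id) >= 0))
    jump <- which(diff(lin$generation_id) == 1) + 1L
    if (length(jump)) {
      ratio <- lin$length_um[jump] / lin$length_um[jump - 1L]
      expect_true(all(ratio < 0.75))
    }
  }
})

test_that("a drug-free population with zero death probability all survives", {
  cfg <- medium_config("glu-aa", n = 40L, late_death_prob = 0, loss_rate = 0)
  sim <- simulate_condition(cfg, "no-drug", seed = 3)
  expect_true(all(sim$truth$true_fate == "survive"))
  ## lineages grow and divide for the full duration
  ends <- sim$observations[, max(time_h), by = lineage_id]$V1
  expect_true(all(abs(ends - (cfg$t_end + cfg$discard_h)) < 1e-9))
})

test_that("noiseless lineages grow log-linearly at the configured rate", {
  cfg <- medium_config("glu-aa", n = 12L, measurement_noise_cv = 0,
                       loss_rate = 0, late_death_prob = 0, mu_cv = 0)
  sim <- simulate_condition(cfg, "no-drug", seed = 5)
  obs <- sim$observations
  fits <- fit_generations(obs)
  expect_true(all(abs(fits[valid == TRUE]$mu - cfg$mu_median) < 1e-9))
  ## and lengths never reach the channel bound under homeostatic division
  expect_true(max(obs$length_um) < cfg$max_channel_length)
})

test_that("high-SOS deaths arrest before the SOS spike and exceed 5x induced", {
  cfg <- medium_config("glu-aa", n = 1L, measurement_noise_cv = 0,
                       loss_rate = 0)
  found <- 0L
  for (s in 1:8) {
    sim <- simulate_lineage(cfg, "CIP", seed = 1000 + s,
                            fate_probs = c(survive = 0, die_low = 0,
                                           die_high = 1))
    if (sim$truth$true_fate != "die_high") next
    found <- found + 1L
    obs <- sim$observations
    expr <- obs$gfp_total / obs$area_um2
    growing <- which(diff(obs$length_um) > 1e-12)
    expect_lt(max(growing), which.max(expr))
    expect_gt(max(expr), 5 * cfg$sos_induced)
  }
  expect_gte(found, 5L)
})

test_that("post-death fluorescence bleaches exponentially at the set rate", {
  cfg <- medium_config("glu-aa", n = 1L, loss_rate = 0)
  sim <- simulate_lineage(cfg, "CIP", seed = 77,
                          fate_probs = c(survive = 0, die_low = 1,
                                         die_high = 0))
  expect_identical(sim$truth$true_fate, "die_low")
  obs <- sim$observations
  death_raw <- sim$truth$true_death_time + cfg$discard_h
  lag <- cfg$gfp_maturation_time / 60
  post <- obs[obs$time_h > death_raw + lag + 0.1, ]
  expect_gt(nrow(post), 20)
  ## least-squares oracle on the log signal
  fit <- stats::lm(log(mkate_total / area_um2) ~ time_h, data = post)
  expect_equal(unname(-coef(fit)[2]), cfg$bleach_rate, tolerance = 0.1)
  ## decay is monotone up to measurement noise: fitted trend strictly down
  expect_true(all(diff(fitted(fit)) < 0))
  ## elongation is exactly zero after death (pre-noise lengths frozen)
  cfg0 <- cfg; cfg0$measurement_noise_cv <- 0
  sim0 <- simulate_lineage(cfg0, "CIP", seed = 77,
                           fate_probs = c(survive = 0, die_low = 1,
                                          die_high = 0))
  obs0 <- sim0$observations
  frozen <- obs0[obs0$time_h >= sim0$truth$true_death_time + cfg$discard_h, ]
  expect_true(all(abs(diff(frozen$length_um)) < 1e-12))
})

test_that("truth-fate frequencies match the configured probabilities", {
  ## binomial sampling check at n = 2000 against (0.36, 0.52, 0.12)
  cfg <- medium_config("glu-aa", n = 2000L, replicate_jitter = 0,
                       loss_rate = 0)
  sim <- simulate_condition(cfg, "CIP", seed = 31)
  p <- cfg$fate_probs[["CIP"]]
  for (cls in c("survive", "die_low", "die_high")) {
    nm <- if (cls == "survive") "survive" else cls
    obs_frac <- mean(sim$truth$true_fate == nm)
    se <- sqrt(p[[cls]] * (1 - p[[cls]]) / 2000)
    expect_lt(abs(obs_frac - p[[cls]]), 3 * se + 1e-9)
  }
})

test_that("channel truncation and washout censor lineages as lost", {
  cfg <- medium_config("glu-aa", n = 150L, loss_rate = 0.02)
  sim <- simulate_condition(cfg, "CIP", seed = 13)
  lost <- sim$truth[true_fate == "lost"]
  expect_gt(nrow(lost), 10)
  expect_true(all(is.na(lost$true_death_time)))
  ends <- sim$observations[, .(t_last = max(time_h)), by = lineage_id]
  lost_ends <- ends[lineage_id %in% lost$lineage_id]
  expect_true(all(lost_ends$t_last < cfg$t_end + cfg$discard_h - 1e-9))
  ## hard truncation: no rows beyond the channel bound (up to meas. noise)
  expect_lt(max(sim$observations$length_um),
            cfg$max_channel_length * (1 + 6 * cfg$measurement_noise_cv))
  ## death times, where present, lie in the drug-induced window
  dd <- sim$truth[startsWith(true_fate, "die")]
  expect_true(all(dd$true_death_time >= cfg$t_drug_on &
                    dd$true_death_time <= cfg$t_drug_off + 3))
})
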