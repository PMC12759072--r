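## Fate-classifier behaviour on hand-built trajectories and on simulated
## populations with known ground truth.

hand_traj <- function(obs) lineage_trajectories(obs)

test_that("hand-built trajectories get the textbook calls", {
  tl <- test_timeline()
  tt <- seq(0, 24, by = 1 / 12)
  mu_ref <- 0.1

  ## constant growth throughout -> survived
  grow <- synthetic_lineage(tt, 2 * exp(0.1 * tt), lineage_id = 1L)
  f <- classify_fates(hand_traj(grow), timeline = tl, mu_ref = mu_ref)
  expect_identical(f$fate, "survived")

  ## elongation zero from hour 5 onward -> died at 5
  len <- 2 * exp(0.1 * pmin(tt, 5))
  dead <- synthetic_lineage(tt, len, lineage_id = 2L)
  f <- classify_fates(hand_traj(dead), timeline = tl, mu_ref = mu_ref)
  expect_identical(f$fate, "died")
  expect_equal(f$death_time, 5, tolerance = 0.25)

  ## 2 h arrest at hour 6 followed by sustained full-rate regrowth -> survived
  grown <- cumsum(c(0, 0.1 * diff(tt) * !(tt[-1] > 6 & tt[-1] <= 8)))
  pers <- synthetic_lineage(tt, 2 * exp(grown), lineage_id = 3L)
  f <- classify_fates(hand_traj(pers), timeline = tl, mu_ref = mu_ref)
  expect_identical(f$fate, "survived")

  ## observation stops at hour 10 without arrest -> censored there
  short <- synthetic_lineage(tt[tt <= 10], 2 * exp(0.1 * tt[tt <= 10]),
                             lineage_id = 4L)
  f <- classify_fates(hand_traj(short), timeline = tl, mu_ref = mu_ref)
  expect_identical(f$fate, "censored")
  expect_equal(f$censor_time, 10, tolerance = 1e-6)

  expect_error(classify_fates(hand_traj(grow)[0], timeline = tl,
                              mu_ref = mu_ref), "empty")
})

test_that("classification is invariant to uniform length rescaling", {
  sim <- sim_cached("glu-aa", "CIP", n = 60L, seed = 11L)
  tl <- test_timeline()
  ret <- retain_observations(sim$observations)
  f1 <- classify_fates(lineage_trajectories(ret), timeline = tl)
  ret2 <- data.table::copy(ret)[, `:=`(length_um = length_um * 3,
                                       area_um2 = area_um2 * 3)]
  f2 <- classify_fates(lineage_trajectories(ret2), timeline = tl)
  expect_identical(f1$fate, f2$fate)
  expect_equal(f1$death_time, f2$death_time)
})

test_that("QC removes initially filamented and non-growing lineages", {
  tl <- test_timeline()
  tt <- seq(0, 24, by = 1 / 12)
  healthy <- rbindlist(lapply(1:10, function(i)
    synthetic_lineage(tt, (1.8 + 0.05 * i) * exp(0.5 * (tt %% 1.4)),
                      lineage_id = i,
                      generation_id = floor(tt / 1.4))))
  fil <- synthetic_lineage(tt, 10 * exp(0.5 * (tt %% 1.4)),
                           lineage_id = 98L,
                           generation_id = floor(tt / 1.4))
  flat <- synthetic_lineage(tt, rep(2, length(tt)), lineage_id = 99L)
  traj <- lineage_trajectories(rbind(healthy, fil, flat))
  qc <- apply_qc_filters(traj, classifier_params(), tl)
  expect_setequal(qc$exclusions$lineage_id, c(98L, 99L))
  expect_identical(qc$exclusions[lineage_id == 98L]$qc_reason,
                   "initially filamented")
  expect_identical(qc$exclusions[lineage_id == 99L]$qc_reason,
                   "non-growing at start")
  expect_false(any(qc$kept$lineage_id %in% c(98L, 99L)))

  ## a healthy simulated drug-free population is essentially untouched
  ana <- analysis_cached("glu-aa", "no-drug", n = 300L, seed = 301L)
  kept_frac <- 1 - nrow(ana$qc_exclusions) /
    (nrow(ana$qc_exclusions) + length(unique(ana$fates$lineage_id)))
  expect_gte(kept_frac, 0.99)
})

test_that("fates and death times recover the simulated ground truth", {
  for (med in c("glu-aa", "gly")) {
    sim <- sim_cached(med, "CIP", n = 500L, reps = 1L, seed = 101L)
    ana <- analysis_cached(med, "CIP", n = 500L, reps = 1L, seed = 101L)
    cmp <- compare_to_truth(ana, sim)
    expect_gte(mean(cmp$fate == cmp$truth_lab), 0.95)
    dd <- cmp[fate == "died" & truth_lab == "died"]
    dt_h <- if (med == "gly") 1 / 6 else 1 / 12
    expect_lte(median(abs(dd$death_time - dd$true_death_time)) / dt_h, 2)
  }
})

test_that("with zero measurement noise the confusion matrix is diagonal", {
  cfg <- medium_config("glu-aa", n = 150L, measurement_noise_cv = 0,
                       loss_rate = 0)
  sim <- simulate_condition(cfg, "CIP", seed = 51)
  ana <- analyse_condition(sim$observations, make_timeline(cfg))
  cmp <- compare_to_truth(ana, sim)
  expect_identical(cmp$fate, cmp$truth_lab)
  ## sub-classes too
  dead <- cmp[fate == "died"]
  expect_equal(dead$sos_class,
               c(die_low = "low", die_high = "high")[dead$true_fate],
               ignore_attr = TRUE)
})

test_that("SOS threshold arithmetic, fallback, and monotonicity", {
  ## survivors' final-2h median 227 a.u. and multiplier 3 -> threshold 681
  tl <- test_timeline()
  tt <- seq(0, 24, by = 1 / 12)
  surv <- rbindlist(lapply(1:25, function(i) {
    s <- synthetic_lineage(tt, 2 * exp(0.1 * tt), lineage_id = i,
                           gfp_per_area = 227)
    s
  }))
  traj <- lineage_trajectories(surv)
  fates <- classify_fates(traj, timeline = tl, mu_ref = 0.1)
  thr <- sos_threshold(traj, fates, classifier_params(), tl)
  expect_equal(thr, 681, tolerance = 1e-9)

  ## too few survivors: fallback with a warning
  few <- fates[1:5]
  expect_warning(thr2 <- sos_threshold(traj, few, classifier_params(), tl),
                 "fallback")
  expect_equal(thr2, classifier_params()$sos_threshold_fallback)

  ## raising the multiplier never increases the high-SOS count
  sim <- sim_cached("glu-aa", "CIP", n = 200L, seed = 11L)
  ret <- retain_observations(sim$observations)
  trj <- lineage_trajectories(ret)
  ft <- classify_fates(trj, timeline = tl)
  counts <- vapply(c(1.5, 3, 6, 12), function(mult) {
    p <- classifier_params(sos_threshold_multiplier = mult)
    th <- sos_threshold(trj, ft, p, tl)
    sum(classify_sos(trj, ft, th, tl)$sos_class == "high", na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("simulated SOS classes separate cleanly at the default threshold", {
  sim <- sim_cached("glu-aa", "CIP", n = 500L, reps = 1L, seed = 101L)
  ana <- analysis_cached("glu-aa", "CIP", n = 500L, reps = 1L, seed = 101L)
  cmp <- compare_to_truth(ana, sim)
  hi <- cmp[true_fate == "die_high" & fate == "died"]
  expect_gte(mean(hi$sos_class == "high"), 0.95)
  lo <- cmp[true_fate == "die_low" & fate == "died"]
  expect_gte(mean(lo$sos_class == "low"), 0.95)
})

test_that("fate decomposition fractions sum to one", {
  ana <- analysis_cached("glu-aa", "CIP", n = 200L, seed = 11L)
  d <- ana$decomposition
  expect_equal(d$survived + d$died_low + d$died_high + d$censored,
               rep(1, nrow(d)), tolerance = 1e-12)
})
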