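## Stochastic generator of mother-machine measurement tables.
##
## Each lineage is the mother cell at the closed end of one microchannel:
## exponential elongation at a cell-specific rate, sizer division (divide at
## twice the birth length, mother keeps the proximal half), drug effects on
## the rate (TET) and on fate (CIP), post-death reporter bleaching, terminal
## filamentation of high-SOS cells, and censoring by washout or by the cell
## out-growing the microchannel.

obs_schema <- function() c("condition", "replicate_id", "lineage_id",
                           "generation_id", "frame", "time_h", "length_um",
                           "area_um2", "gfp_total", "mkate_total")

draw_fate <- function(probs, u) {
  c("survive", "die_low", "die_high")[findInterval(u, cumsum(probs),
                                                   left.open = TRUE) + 1L]
}

#' Simulate one mother-cell lineage
#'
#' Deterministic given `(config, condition, seed)`. Returns the per-frame
#' measurement rows (raw clock: frame 0 is the start of the burn-in,
#' `discard_h` hours before retained hour 0) and the ground-truth record.
#'
#' The fate is drawn from the condition's fate probabilities (CIP arms) or
#' from the small age-related late-death hazard (drug-free and TET arms).
#' Death freezes the length; both reporter concentrations subsequently decay
#' at `bleach_rate` after the maturation lag. High-SOS deaths are preceded by
#' a bounded window of filamentation (division suppressed) and followed by a
#' concentration ramp to `high_sos_multiplier` times the induced level while
#' the volume is frozen. Lineages are truncated without a death event when
#' washout strikes first or the cell out-grows the microchannel.
#'
#' @param config a [sim_config()].
#' @param condition one of [mm_conditions()].
#' @param seed integer seed for this lineage's private stream.
#' @param replicate_id,lineage_id identifiers stamped into the rows.
#' @param fate_probs optional override of the condition's
#'   `c(survive, die_low, die_high)` probabilities (used for replicate
#'   jitter).
#' @return list with elements `observations` (data.table in the documented
#'   schema) and `truth` (one-row data.table: `condition`, `replicate_id`,
#'   `lineage_id`, `true_fate`, `true_death_time` (retained hours, `NA`
#'   unless dead), `true_mu`).
#' @export
simulate_lineage <- function(config, condition, seed,
                             replicate_id = 1L, lineage_id = 1L,
                             fate_probs = NULL) {
  if (!condition %in% mm_conditions())
    stop("unknown condition label: '", condition, "'")
  validate_sim_config(config)
  set.seed(seed)

  dt <- config$frame_interval / 60
  burn <- config$discard_h
  t_on <- config$t_drug_on + burn      # raw clock
  t_off <- config$t_drug_off + burn
  t_end <- config$t_end + burn
  n_f <- as.integer(round(t_end / dt)) + 1L
  time_raw <- (seq_len(n_f) - 1L) * dt
  has_cip <- condition_has_cip(condition)
  has_tet <- condition_has_tet(condition)

  ## --- cell-specific parameters -------------------------------------------
  mu_i <- config$mu_median * exp(rnorm(1, 0, sdlog_from_cv(config$mu_cv)))
  z <- rnorm(3, 0, sdlog_from_cv(config$sos_cv))
  sos_base_i <- config$sos_baseline * exp(z[1])
  sos_ind_i <- config$sos_induced * exp(z[2])
  mkate_i <- config$mkate_baseline * exp(z[3])

  ## --- fate and event times -----------------------------------------------
  probs <- fate_probs %||% config$fate_probs[[condition]]
  u <- runif(1)
  if (has_cip) {
    fate <- draw_fate(probs, u)
    death_raw <- if (fate != "survive")
      runif(1, t_on + 1, t_off + 3) else NA_real_
  } else {
    fate <- if (u < (1 - probs[["survive"]]) + config$late_death_prob)
      "die_low" else "survive"
    death_raw <- if (fate != "survive") runif(1, t_end - 4, t_end) else NA_real_
  }
  washout_raw <- if (config$loss_rate > 0)
    rexp(1, config$loss_rate) else Inf

  ## --- elongation-rate series ---------------------------------------------
  red <- if (condition == "CIP-TET") config$tet_reduction_combo
         else config$tet_reduction
  m <- rep(1, n_f)
  if (has_tet && red > 0) {
    on_idx <- time_raw >= t_on & time_raw < t_off
    m[on_idx] <- 1 - red * (1 - exp(-(time_raw[on_idx] - t_on) /
                                      config$tet_relax_time))
    off_idx <- time_raw >= t_off
    red_off <- red * (1 - exp(-(t_off - t_on) / config$tet_relax_time))
    m[off_idx] <- 1 - red_off * exp(-(time_raw[off_idx] - t_off) /
                                      config$tet_relax_time)
  }
  rate <- mu_i * m
  if (!is.na(death_raw)) rate[time_raw >= death_raw] <- 0

  ## --- division suppression (filamentation) -------------------------------
  suppress <- rep(FALSE, n_f)
  if (fate == "die_high")
    suppress[time_raw >= death_raw - config$filament_before_death] <- TRUE
  fil_draw <- runif(2) # fixed draw count keeps the stream layout stable
  if (fate == "survive" && has_cip &&
      fil_draw[1] < config$filament_prob_survivor) {
    fs <- t_on + fil_draw[2] * (t_off - t_on - 2)
    fd <- runif(1, 0.5, 1.5)
    suppress[time_raw >= fs & time_raw < fs + fd] <- TRUE
  }

  ## --- growth and division ------------------------------------------------
  ## sizer: divide on reaching twice the target birth length (noisy
  ## threshold redrawn each generation) -- absolute size control, so birth
  ## sizes stay homeostatic instead of random-walking upward
  sd_div <- config$division_noise_cv
  log_len <- numeric(n_f)
  gen <- integer(n_f)
  cur <- log(config$birth_length) + rnorm(1, 0, sd_div)
  g <- 0L
  thr <- log(2 * config$birth_length) + rnorm(1, 0, sd_div)
  max_log <- log(config$max_channel_length)
  end_i <- n_f
  truncated <- FALSE
  for (i in seq_len(n_f)) {
    if (i > 1L) cur <- cur + rate[i - 1L] * dt
    if (time_raw[i] > washout_raw || cur > max_log) {
      end_i <- i - 1L
      truncated <- TRUE
      break
    }
    if (!suppress[i] && cur >= thr) {
      cur <- cur - log(2)               # mother keeps the proximal half
      g <- g + 1L
      thr <- log(2 * config$birth_length) + rnorm(1, 0, sd_div)
    }
    log_len[i] <- cur
    gen[i] <- g
  }

  ## truth: death only counts if it happened while the lineage was observed
  observed_end <- if (end_i >= 1L) time_raw[end_i] else -Inf
  died_observed <- !is.na(death_raw) && death_raw <= observed_end
  true_fate <- if (truncated && !died_observed) "lost"
               else if (!is.na(death_raw) && fate != "survive" && died_observed)
                 fate
               else "survive"
  truth <- data.table(
    condition = condition, replicate_id = as.integer(replicate_id),
    lineage_id = as.integer(lineage_id),
    true_fate = true_fate,
    true_death_time = if (startsWith(true_fate, "die"))
      death_raw - burn else NA_real_,
    true_mu = mu_i)

  if (end_i < 1L)
    return(list(observations = empty_observations(), truth = truth))

  idx <- seq_len(end_i)
  tt <- time_raw[idx]

  ## --- reporter concentrations --------------------------------------------
  mat <- config$gfp_maturation_time / 60
  sos_conc <- function(t) { # pre-death SOS concentration at raw time t
    out <- rep(sos_base_i, length(t))
    if (has_cip) {
      tau <- config$expr_relax_time
      ris <- t >= t_on + mat & t < t_off + mat
      out[ris] <- sos_ind_i + (sos_base_i - sos_ind_i) *
        exp(-(t[ris] - t_on - mat) / tau)
      pst <- t >= t_off + mat
      c_off <- sos_ind_i + (sos_base_i - sos_ind_i) *
        exp(-(t_off - t_on) / tau)
      out[pst] <- sos_base_i + (c_off - sos_base_i) *
        exp(-(t[pst] - t_off - mat) / config$sos_recovery_time)
    }
    out
  }
  c_sos <- sos_conc(tt)
  c_mk <- rep(mkate_i, end_i)
  if (died_observed) {
    t_d <- death_raw + mat               # bleaching starts after maturation
    dead <- tt >= t_d
    c_at_death <- sos_conc(t_d)
    if (fate == "die_high") {
      peak <- config$high_sos_multiplier * sos_ind_i
      ramp <- dead & tt < t_d + config$spike_rise_time
      c_sos[ramp] <- c_at_death + (peak - c_at_death) *
        (tt[ramp] - t_d) / config$spike_rise_time
      post <- tt >= t_d + config$spike_rise_time
      c_sos[post] <- peak *
        exp(-config$bleach_rate * (tt[post] - t_d - config$spike_rise_time))
    } else {
      c_sos[dead] <- c_at_death * exp(-config$bleach_rate * (tt[dead] - t_d))
    }
    c_mk[dead] <- mkate_i * exp(-config$bleach_rate * (tt[dead] - t_d))
  }

  ## --- observed table ------------------------------------------------------
  len <- exp(log_len[idx])
  area <- len * config$cell_width
  cv <- config$measurement_noise_cv
  obs <- data.table(
    condition = condition,
    replicate_id = as.integer(replicate_id),
    lineage_id = as.integer(lineage_id),
    generation_id = gen[idx],
    frame = idx - 1L,
    time_h = tt,
    length_um = len * mult_noise(end_i, cv),
    area_um2 = area * mult_noise(end_i, cv),
    gfp_total = c_sos * area * mult_noise(end_i, cv),
    mkate_total = c_mk * area * mult_noise(end_i, cv))
  list(observations = obs, truth = truth)
}

empty_observations <- function() {
  data.table(condition = character(), replicate_id = integer(),
             lineage_id = integer(), generation_id = integer(),
             frame = integer(), time_h = numeric(), length_um = numeric(),
             area_um2 = numeric(), gfp_total = numeric(),
             mkate_total = numeric())
}

#' Simulate all replicates of one condition
#'
#' Runs `n_replicates` independent replicates of `n_lineages` mother-cell
#' lineages each. Per-replicate fate probabilities receive a small absolute
#' jitter on the survival probability (SD `replicate_jitter`, dying classes
#' rescaled proportionally) emulating day-to-day variability; per-lineage
#' seeds are derived with [derive_seed()] so the output is reproducible and
#' stable under changes of `n_lineages`.
#'
#' @param config a [sim_config()].
#' @param condition one of [mm_conditions()].
#' @param seed master seed for this condition.
#' @return list with `observations` (data.table, documented schema) and
#'   `truth` (one row per lineage).
#' @export
simulate_condition <- function(config, condition, seed) {
  if (config$n_lineages < 1L) stop("n_lineages must be >= 1")
  if (!condition %in% mm_conditions())
    stop("unknown condition label: '", condition, "'")
  cond_idx <- match(condition, mm_conditions())
  obs_list <- vector("list", config$n_replicates * config$n_lineages)
  truth_list <- vector("list", length(obs_list))
  k <- 0L
  for (r in seq_len(config$n_replicates)) {
    probs <- config$fate_probs[[condition]]
    if (config$replicate_jitter > 0 && condition_has_cip(condition)) {
      set.seed(derive_seed(seed, cond_idx, r, 0L))
      p_s <- min(max(probs[["survive"]] + rnorm(1, 0, config$replicate_jitter),
                     0.01), 0.99)
      rest <- probs[c("die_low", "die_high")]
      rest <- if (sum(rest) > 0) rest * (1 - p_s) / sum(rest) else c(0, 0)
      probs <- c(survive = p_s, rest)
    }
    for (l in seq_len(config$n_lineages)) {
      k <- k + 1L
      sim <- simulate_lineage(config, condition,
                              seed = derive_seed(seed, cond_idx, r, l),
                              replicate_id = r, lineage_id = l,
                              fate_probs = probs)
      obs_list[[k]] <- sim$observations
      truth_list[[k]] <- sim$truth
    }
  }
  list(observations = rbindlist(obs_list),
       truth = rbindlist(truth_list))
}

#' Write / read simulated tables as stamped CSV
#'
#' `write_observations()` writes the measurement table (and optionally the
#' ground truth alongside, suffixed `_truth.csv`) in the documented schema:
#' `condition,replicate_id,lineage_id,generation_id,frame,time_h,length_um,`
#' `area_um2,gfp_total,mkate_total` (UTF-8, `.` decimal, LF newlines).
#'
#' @param sim result of [simulate_condition()], or a bare observation table.
#' @param path output CSV path.
#' @param config,seed provenance recorded in the stamp line.
#' @return `path`, invisibly.
#' @export
write_observations <- function(sim, path, config = NULL, seed = NULL) {
  obs <- if (is.data.frame(sim)) sim else sim$observations
  write_stamped_csv(obs[, obs_schema(), with = FALSE], path, config, seed)
  if (!is.data.frame(sim) && !is.null(sim$truth)) {
    write_stamped_csv(sim$truth, sub("\\.csv$", "_truth.csv", path),
                      config, seed)
  }
  invisible(path)
}
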