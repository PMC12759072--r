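## Lineage fate classification: QC filters, death/censoring calls with death
## times, and low/high-SOS sub-classification of dead lineages.
##
## A lineage is called dead when its instantaneous elongation rate falls
## below a small fraction of the drug-free median and stays there — with no
## later excursion above the recovery fraction — until the end of
## observation. The rate is measured as the rolling OLS slope of the
## division-corrected log-length curve; the smoothing window is widened
## automatically when measurement noise would otherwise make the slope
## estimate comparable to the thresholds (slow media, coarse frames). The
## death time is then refined as the point where the growth curve first
## reaches its post-arrest plateau.

#' Classifier tuning parameters
#'
#' @param arrest_fraction fraction of the drug-free median elongation rate
#'   below which a cell counts as arrested.
#' @param arrest_window hours of sustained arrest required for a death call.
#' @param recovery_fraction fraction of the drug-free median above which any
#'   later growth voids a death call.
#' @param sos_threshold_multiplier fold over the survivors' steady-state
#'   median SOS expression defining the high-SOS class.
#' @param sos_threshold_fallback absolute threshold (a.u.) used when too few
#'   survivors are available to anchor the relative threshold.
#' @param max_channel_length microchannel length, micrometres (hyper-
#'   filamented lineages are censored at this bound, never called dead).
#' @param smooth_window rolling-slope window in hours; `NULL` (default)
#'   chooses it from the estimated measurement noise so that the slope SD is
#'   at most a quarter of the recovery threshold.
#' @param qc_filament_multiple QC: lineages whose mean length in the first
#'   two retained hours exceeds this multiple of the population median birth
#'   length are excluded as initially filamented.
#' @return a `classifier_params` list.
#' @export
classifier_params <- function(arrest_fraction = 0.05,
                              arrest_window = 1,
                              recovery_fraction = 0.2,
                              sos_threshold_multiplier = 3,
                              sos_threshold_fallback = 1000,
                              max_channel_length = 40,
                              smooth_window = NULL,
                              qc_filament_multiple = 4) {
  stopifnot(arrest_fraction > 0, recovery_fraction > arrest_fraction,
            recovery_fraction < 1, arrest_window > 0,
            sos_threshold_multiplier > 0)
  structure(mget(names(formals())), class = "classifier_params")
}

## residual SD of the growth curve about its local trend, estimated from
## first differences (robust, per lineage, then pooled by median)
estimate_growth_noise <- function(traj) {
  d <- traj[, {
    dd <- diff(growth_curve)
    list(s = stats::mad(dd, na.rm = TRUE) / sqrt(2))
  }, by = eval(lin_keys())]
  stats::median(d$s, na.rm = TRUE)
}

## smoothing window (hours) such that the rolling-slope SD due to
## measurement noise sigma is <= (recovery_fraction * mu_ref) / z
auto_smooth_window <- function(sigma, dt_h, mu_ref, recovery_fraction,
                               arrest_window, z = 4) {
  target <- recovery_fraction * mu_ref / z
  w <- (z * sigma * sqrt(12 * dt_h) / (recovery_fraction * mu_ref))^(2 / 3)
  max(arrest_window, w, 3 * dt_h)
}

#' Drug-free reference elongation rate
#'
#' Median of the valid per-generation fitted rates over the pre-drug window,
#' pooled across lineages — the `mu_ref` against which arrest and recovery
#' thresholds are set.
#'
#' @param fits a [fit_generations()] table on the retained clock.
#' @param timeline a [make_timeline()] list.
#' @return scalar, 1/h.
#' @export
reference_mu <- function(fits, timeline) {
  f <- as.data.table(fits)[valid & birth_time < timeline$t_on]
  if (nrow(f) == 0L) stop("no valid pre-drug generation fits")
  median(f$mu, na.rm = TRUE)
}

#' Quality-control filters on the pre-drug window
#'
#' Excludes lineages that were initially filamented (mean length in the
#' first two retained hours above `qc_filament_multiple` times the
#' population median birth length) or initially non-growing (fitted growth
#' rate over the first two hours below `arrest_fraction` times the
#' population median rate).
#'
#' @param traj trajectory table on the retained clock.
#' @param params a [classifier_params()].
#' @param timeline a [make_timeline()] list.
#' @return list: `kept` (trajectory table restricted to surviving QC),
#'   `exclusions` (data.table of lineage keys and reasons).
#' @export
apply_qc_filters <- function(traj, params = classifier_params(),
                             timeline) {
  traj <- as.data.table(traj)
  pre <- traj[time_h < timeline$t_on]
  early <- pre[, {
    n <- .N
    if (n >= 3) {
      tt <- time_h; y <- growth_curve
      b <- sum((tt - mean(tt)) * (y - mean(y))) / sum((tt - mean(tt))^2)
    } else b <- NA_real_
    .(mean_len = mean(length_um), pre_rate = b,
      birth_len = min(length_um))
  }, by = eval(lin_keys())]
  med_birth <- median(early$birth_len, na.rm = TRUE)
  med_rate <- median(early$pre_rate, na.rm = TRUE)
  early[, qc_reason := fifelse(
    mean_len > params$qc_filament_multiple * med_birth, "initially filamented",
    fifelse(!is.na(pre_rate) & pre_rate < params$arrest_fraction * med_rate,
            "non-growing at start", NA_character_))]
  excl <- early[!is.na(qc_reason), c(lin_keys(), "qc_reason"), with = FALSE]
  kept <- traj[!excl, on = lin_keys()]
  list(kept = kept, exclusions = excl)
}

## classify one lineage from its ordered frames; internal worker
classify_one <- function(time_h, growth_curve, params, timeline,
                         mu_ref, k_smooth, sigma) {
  n <- length(time_h)
  dt_h <- timeline$dt
  ends_early <- time_h[n] < timeline$t_end - 1.5 * dt_h
  if (n < max(5L, k_smooth)) {
    return(list(fate = if (ends_early) "censored" else "survived",
                death_time = NA_real_,
                censor_time = if (ends_early) time_h[n] else NA_real_))
  }
  r <- rolling_slope(growth_curve, dt_h, k_smooth)
  thr_a <- params$arrest_fraction * mu_ref
  thr_r <- params$recovery_fraction * mu_ref
  below <- r < thr_a
  high <- which(r > thr_r)
  i_min <- if (length(high)) max(high) + 1L else 1L
  w_frames <- max(1L, as.integer(round(params$arrest_window / dt_h)))
  death_time <- NA_real_
  ## earliest frame >= drug onset, after the last recovery-level excursion,
  ## from which the rate stays below the arrest threshold for arrest_window
  cand <- which(seq_len(n) >= i_min & time_h >= timeline$t_on &
                  seq_len(n) <= n - w_frames)
  if (length(cand)) {
    cs <- cumsum(below)
    ok <- cand[(cs[cand + w_frames] - cs[cand] + below[cand]) >= w_frames + 1L]
    if (length(ok)) {
      i0 <- ok[1]
      ## refine: the growth curve is flat after death; find where it first
      ## reaches the plateau
      plateau_idx <- which(time_h >= time_h[i0] &
                             time_h <= time_h[i0] + 3)
      plateau <- median(growth_curve[plateau_idx])
      margin <- max(2 * sigma, 0.02)
      crossed <- which(growth_curve >= plateau - margin &
                         time_h >= timeline$t_on - params$arrest_window)
      death_time <- if (length(crossed)) max(time_h[crossed[1]], timeline$t_on)
                    else time_h[i0]
    }
  }
  if (!is.na(death_time)) {
    list(fate = "died", death_time = death_time, censor_time = NA_real_)
  } else if (ends_early) {
    list(fate = "censored", death_time = NA_real_, censor_time = time_h[n])
  } else {
    list(fate = "survived", death_time = NA_real_, censor_time = NA_real_)
  }
}

#' Classify lineage fates
#'
#' Applies the arrest/recovery rule to every lineage of a trajectory table
#' (retained clock): died (with death time), censored (observation ends
#' before the experiment does: washout or hyper-filamentation), or survived.
#' Death takes precedence over later censoring.
#'
#' @param traj trajectory table (ideally QC-filtered).
#' @param params a [classifier_params()].
#' @param timeline a [make_timeline()] list.
#' @param mu_ref drug-free reference rate; computed from the data when
#'   omitted.
#' @return data.table: lineage keys, `fate`, `death_time`, `censor_time`.
#' @export
classify_fates <- function(traj, params = classifier_params(), timeline,
                           mu_ref = NULL) {
  traj <- as.data.table(traj)
  if (nrow(traj) == 0L) stop("empty trajectory table")
  setorderv(traj, c(lin_keys(), "frame"))
  if (is.null(mu_ref)) {
    fits <- fit_generations(traj)
    mu_ref <- reference_mu(fits, timeline)
  }
  sigma <- estimate_growth_noise(traj)
  w <- params$smooth_window %||%
    auto_smooth_window(sigma, timeline$dt, mu_ref,
                       params$recovery_fraction, params$arrest_window)
  k <- max(3L, as.integer(round(w / timeline$dt)))
  if (k %% 2L == 0L) k <- k + 1L
  fates <- traj[, classify_one(time_h, growth_curve, params, timeline,
                               mu_ref, k, sigma),
                by = eval(lin_keys())]
  fates[]
}

#' SOS threshold separating low- and high-SOS dead cells
#'
#' The threshold is `sos_threshold_multiplier` times the median SOS
#' expression of *surviving* lineages over the final two hours of drug
#' exposure (their steady state). With fewer than `min_survivors` survivors
#' the configured absolute fallback is used with a warning.
#'
#' @param traj trajectory table (retained clock).
#' @param fates a [classify_fates()] table.
#' @param params a [classifier_params()].
#' @param timeline a [make_timeline()] list.
#' @param min_survivors minimum surviving lineages required (default 20).
#' @return scalar threshold, a.u.
#' @export
sos_threshold <- function(traj, fates, params = classifier_params(),
                          timeline, min_survivors = 20L) {
  surv <- as.data.table(fates)[fate == "survived"]
  if (nrow(surv) < min_survivors) {
    warning("fewer than ", min_survivors,
            " survivors; using the absolute fallback SOS threshold")
    return(params$sos_threshold_fallback)
  }
  tr <- as.data.table(traj)[surv[, lin_keys(), with = FALSE],
                            on = lin_keys()]
  m <- window_median(tr, "sos_expression", timeline$t_off - 2, timeline$t_off)
  params$sos_threshold_multiplier * m
}

#' Sub-classify dead lineages by their SOS response
#'
#' For each dead lineage the peak SOS expression between drug onset and
#' three hours past death (capturing the post-arrest concentration spike of
#' high-SOS cells) is compared to the threshold.
#'
#' @param traj trajectory table (retained clock).
#' @param fates a [classify_fates()] table.
#' @param threshold from [sos_threshold()].
#' @param timeline a [make_timeline()] list.
#' @return `fates` with `sos_class` (`"low"`, `"high"`, or
#'   `"not_applicable"`) and `peak_sos` columns added.
#' @export
classify_sos <- function(traj, fates, threshold, timeline) {
  fates <- copy(as.data.table(fates))
  dead <- fates[fate == "died"]
  if (nrow(dead)) {
    tr <- as.data.table(traj)[dead[, c(lin_keys(), "death_time"),
                                   with = FALSE], on = lin_keys()]
    peaks <- tr[time_h >= timeline$t_on & time_h <= death_time + 3,
                .(peak_sos = max(sos_expression)), by = eval(lin_keys())]
    fates[peaks, peak_sos := i.peak_sos, on = lin_keys()]
    fates[fate == "died",
          sos_class := fifelse(peak_sos >= threshold, "high", "low")]
  }
  if (!"peak_sos" %in% names(fates)) fates[, peak_sos := NA_real_]
  if (!"sos_class" %in% names(fates)) fates[, sos_class := NA_character_]
  fates[fate != "died", sos_class := "not_applicable"]
  fates[]
}

#' Fate decomposition of a classified population
#'
#' Fractions of lineages classified survived, low-SOS dead, high-SOS dead
#' and censored; the four fractions sum to one per condition/replicate
#' grouping.
#'
#' @param fates a [classify_sos()] table.
#' @param by grouping columns (default `"condition"`).
#' @return data.table with `n` and the four fraction columns.
#' @export
fate_decomposition <- function(fates, by = "condition") {
  f <- as.data.table(fates)
  f[, .(n = .N,
        survived = mean(fate == "survived"),
        died_low = mean(fate == "died" & sos_class == "low"),
        died_high = mean(fate == "died" & sos_class == "high"),
        censored = mean(fate == "censored")),
    by = by]
}
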