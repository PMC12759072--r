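## Per-generation elongation-rate fits, per-frame expression levels, lineage
## trajectories and windowed population distributions.

lin_keys <- function() c("condition", "replicate_id", "lineage_id")

#' Fit an exponential elongation rate to one generation
#'
#' Ordinary least squares of `log(length)` against time: the cell-length
#' model is `S_t = S_0 * exp(mu * t)` with `mu` the elongation rate (1/h) and
#' `S_0` the birth length. Fits with fewer than 3 frames are flagged invalid
#' and carry `mu = NA` (the minimum-3-frames fitting constraint).
#'
#' @param time_h strictly increasing times, hours.
#' @param length_um positive cell lengths, micrometres.
#' @return one-row data.table: `mu`, `s0` (length predicted at the first
#'   frame), `n_frames`, `r2`, `valid`, `birth_time`, `end_time`.
#' @export
fit_elongation_rate <- function(time_h, length_um) {
  if (any(length_um <= 0)) stop("lengths must be positive to log-transform")
  if (is.unsorted(time_h, strictly = TRUE))
    stop("times must be strictly increasing")
  n <- length(time_h)
  if (n < 3L) {
    return(data.table(mu = NA_real_, s0 = NA_real_, n_frames = n,
                      r2 = NA_real_, valid = FALSE,
                      birth_time = time_h[1], end_time = time_h[n]))
  }
  y <- log(length_um)
  mt <- mean(time_h); my <- mean(y)
  sxx <- sum((time_h - mt)^2)
  b <- sum((time_h - mt) * (y - my)) / sxx
  a <- my - b * mt
  ss_tot <- sum((y - my)^2)
  ss_res <- sum((y - (a + b * time_h))^2)
  data.table(mu = b, s0 = exp(a + b * time_h[1]), n_frames = n,
             r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
             valid = TRUE, birth_time = time_h[1], end_time = time_h[n])
}

#' Fit elongation rates for every generation of an observation table
#'
#' Vectorised closed-form least squares grouped by
#' `(condition, replicate_id, lineage_id, generation_id)`; identical to
#' applying [fit_elongation_rate()] per generation.
#'
#' @param obs an observation table (documented CSV schema).
#' @return data.table of generation fits keyed by lineage and generation.
#' @export
fit_generations <- function(obs) {
  if (any(obs$length_um <= 0)) stop("lengths must be positive to log-transform")
  dt <- as.data.table(obs)[, .(condition, replicate_id, lineage_id,
                               generation_id, time_h, y = log(length_um))]
  s <- dt[, .(n_frames = .N, st = sum(time_h), sy = sum(y),
              stt = sum(time_h^2), sty = sum(time_h * y), syy = sum(y^2),
              birth_time = min(time_h), end_time = max(time_h)),
          by = c(lin_keys(), "generation_id")]
  n <- s$n_frames
  sxx <- s$stt - s$st^2 / n
  sxy <- s$sty - s$st * s$sy / n
  ss_tot <- s$syy - s$sy^2 / n
  b <- ifelse(n >= 3 & sxx > 0, sxy / sxx, NA_real_)
  a <- s$sy / n - b * s$st / n
  ss_res <- pmax(ss_tot - b^2 * sxx, 0)
  s[, `:=`(mu = b,
           s0 = exp(a + b * birth_time),
           r2 = ifelse(ss_tot > 1e-12, 1 - ss_res / ss_tot, NA_real_),
           valid = n >= 3L & !is.na(b))]
  s[, c("st", "sy", "stt", "sty", "syy") := NULL]
  setcolorder(s, c(lin_keys(), "generation_id", "mu", "s0", "n_frames",
                   "r2", "valid", "birth_time", "end_time"))
  s[]
}

#' Detect generation boundaries from length drops
#'
#' Fallback when no generation ids are exported: a new generation starts at
#' any frame whose length falls below 0.6 times the previous frame's length
#' (a division halves the mother's length).
#'
#' @param length_um length series of one lineage, frames ordered.
#' @param drop_fraction boundary threshold (default 0.6).
#' @return list with `generation_id` (0-based ids per frame) and
#'   `boundaries` (frame indices, 1-based, at which a new generation starts).
#' @export
detect_generations <- function(length_um, drop_fraction = 0.6) {
  n <- length(length_um)
  if (n == 0L) return(list(generation_id = integer(), boundaries = integer()))
  is_boundary <- c(FALSE, length_um[-1] < drop_fraction * length_um[-n])
  list(generation_id = cumsum(is_boundary),
       boundaries = which(is_boundary))
}

#' Per-frame expression levels (fluorescence per area)
#'
#' SOS expression is the total reporter fluorescence divided by the cell
#' area, a concentration proxy; likewise for the constitutive reporter.
#'
#' @param obs observation table with `gfp_total`, `mkate_total`, `area_um2`.
#' @return the table with `sos_expression` and `mkate_expression` columns
#'   added (a.u.).
#' @export
expression_per_area <- function(obs) {
  obs <- as.data.table(obs)
  if (any(obs$area_um2 <= 0)) stop("cell area must be positive")
  obs[, `:=`(sos_expression = gfp_total / area_um2,
             mkate_expression = mkate_total / area_um2)]
  obs[]
}

#' Drop the initial non-steady-state hours and re-zero the clock
#'
#' Standard convention: the first `discard_h` hours of each experiment are
#' discarded so only steady-state cells are analysed, and time is re-zeroed
#' so the drug window sits at `[t_drug_on, t_drug_off]` retained hours.
#'
#' @param obs observation table on the raw clock.
#' @param discard_h hours to discard (default 4).
#' @return the retained table, `time_h` re-zeroed and `frame` re-based.
#' @export
retain_observations <- function(obs, discard_h = 4) {
  obs <- as.data.table(obs)[time_h >= discard_h - 1e-9]
  obs[, time_h := time_h - discard_h]
  obs[, frame := frame - min(frame), by = eval(lin_keys())]
  obs[]
}

#' Build per-frame lineage trajectories
#'
#' Combines the raw frames with (i) each generation's fitted elongation rate
#' broadcast over its frames, (ii) a division-corrected instantaneous rate,
#' and (iii) the expression levels. The instantaneous rate is the rolling
#' OLS slope of the *growth curve* `log(length) + log(2) * divisions so far`,
#' which is continuous across divisions (the mother keeps half its length),
#' so non-dividing filamenting cells and dividing cells are measured on the
#' same footing.
#'
#' @param obs observation table (any clock).
#' @param fits optional precomputed [fit_generations()] result.
#' @param smooth_window width of the rolling-slope window in hours
#'   (default: 3 frames).
#' @return data.table with one row per frame: keys, `time_h`, `length_um`,
#'   `generation_id`, `mu` (generation fit), `inst_rate`, `growth_curve`,
#'   `sos_expression`, `mkate_expression`.
#' @export
lineage_trajectories <- function(obs, fits = NULL, smooth_window = NULL) {
  obs <- expression_per_area(as.data.table(obs))
  if (is.null(fits)) fits <- fit_generations(obs)
  traj <- merge(obs,
                fits[, c(lin_keys(), "generation_id", "mu"), with = FALSE],
                by = c(lin_keys(), "generation_id"), all.x = TRUE, sort = FALSE)
  setorderv(traj, c(lin_keys(), "frame"))
  dt_h <- infer_dt(traj$time_h)
  k <- if (is.null(smooth_window)) 3L
       else max(3L, as.integer(round(smooth_window / dt_h)))
  traj[, gen_index := generation_id - generation_id[1], by = eval(lin_keys())]
  traj[, growth_curve := log(length_um) + log(2) * gen_index, by = eval(lin_keys())]
  traj[, inst_rate := rolling_slope(growth_curve, dt_h, k), by = eval(lin_keys())]
  traj[]
}

infer_dt <- function(time_h) {
  d <- diff(sort(unique(round(time_h, 9))))
  d <- d[d > 1e-9]
  if (!length(d)) stop("cannot infer the frame interval from a single time")
  min(d)
}

#' Windowed population distributions
#'
#' Discards the first `discard_first_h` hours, re-zeroes time, and pools the
#' requested per-frame value over consecutive windows of `window_h` hours,
#' reporting the median and the number of pooled points per window. A final
#' window not fully covered by the observation span is flagged `partial`;
#' empty windows carry `count = 0` and an `NA` median.
#'
#' @param traj a trajectory table (or any table with `time_h`).
#' @param value name of the column to pool (e.g. `"inst_rate"`, `"mu"`,
#'   `"sos_expression"`).
#' @param window_h window width, hours (default 2).
#' @param discard_first_h initial hours to discard before windowing
#'   (default 4; use 0 if the input is already on the retained clock).
#' @return data.table: `window_t0`, `window_t1`, `median`, `count`,
#'   `partial`.
#' @export
window_distributions <- function(traj, value = "inst_rate", window_h = 2,
                                 discard_first_h = 4) {
  stopifnot(value %in% names(traj))
  dt <- as.data.table(traj)[time_h >= discard_first_h - 1e-9,
                            .(time_h = time_h - discard_first_h,
                              value = get(value))]
  if (nrow(dt) == 0L) stop("no observations remain after the discard")
  span <- max(dt$time_h)
  n_win <- ceiling((span + 1e-9) / window_h)
  if (n_win < 1L) n_win <- 1L
  out <- data.table(window_t0 = (seq_len(n_win) - 1) * window_h)
  out[, window_t1 := window_t0 + window_h]
  pooled <- dt[, .(median = median(value, na.rm = TRUE), count = .N),
               by = .(window_t0 = floor((time_h + 1e-9) / window_h) * window_h)]
  out <- merge(out, pooled, by = "window_t0", all.x = TRUE)
  out[is.na(count), count := 0L]
  out[count == 0L, median := NA_real_]
  out[, partial := window_t1 > span + 1e-9]
  out[]
}

#' Median of a per-frame value over a time window
#'
#' Convenience for pooled medians such as the population SOS expression over
#' the final two hours of drug exposure.
#'
#' @param traj trajectory table on the retained clock.
#' @param value column to pool.
#' @param t0,t1 window `[t0, t1)`, retained hours.
#' @return the pooled median (scalar).
#' @export
window_median <- function(traj, value, t0, t1) {
  v <- as.data.table(traj)[time_h >= t0 - 1e-9 & time_h < t1 - 1e-9,
                           get(value)]
  median(v, na.rm = TRUE)
}
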