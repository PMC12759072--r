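## Simulation configuration: construction, validation, calibrated defaults.

#' Known treatment arms
#' @export
mm_conditions <- function() c("no-drug", "TET", "CIP", "CIP-TET")

condition_has_cip <- function(condition) condition %in% c("CIP", "CIP-TET")
condition_has_tet <- function(condition) condition %in% c("TET", "CIP-TET")

#' Build and validate a mother-machine simulation configuration
#'
#' A `sim_config` collects everything the lineage generator needs: the imaging
#' cadence, the drug on/off window (in retained time, i.e. after the initial
#' steady-state hours have been discarded), the drug-free elongation-rate
#' distribution, the per-condition fate probabilities, the SOS/constitutive
#' reporter levels and their post-death dynamics, and the censoring model.
#'
#' Times are in hours of *retained* time: hour 0 is the first analysed frame,
#' the drugs are switched on at `t_drug_on` and off at `t_drug_off`, and the
#' experiment ends at `t_end`. The generator additionally simulates
#' `discard_h` hours of drug-free burn-in before hour 0 so that the standard
#' discard-the-first-hours convention of downstream analysis can be exercised;
#' exported tables carry the raw clock.
#'
#' @param medium_name growth-medium label (e.g. `"glu-aa"`).
#' @param frame_interval imaging interval, minutes.
#' @param t_start,t_drug_on,t_drug_off,t_end experiment timeline, hours of
#'   retained time.
#' @param n_lineages mother-cell lineages per replicate.
#' @param n_replicates independent replicates per condition.
#' @param mu_median drug-free median elongation rate, 1/h.
#' @param mu_cv cell-to-cell coefficient of variation of the elongation rate.
#' @param tet_reduction steady-state fractional reduction of elongation under
#'   TET alone; `tet_reduction_combo` the analogous value under CIP-TET
#'   (defaults to `tet_reduction`).
#' @param tet_relax_time time constant, hours, with which the TET effect is
#'   approached (and relaxes after washout).
#' @param fate_probs named list mapping each condition to
#'   `c(survive, die_low, die_high)` probabilities summing to 1.
#' @param late_death_prob probability of an age-related death in the final 4 h
#'   for conditions without CIP.
#' @param sos_baseline,sos_induced median SOS expression (a.u., fluorescence
#'   per area) without drug and at the CIP-exposed steady state of surviving /
#'   low-SOS cells.
#' @param high_sos_multiplier fold-increase of the high-SOS post-arrest peak
#'   over the induced level.
#' @param expr_relax_time,sos_recovery_time time constants (h) for SOS
#'   induction under CIP and for its return to baseline after drug removal.
#' @param spike_rise_time hours of continued SOS production after growth
#'   arrest in high-SOS cells (volume frozen, concentration ramps to the peak).
#' @param gfp_maturation_time reporter maturation delay, minutes.
#' @param bleach_rate post-death fluorophore decay rate, 1/h.
#' @param mkate_baseline constitutive reporter level, a.u.
#' @param sos_cv cell-to-cell coefficient of variation of reporter levels.
#' @param birth_length birth length, micrometres.
#' @param division_noise_cv multiplicative noise on the sizer division
#'   threshold.
#' @param cell_width cell width used to convert length to area, micrometres.
#' @param max_channel_length microchannel length, micrometres; lineages whose
#'   cell exceeds it are truncated (hyper-filamentation censoring).
#' @param filament_prob_survivor probability that a surviving CIP-exposed cell
#'   transiently filaments.
#' @param filament_before_death hours of terminal filamentation of high-SOS
#'   dying cells.
#' @param loss_rate random lineage washout hazard, 1/h.
#' @param replicate_jitter SD of the absolute between-replicate jitter applied
#'   to the survival probability.
#' @param measurement_noise_cv multiplicative lognormal measurement noise on
#'   length, area and fluorescence totals.
#' @param discard_h burn-in hours simulated before retained hour 0.
#' @param seed default master seed.
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [default_parameter_sets()] for calibrated per-medium sets.
#' @export
sim_config <- function(medium_name,
                       frame_interval = 5,
                       t_start = 0, t_drug_on = 2, t_drug_off = 14, t_end = 24,
                       n_lineages = 500L,
                       n_replicates = 3L,
                       mu_median,
                       mu_cv = 0.15,
                       tet_reduction,
                       tet_reduction_combo = NULL,
                       tet_relax_time = 2,
                       fate_probs,
                       late_death_prob = 0.03,
                       sos_baseline,
                       sos_induced,
                       high_sos_multiplier = 10,
                       expr_relax_time = 1.5,
                       sos_recovery_time = 1.5,
                       spike_rise_time = 1,
                       gfp_maturation_time = 20,
                       bleach_rate = 0.5,
                       mkate_baseline = 500,
                       sos_cv = 0.1,
                       birth_length = 2,
                       division_noise_cv = 0.1,
                       cell_width = 1,
                       max_channel_length = 40,
                       filament_prob_survivor = 0.15,
                       filament_before_death = 1.5,
                       loss_rate = 0.005,
                       replicate_jitter = 0.02,
                       measurement_noise_cv = 0.03,
                       discard_h = 4,
                       seed = 1L) {
  cfg <- mget(names(formals()))
  cfg$tet_reduction_combo <- tet_reduction_combo %||% tet_reduction
  cfg$n_lineages <- as.integer(n_lineages)
  cfg$n_replicates <- as.integer(n_replicates)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    if (!(t_start < t_drug_on && t_drug_on < t_drug_off && t_drug_off < t_end))
      stop("timeline must satisfy t_start < t_drug_on < t_drug_off < t_end")
    dt_h <- frame_interval / 60
    spans <- c(t_drug_on - t_start, t_drug_off - t_drug_on, t_end - t_drug_off,
               discard_h)
    if (any(abs(spans / dt_h - round(spans / dt_h)) > 1e-9))
      stop("frame_interval must divide the timeline window lengths")
    pos <- c(frame_interval = frame_interval, mu_median = mu_median,
             tet_relax_time = tet_relax_time, sos_baseline = sos_baseline,
             sos_induced = sos_induced, high_sos_multiplier = high_sos_multiplier,
             bleach_rate = bleach_rate, birth_length = birth_length,
             max_channel_length = max_channel_length, cell_width = cell_width)
    if (any(pos <= 0))
      stop("non-positive rate/time/level: ",
           paste(names(pos)[pos <= 0], collapse = ", "))
    if (any(c(mu_cv, sos_cv, division_noise_cv, measurement_noise_cv,
              loss_rate, replicate_jitter, tet_reduction,
              tet_reduction_combo, late_death_prob) < 0))
      stop("noise levels, reductions and hazards must be non-negative")
    for (cond in names(fate_probs)) {
      p <- fate_probs[[cond]]
      if (length(p) != 3L || any(p < 0) || any(p > 1) ||
          abs(sum(p) - 1) > 1e-9)
        stop("fate_probs for '", cond,
             "' must be 3 probabilities in [0,1] summing to 1")
    }
  })
  invisible(config)
}

#' Calibrated per-medium default parameter sets
#'
#' Returns one [sim_config()] per growth medium (`"glu-aa"`, `"glu"`,
#' `"gly"`), calibrated so that the simulated populations reproduce the
#' summary statistics of the mother-machine study these tools target:
#' drug-free median elongation rates of 1.13, 0.54 and 0.28 1/h; end-of-
#' experiment CIP survival of 36/38/43% with high-SOS dead fractions of
#' 12/25/30%; CIP-TET survival of 76/66/61% with high-SOS fractions 8/20/22%;
#' no-drug median SOS expression 118/95/93 a.u. and CIP-induced steady levels
#' 227/473/462 a.u.; a ~16% TET elongation reduction in glu-aa (14% under the
#' combination). TET reductions for glu and gly are not reported and default
#' to 0.10 and 0.05 (growth-rate-dependent, largest in the fastest medium).
#'
#' @return named list of `sim_config` objects keyed by medium.
#' @export
default_parameter_sets <- function() {
  fp <- function(cip, ciptet) {
    list(`no-drug` = c(survive = 1, die_low = 0, die_high = 0),
         `TET` = c(survive = 1, die_low = 0, die_high = 0),
         `CIP` = cip,
         `CIP-TET` = ciptet)
  }
  list(
    "glu-aa" = sim_config(
      medium_name = "glu-aa", frame_interval = 5,
      mu_median = 1.13, tet_reduction = 0.16, tet_reduction_combo = 0.14,
      sos_baseline = 118, sos_induced = 227,
      fate_probs = fp(c(survive = 0.36, die_low = 0.52, die_high = 0.12),
                      c(survive = 0.77, die_low = 0.15, die_high = 0.08))),
    "glu" = sim_config(
      medium_name = "glu", frame_interval = 5,
      mu_median = 0.54, tet_reduction = 0.10,
      sos_baseline = 95, sos_induced = 473,
      fate_probs = fp(c(survive = 0.38, die_low = 0.37, die_high = 0.25),
                      c(survive = 0.66, die_low = 0.14, die_high = 0.20))),
    "gly" = sim_config(
      medium_name = "gly", frame_interval = 10,
      mu_median = 0.28, tet_reduction = 0.05,
      sos_baseline = 93, sos_induced = 462,
      fate_probs = fp(c(survive = 0.43, die_low = 0.27, die_high = 0.30),
                      c(survive = 0.61, die_low = 0.17, die_high = 0.22)))
  )
}

#' Timeline of an experiment in retained time
#'
#' @param config a [sim_config()].
#' @return list with `t_on`, `t_off`, `t_end`, `dt` (hours) and `discard_h`.
#' @export
make_timeline <- function(config) {
  list(t_on = config$t_drug_on, t_off = config$t_drug_off,
       t_end = config$t_end, dt = config$frame_interval / 60,
       discard_h = config$discard_h)
}
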