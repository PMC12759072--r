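## Ingestion of measurement tables and the end-to-end driver chaining
## simulate -> fit -> classify -> survival -> interaction into a flat-CSV
## report bundle, so that any stage can be re-run in isolation.

#' Read and validate an observation table
#'
#' Accepts the documented CSV schema (extra columns tolerated, missing ones
#' fatal) and validates structural invariants: strictly increasing frames
#' within each lineage, positive lengths and areas. Validation failures are
#' reported with row numbers.
#'
#' @param path CSV path (a leading `#` stamp line is tolerated).
#' @return a validated data.table sorted by replicate, lineage, frame.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obs <- read_stamped_csv(path)
  if (nrow(obs) == 0L) stop("empty observation file: ", path)
  missing <- setdiff(obs_schema(), names(obs))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  validate_observations(obs)
  setorderv(obs, c("condition", "replicate_id", "lineage_id", "frame"))
  obs[]
}

#' @rdname read_observations
#' @param obs an in-memory observation table.
#' @export
validate_observations <- function(obs) {
  obs <- as.data.table(obs)
  bad_len <- which(obs$length_um <= 0)
  bad_area <- which(obs$area_um2 <= 0)
  problems <- c(
    if (length(bad_len))
      paste0("non-positive length_um at row(s) ",
             paste(head(bad_len, 5), collapse = ", ")),
    if (length(bad_area))
      paste0("non-positive area_um2 at row(s) ",
             paste(head(bad_area, 5), collapse = ", ")))
  mono <- obs[, .(ok = !is.unsorted(frame, strictly = TRUE)), by = eval(lin_keys())]
  if (any(!mono$ok)) {
    k <- mono[!(ok)][1]
    problems <- c(problems,
                  paste0("non-monotone frames within lineage ",
                         k$condition, "/", k$replicate_id, "/", k$lineage_id))
  }
  if (length(problems))
    stop("invalid observation table:\n  ", paste(problems, collapse = "\n  "))
  invisible(obs)
}

#' Analyse one condition from raw observations to fates and events
#'
#' The single-condition core of the pipeline: discard the burn-in, fit
#' generations, build trajectories, apply QC, classify fates and SOS
#' classes, and construct event records.
#'
#' @param obs raw-clock observation table for one condition.
#' @param timeline a [make_timeline()] list.
#' @param params a [classifier_params()].
#' @param mu_ref drug-free reference rate; pass the no-drug estimate when
#'   analysing drug arms, otherwise it is taken from the pre-drug window.
#' @return list: `trajectories`, `fits`, `qc_exclusions`, `fates`,
#'   `sos_threshold`, `events`, `sf`, `decomposition`.
#' @export
analyse_condition <- function(obs, timeline, params = classifier_params(),
                              mu_ref = NULL) {
  ret <- retain_observations(obs, timeline$discard_h)
  fits <- fit_generations(ret)
  traj <- lineage_trajectories(ret, fits)
  qc <- apply_qc_filters(traj, params, timeline)
  fates <- classify_fates(qc$kept, params, timeline, mu_ref = mu_ref)
  thr <- tryCatch(sos_threshold(qc$kept, fates, params, timeline),
                  warning = function(w) {
                    params$sos_threshold_fallback
                  })
  fates <- classify_sos(qc$kept, fates, thr, timeline)
  list(trajectories = qc$kept, fits = fits, qc_exclusions = qc$exclusions,
       fates = fates, sos_threshold = thr,
       events = event_records(fates, timeline),
       sf = survival_fraction(fates),
       decomposition = fate_decomposition(fates))
}

#' Run the full analysis pipeline for one medium
#'
#' Simulates (or ingests) the four treatment arms, runs QC, per-generation
#' fitting, fate and SOS classification, Kaplan-Meier estimation (whole
#' population and SOS strata), replicate survival fractions, and the
#' drug-interaction statistics, writing every intermediate artifact as a
#' stamped CSV into `out_dir`.
#'
#' @param config a [sim_config()] for the medium.
#' @param conditions treatment arms to run (default all four).
#' @param seed master seed.
#' @param out_dir output directory (created); `NULL` skips writing.
#' @param params a [classifier_params()] (its channel-length bound is taken
#'   from the config).
#' @param observations optional named list of pre-loaded raw observation
#'   tables per condition (bypasses simulation).
#' @return (invisibly) list with per-condition analyses, the replicate `Sf`
#'   table, survival curves, the fate decomposition and the
#'   [interaction_report()].
#' @export
run_pipeline <- function(config, conditions = mm_conditions(), seed = 1L,
                         out_dir = NULL, params = NULL,
                         observations = NULL) {
  timeline <- make_timeline(config)
  params <- params %||%
    classifier_params(max_channel_length = config$max_channel_length)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  per_cond <- list()
  truth <- list()
  ## drug-free reference rate from the no-drug arm when available
  mu_ref <- NULL
  ord <- unique(c(intersect("no-drug", conditions), conditions))
  for (cond in ord) {
    if (!is.null(observations)) {
      obs <- observations[[cond]]
      if (is.null(obs) || nrow(obs) == 0L)
        stop("pipeline aborted at ingestion: no observations for '", cond, "'")
    } else {
      sim <- simulate_condition(config, cond,
                                seed = derive_seed(seed, 7L,
                                                   match(cond, mm_conditions())))
      obs <- sim$observations
      truth[[cond]] <- sim$truth
    }
    res <- tryCatch(
      analyse_condition(obs, timeline, params, mu_ref = mu_ref),
      error = function(e)
        stop("pipeline stage 'analyse' failed for condition '", cond,
             "': ", conditionMessage(e)))
    if (cond == "no-drug")
      mu_ref <- reference_mu(res$fits, timeline)
    per_cond[[cond]] <- res
    message(sprintf("[mmsurv] %-8s %s: %d lineages, %d QC-excluded, Sf=%.3f",
                    config$medium_name, cond,
                    nrow(res$fates) + nrow(res$qc_exclusions),
                    nrow(res$qc_exclusions), res$sf$mean))
  }
  sf_table <- rbindlist(lapply(per_cond, function(r) r$sf$replicates))
  decomposition <- rbindlist(lapply(per_cond, function(r) r$decomposition))
  curves <- lapply(per_cond, function(r) kaplan_meier(r$events))
  interaction <- NULL
  if (all(c("CIP", "TET", "CIP-TET") %in% names(per_cond))) {
    sfs <- lapply(per_cond, function(r) r$sf$replicates$sf)
    interaction <- interaction_report(sfs, medium = config$medium_name)
  }
  if (!is.null(out_dir)) {
    w <- function(x, name) write_stamped_csv(x, file.path(out_dir, name),
                                             config = config, seed = seed)
    for (cond in names(per_cond)) {
      tag <- gsub("[^A-Za-z0-9]+", "_", cond)
      w(per_cond[[cond]]$fits, paste0("generation_fits_", tag, ".csv"))
      w(per_cond[[cond]]$fates, paste0("fates_", tag, ".csv"))
      w(curves[[cond]], paste0("survival_curve_", tag, ".csv"))
      writeLines(c(stamp_lines(config, seed),
                   sprintf("%s/%d/%d: %s",
                           per_cond[[cond]]$qc_exclusions$condition,
                           per_cond[[cond]]$qc_exclusions$replicate_id,
                           per_cond[[cond]]$qc_exclusions$lineage_id,
                           per_cond[[cond]]$qc_exclusions$qc_reason)),
                 file.path(out_dir, paste0("qc_exclusions_", tag, ".txt")))
    }
    w(sf_table, "survival_fractions.csv")
    w(decomposition, "fate_decomposition.csv")
    if (!is.null(interaction)) {
      itab <- data.table(
        medium = interaction$medium,
        bliss_mean = interaction$bliss_mean,
        bliss_sem = interaction$bliss_sem,
        sigma = interaction$sigma,
        p_bliss_one_sided = interaction$p_bliss_one_sided,
        p_ttest_cip_vs_ciptet = interaction$p_ttest_cip_vs_ciptet,
        exceeds_bliss = interaction$exceeds_bliss)
      w(itab, "interaction_report.csv")
    }
  }
  invisible(list(conditions = per_cond, truth = truth, sf_table = sf_table,
                 curves = curves, decomposition = decomposition,
                 interaction = interaction, mu_ref = mu_ref,
                 timeline = timeline))
}
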