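## Shared fixtures: configurations, memoised simulations/analyses (several
## test files interrogate the same simulated populations), and hand-built
## synthetic lineages for classifier edge cases.

library(data.table)

.mm_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.mm_cache[[key]])) assign(key, force(expr), envir = .mm_cache)
  get(key, envir = .mm_cache)
}

medium_config <- function(medium, n = 300L, reps = 1L, ...) {
  cfg <- default_parameter_sets()[[medium]]
  cfg$n_lineages <- as.integer(n)
  cfg$n_replicates <- as.integer(reps)
  extra <- list(...)
  for (nm in names(extra)) cfg[[nm]] <- extra[[nm]]
  cfg
}

sim_cached <- function(medium, condition, n = 300L, reps = 1L, seed = 101L,
                       ...) {
  key <- paste("sim", medium, condition, n, reps, seed, ...)
  cached(key, simulate_condition(medium_config(medium, n, reps, ...),
                                 condition, seed = seed))
}

analysis_cached <- function(medium, condition, n = 300L, reps = 1L,
                            seed = 101L, ...) {
  key <- paste("ana", medium, condition, n, reps, seed, ...)
  cached(key, {
    cfg <- medium_config(medium, n, reps, ...)
    sim <- sim_cached(medium, condition, n, reps, seed, ...)
    analyse_condition(sim$observations, make_timeline(cfg))
  })
}

## truth labels mapped onto classifier vocabulary
truth_label <- function(true_fate) {
  fifelse(true_fate == "survive", "survived",
          fifelse(true_fate == "lost", "censored", "died"))
}

compare_to_truth <- function(analysis, sim) {
  cmp <- merge(analysis$fates, sim$truth,
               by = c("condition", "replicate_id", "lineage_id"))
  cmp[, truth_lab := truth_label(true_fate)]
  cmp
}

## hand-built single-lineage observation table (no divisions unless lengths
## encode them); areas equal lengths, flat reporter totals
synthetic_lineage <- function(time_h, length_um, lineage_id = 1L,
                              condition = "CIP", gfp_per_area = 100,
                              mkate_per_area = 500,
                              generation_id = NULL) {
  if (is.null(generation_id))
    generation_id <- detect_generations(length_um)$generation_id
  data.table(condition = condition, replicate_id = 1L,
             lineage_id = as.integer(lineage_id),
             generation_id = as.integer(generation_id),
             frame = seq_along(time_h) - 1L, time_h = time_h,
             length_um = length_um, area_um2 = length_um,
             gfp_total = gfp_per_area * length_um,
             mkate_total = mkate_per_area * length_um)
}

test_timeline <- function(dt = 1 / 12) {
  list(t_on = 2, t_off = 14, t_end = 24, dt = dt, discard_h = 4)
}
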