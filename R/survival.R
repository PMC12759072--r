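## Kaplan-Meier estimation with right-censoring, log-rank comparisons and
## replicate-level end-of-experiment survival fractions. The product-limit
## and log-rank machinery is delegated to the survival package; this module
## defines the event construction and the summaries used downstream.

#' Build event records from classified fates
#'
#' Durations are measured from drug onset (`t_on`) so the survival function
#' reflects post-exposure survival: deaths at `death_time - t_on` with
#' `event = 1`; censored lineages at `censor_time - t_on` with `event = 0`;
#' survivors censored at `t_end - t_on`.
#'
#' @param fates a [classify_fates()] / [classify_sos()] table.
#' @param timeline a [make_timeline()] list.
#' @param from time origin (default `timeline$t_on`; use `0` to keep the
#'   full retained timeline).
#' @return data.table: lineage keys, `duration`, `event`, `group`
#'   (condition).
#' @export
event_records <- function(fates, timeline, from = timeline$t_on) {
  f <- as.data.table(fates)
  out <- f[, .(condition, replicate_id, lineage_id,
               duration = pmax(fifelse(fate == "died", death_time,
                                       fifelse(fate == "censored",
                                               censor_time, timeline$t_end)) -
                                 from, 0),
               event = as.integer(fate == "died"),
               group = condition)]
  out[]
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate `S(t) = prod(1 - d_i / n_i)` over event times,
#' with Greenwood variance and complementary log-log 95% confidence
#' intervals. Datasets with no deaths give `S == 1` throughout.
#'
#' @param events an [event_records()] table (single group).
#' @return data.table: `time`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   `lower`, `upper`.
#' @export
kaplan_meier <- function(events) {
  ev <- as.data.table(events)
  if (nrow(ev) == 0L) stop("at least one event record is required")
  if (any(ev$duration < 0)) stop("durations must be non-negative")
  fit <- survival::survfit(survival::Surv(duration, event) ~ 1, data = ev,
                           conf.type = "log-log")
  s <- summary(fit, censored = TRUE)
  data.table(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
             n_censor = s$n.censor, surv = s$surv,
             lower = fifelse(is.na(s$lower) & s$surv == 1, 1, s$lower),
             upper = fifelse(is.na(s$upper) & s$surv == 1, 1, s$upper))
}

#' Two-sample log-rank test
#'
#' Standard observed-minus-expected chi-square with one degree of freedom;
#' two-sided p from the upper chi-square tail. If neither group has any
#' death the statistic is 0 and p is 1.
#'
#' @param events_a,events_b [event_records()] tables for the two groups.
#' @return list: `statistic`, `p_value`.
#' @export
log_rank <- function(events_a, events_b) {
  a <- as.data.table(events_a)
  b <- as.data.table(events_b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both groups must be non-empty")
  dat <- rbind(a[, .(duration, event, g = 0L)],
               b[, .(duration, event, g = 1L)])
  if (sum(dat$event) == 0L) return(list(statistic = 0, p_value = 1))
  sd <- survival::survdiff(survival::Surv(duration, event) ~ g, data = dat)
  list(statistic = unname(sd$chisq),
       p_value = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' End-of-experiment survival fractions per replicate
#'
#' `sf = survivors / (survivors + deaths)` among lineages observed to the
#' end of the experiment; lineages censored before the end (washout,
#' hyper-filamentation) are excluded from the denominator by default, or
#' counted as survivors with `censored = "as_survived"`.
#'
#' @param fates classified fates of one condition.
#' @param censored `"exclude"` (default) or `"as_survived"`.
#' @return list: `replicates` (data.table `condition`, `replicate_id`, `sf`,
#'   `n_lineages`), `mean`, `sem`, `n_replicates`.
#' @export
survival_fraction <- function(fates, censored = c("exclude", "as_survived")) {
  censored <- match.arg(censored)
  f <- as.data.table(fates)
  if (nrow(f) == 0L) stop("empty fate table")
  reps <- f[, {
    n_s <- sum(fate == "survived")
    n_d <- sum(fate == "died")
    n_c <- sum(fate == "censored")
    if (censored == "as_survived") n_s <- n_s + n_c
    denom <- n_s + n_d
    if (denom == 0L) stop("replicate with no classifiable lineages")
    .(sf = n_s / denom, n_lineages = denom)
  }, by = .(condition, replicate_id)]
  list(replicates = reps[],
       mean = mean(reps$sf),
       sem = if (nrow(reps) > 1) sd(reps$sf) / sqrt(nrow(reps)) else NA_real_,
       n_replicates = nrow(reps))
}

#' SOS-stratified survival fraction
#'
#' The contribution of one dead class to population survival:
#' `1 - (dead in class) / (survivors + all deaths)` per replicate, i.e. the
#' fraction of the classified population that did *not* die through that
#' route. Computed per replicate with mean and SEM, mirroring the
#' decomposition of survival into low- and high-SOS death channels.
#'
#' @param fates a [classify_sos()] table for one condition.
#' @param class `"low"` or `"high"`.
#' @return as [survival_fraction()].
#' @export
stratum_survival_fraction <- function(fates, class = c("low", "high")) {
  class <- match.arg(class)
  f <- as.data.table(fates)
  reps <- f[, {
    denom <- sum(fate %in% c("survived", "died"))
    if (denom == 0L) stop("replicate with no classifiable lineages")
    .(sf = 1 - sum(fate == "died" & sos_class == class) / denom,
      n_lineages = denom)
  }, by = .(condition, replicate_id)]
  list(replicates = reps[],
       mean = mean(reps$sf),
       sem = if (nrow(reps) > 1) sd(reps$sf) / sqrt(nrow(reps)) else NA_real_,
       n_replicates = nrow(reps))
}
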