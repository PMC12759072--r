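## Drug-interaction statistics: Bliss-independence expected survival and its
## SEM, the one-sided ANOVA contrast test of the Bliss null, pairwise t-tests
## and the suppression statistic Sigma.

#' Bliss-independence expected survival from replicate survival fractions
#'
#' Under Bliss independence the survival fraction of the combination equals
#' the product of the single-drug survival fractions,
#' `Bliss_ij = exp(log(Sf_CIP_i) + log(Sf_TET_j))`. All replicate pairs
#' (full Cartesian product by default, or matched by index) are enumerated;
#' the reported SEM follows the conventional printed propagation
#' `sqrt(sd_CIP / sqrt(n_CIP) + sd_TET / sqrt(n_TET))` (`sem_method =
#' "as_printed"`); `"delta"` gives the standard log-scale variance
#' propagation instead.
#'
#' @param sf_cip,sf_tet replicate survival fractions (each in `(0, 1]`).
#' @param pairing `"cross"` (default) or `"matched"`.
#' @param sem_method `"as_printed"` (default) or `"delta"`.
#' @return list: `values` (pairwise Bliss expectations), `mean`, `sem`.
#' @export
bliss_expected <- function(sf_cip, sf_tet,
                           pairing = c("cross", "matched"),
                           sem_method = c("as_printed", "delta")) {
  pairing <- match.arg(pairing)
  sem_method <- match.arg(sem_method)
  if (any(sf_cip <= 0) || any(sf_tet <= 0))
    stop("survival fractions must be positive (log-transform undefined at 0)")
  if (any(sf_cip > 1) || any(sf_tet > 1))
    stop("survival fractions cannot exceed 1")
  values <- if (pairing == "cross") {
    as.vector(outer(sf_cip, sf_tet, function(a, b) exp(log(a) + log(b))))
  } else {
    if (length(sf_cip) != length(sf_tet))
      stop("matched pairing requires equal replicate counts")
    exp(log(sf_cip) + log(sf_tet))
  }
  n_c <- length(sf_cip); n_t <- length(sf_tet)
  sem <- if (n_c > 1 && n_t > 1) {
    if (sem_method == "as_printed") {
      sqrt(sd(sf_cip) / sqrt(n_c) + sd(sf_tet) / sqrt(n_t))
    } else {
      mean(values) * sqrt(var(log(sf_cip)) / n_c + var(log(sf_tet)) / n_t)
    }
  } else NA_real_
  list(values = values, mean = mean(values), sem = sem)
}

#' One-sided ANOVA contrast test of the Bliss null
#'
#' Fixed-effects one-way layout on `y = log(Sf)` with the three arms CIP,
#' TET and CIP-TET as groups. The Bliss null is the linear contrast
#' `c = mean_CIP + mean_TET - mean_CIPTET = 0`; the alternative of interest
#' is `c < 0` (the combination survives more than independence predicts).
#' The pooled residual variance supplies the standard error; the one-sided
#' p-value is the lower t tail.
#'
#' @param sf_cip,sf_tet,sf_ciptet replicate survival fractions per arm.
#' @return list: `contrast` (on the log scale), `se`, `t`, `df`,
#'   `p_one_sided`.
#' @export
bliss_anova_test <- function(sf_cip, sf_tet, sf_ciptet) {
  if (any(c(sf_cip, sf_tet, sf_ciptet) <= 0))
    stop("survival fractions must be positive (log-transform undefined at 0)")
  y <- log(c(sf_cip, sf_tet, sf_ciptet))
  g <- factor(rep(c("CIP", "TET", "CIPTET"),
                  c(length(sf_cip), length(sf_tet), length(sf_ciptet))),
              levels = c("CIP", "TET", "CIPTET"))
  df <- length(y) - 3L
  if (df < 1L)
    stop("no residual degrees of freedom: at least one arm needs >= 2 replicates")
  fit <- stats::lm(y ~ 0 + g)
  means <- stats::coef(fit)
  s2 <- sum(stats::residuals(fit)^2) / df
  ns <- table(g)
  contrast <- unname(means["gCIP"] + means["gTET"] - means["gCIPTET"])
  se <- sqrt(s2 * sum(1 / ns))
  t_stat <- contrast / se
  list(contrast = contrast, se = se, t = t_stat, df = df,
       p_one_sided = pt(t_stat, df))
}

#' Suppression statistic
#'
#' Relative change of the mean survival fraction under the combination with
#' respect to the antagonised single drug:
#' `Sigma = (Sf_combo - Sf_single) / Sf_single`. Positive values mean the
#' combination rescues cells that the single drug would kill; negative
#' values would indicate synergy on death.
#'
#' @param sf_ct_mean mean survival fraction under the combination.
#' @param sf_c_mean mean survival fraction under the single drug (> 0).
#' @return scalar Sigma.
#' @export
suppression_sigma <- function(sf_ct_mean, sf_c_mean) {
  if (sf_c_mean <= 0) stop("the single-drug survival fraction must be positive")
  (sf_ct_mean - sf_c_mean) / sf_c_mean
}

#' Two-sample t-test on replicate survival fractions
#'
#' Equal-variance two-sided test by default (`welch = TRUE` for the
#' unequal-variance form). Identical degenerate groups (zero variance and
#' equal means) return p = 1.
#'
#' @param sf_a,sf_b replicate values (>= 2 each).
#' @return list: `statistic`, `p_value`.
#' @export
pairwise_ttest <- function(sf_a, sf_b, welch = FALSE) {
  if (length(sf_a) < 2L || length(sf_b) < 2L)
    stop("at least two replicates per group are required")
  if (sd(c(sf_a, sf_b)) == 0)
    return(list(statistic = 0, p_value = 1))
  tt <- t.test(sf_a, sf_b, var.equal = !welch)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Interaction report for one medium
#'
#' Assembles, from per-replicate survival fractions of the four arms, the
#' Bliss expectation with SEM, the one-sided ANOVA contrast p-value, the
#' pairwise two-sided t-tests, and the suppression statistic.
#'
#' @param sf_by_condition named list of numeric replicate `Sf` vectors with
#'   entries `"CIP"`, `"TET"`, `"CIP-TET"` (and optionally `"no-drug"`).
#' @param medium label carried into the output.
#' @return list of class `interaction_result`.
#' @export
interaction_report <- function(sf_by_condition, medium = NA_character_) {
  need <- c("CIP", "TET", "CIP-TET")
  if (!all(need %in% names(sf_by_condition)))
    stop("sf_by_condition needs entries: ", paste(need, collapse = ", "))
  cip <- sf_by_condition[["CIP"]]
  tet <- sf_by_condition[["TET"]]
  ct <- sf_by_condition[["CIP-TET"]]
  bl <- bliss_expected(cip, tet)
  an <- tryCatch(bliss_anova_test(cip, tet, ct), error = function(e) NULL)
  tt <- tryCatch(pairwise_ttest(cip, ct), error = function(e) NULL)
  structure(list(
    medium = medium,
    sf_means = vapply(sf_by_condition, mean, numeric(1)),
    bliss_values = bl$values,
    bliss_mean = bl$mean,
    bliss_sem = bl$sem,
    sigma = suppression_sigma(mean(ct), mean(cip)),
    p_bliss_one_sided = if (is.null(an)) NA_real_ else an$p_one_sided,
    bliss_contrast = if (is.null(an)) NA_real_ else an$contrast,
    p_ttest_cip_vs_ciptet = if (is.null(tt)) NA_real_ else tt$p_value,
    exceeds_bliss = mean(ct) > bl$mean
  ), class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat("Drug-interaction report", if (!is.na(x$medium)) paste0("(", x$medium, ")"),
      "\n")
  cat(sprintf("  mean Sf: %s\n",
              paste(sprintf("%s=%.3f", names(x$sf_means), x$sf_means),
                    collapse = ", ")))
  cat(sprintf("  Bliss expected Sf: %.3f (SEM %.3f)\n", x$bliss_mean,
              x$bliss_sem))
  cat(sprintf("  suppression Sigma: %.3f\n", x$sigma))
  cat(sprintf("  one-sided Bliss ANOVA p: %.3g; t-test CIP vs CIP-TET p: %.3g\n",
              x$p_bliss_one_sided, x$p_ttest_cip_vs_ciptet))
  invisible(x)
}
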