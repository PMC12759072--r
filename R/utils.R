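## Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Integer counter scheme (multiplicative-congruential mixing mod 2^31 - 1) so
#' that the stream assigned to replicate r / lineage l is a pure function of
#' `(master, indices)`: adding lineages or replicates never reshuffles the
#' random numbers given to earlier ones.
#'
#' @param master integer master seed.
#' @param ... further non-negative integer indices (condition, replicate,
#'   lineage, ...).
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, prime; products below stay exact in doubles
  x <- (abs(as.numeric(master)) + 1) %% m
  for (idx in c(...)) {
    x <- (x * 48271 + as.numeric(idx) + 11) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

## lognormal sdlog that preserves the median while giving coefficient of
## variation `cv` (exact for small cv; cv is interpreted on the linear scale)
sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

## multiplicative lognormal measurement noise, median-preserving
mult_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  exp(rnorm(n, 0, sdlog_from_cv(cv)))
}

## FNV-1a hash of a character scalar, returned as 8 hex digits; used to stamp
## output files with a config fingerprint without external dependencies
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

config_hash <- function(config) {
  fnv1a(paste(deparse(config[order(names(config))]), collapse = ""))
}

#' Rolling least-squares slope of an equally spaced series
#'
#' Centred ordinary-least-squares slope of `y` against time over a sliding
#' window of `k` points spaced `dt` apart. Edge positions (where the window
#' would overhang) are filled with the nearest interior estimate so the result
#' has the length of `y`.
#'
#' @param y numeric series.
#' @param dt spacing of consecutive points (hours).
#' @param k odd window size in points (`k >= 3`).
#' @return numeric vector of slopes, in units of `y` per hour.
#' @export
rolling_slope <- function(y, dt, k = 3L) {
  n <- length(y)
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  if (k < 3L) k <- 3L
  if (n < k) { # too short: single global slope
    if (n < 2L) return(rep(NA_real_, n))
    tt <- seq_len(n) * dt
    b <- sum((tt - mean(tt)) * (y - mean(y))) / sum((tt - mean(tt))^2)
    return(rep(b, n))
  }
  j <- seq_len(k) - (k + 1) / 2          # centred index offsets
  w <- j / (sum(j^2) * dt)               # OLS slope weights
  s <- stats::filter(y, rev(w), sides = 2)
  s <- as.numeric(s)
  half <- (k - 1L) %/% 2L
  s[seq_len(half)] <- s[half + 1L]
  s[(n - half + 1L):n] <- s[n - half]
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stamp_lines <- function(config = NULL, seed = NULL) {
  paste0("# mmsurv",
         if (!is.null(seed)) paste0(" seed=", seed),
         if (!is.null(config)) paste0(" config=", config_hash(config)))
}

#' Write a CSV with an mmsurv provenance stamp
#'
#' Writes `x` as plain CSV preceded by a single `#` comment line recording the
#' seed and configuration fingerprint. [read_stamped_csv()] is the inverse.
#'
#' @param x a data.frame / data.table.
#' @param path output file.
#' @param config,seed optional provenance to record.
#' @return `path`, invisibly.
#' @export
write_stamped_csv <- function(x, path, config = NULL, seed = NULL) {
  con <- file(path, "w")
  writeLines(stamp_lines(config, seed), con)
  close(con)
  data.table::fwrite(x, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_stamped_csv
#' @export
read_stamped_csv <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && startsWith(first, "#")) 1L else 0L
  data.table::fread(path, skip = skip)
}
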