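#' Exact two-sided Poisson test with exposure offset
#'
#' Tests whether an observed event count `x` differs from the count
#' expected under a homogeneous per-position rate `r` acting over an
#' exposure of `T` callable positions, i.e. against `Poisson(mu = r * T)`.
#' The two-sided p-value follows the minimum-likelihood construction: the
#' sum of `Poisson(mu)` probabilities over all outcomes whose probability
#' does not exceed that of `x` (within relative tolerance `1e-7`), the
#' construction used by [stats::poisson.test()].
#'
#' @param x Observed event count (non-negative integer).
#' @param T Exposure in callable positions (> 0). Total panel callable
#'   length summed over individuals in the burden analysis.
#' @param r Null event rate per position (>= 0).
#' @return Two-sided p-value in `(0, 1]` (0 only in the degenerate case
#'   `r * T == 0` with `x > 0`, where the observation is impossible under
#'   the null).
#' @examples
#' poisson_two_sided(20, T = 1, r = 5) # far above the mode
#' @export
poisson_two_sided <- function(x, T = 1, r) {
  if (length(x) != 1 || is.na(x) || x < 0 || x %% 1 != 0) {
    abort("x must be a single non-negative integer")
  }
  if (T <= 0) abort("exposure T must be > 0")
  if (r < 0) abort("rate r must be >= 0")
  mu <- r * T
  if (mu == 0) return(if (x == 0) 1 else 0)
  ## minimum-likelihood construction with exact tail sums: qualifying
  ## outcomes are those with pmf <= pmf(x) within relative tolerance 1e-7;
  ## the boundary on the far side of the mode is located by scanning from
  ## the reflection of x, then both tails are accumulated with ppois
  rel_err <- 1 + 1e-7
  d <- dpois(x, mu)
  p <- if (x == mu) {
    1
  } else if (x < mu) {
    ## count qualifying outcomes in the upper tail, then sum both tails
    N <- max(ceiling(2 * mu - x), 1)
    while (dpois(N, mu) > d) N <- 2 * N
    i <- seq.int(from = ceiling(mu), to = N)
    y <- sum(dpois(i, mu) <= d * rel_err)
    ppois(x, mu) + ppois(N - y, mu, lower.tail = FALSE)
  } else {
    i <- seq.int(from = 0, to = floor(mu))
    y <- sum(dpois(i, mu) <= d * rel_err)
    ppois(y - 1, mu) + ppois(x - 1, mu, lower.tail = FALSE)
  }
  min(1, p)
}

#' Central expectation interval of a Poisson count
#'
#' The integer interval `[lo, hi]` of random expectation for a
#' `Poisson(r * T)` count: `lo` is the largest integer with
#' `P(X <= lo - 1) <= (1 - level)/2` and `hi` the smallest integer with
#' `P(X <= hi) >= 1 - (1 - level)/2`, so the interval always holds at
#' least `level` probability mass. This is the "box" of random expectation
#' drawn around the expected panel count.
#'
#' @param T Exposure (> 0).
#' @param r Rate per position (>= 0).
#' @param level Coverage level, default 0.95.
#' @return Named numeric vector `c(lo, hi)` (integers).
#' @export
expectation_interval <- function(T, r, level = 0.95) {
  stopifnot(T > 0, r >= 0, level > 0, level < 1)
  mu <- r * T
  alpha <- (1 - level) / 2
  if (mu == 0) return(c(lo = 0, hi = 0))
  lo <- qpois(alpha, mu)
  while (lo > 0 && ppois(lo - 1, mu) > alpha) lo <- lo - 1
  while (ppois(lo, mu) <= alpha) lo <- lo + 1
  hi <- qpois(1 - alpha, mu)
  while (ppois(hi, mu) < 1 - alpha) hi <- hi + 1
  while (hi > 0 && ppois(hi - 1, mu) >= 1 - alpha) hi <- hi - 1
  c(lo = as.numeric(lo), hi = as.numeric(hi))
}

#' Fisher exact comparison of mutation rates between two groups
#'
#' Builds a 2x2 table from two per-population burden summaries and applies
#' the two-sided Fisher exact test. In mode `"events_vs_exposure"` the
#' table rows are `[events, callable positions - events]` per group (a
#' rate-per-callable-position contrast); in mode `"carriers"` they are
#' `[carriers, non-carriers]` (a carrier-prevalence contrast).
#'
#' @param a,b `population_burden` tibbles (per-sample rows, single
#'   population each; see [population_burden()]), or lists with elements
#'   `events`/`exposure` (mode `events_vs_exposure`) or
#'   `carriers`/`non_carriers` (mode `carriers`).
#' @param mode Which 2x2 construction to test.
#' @return Two-sided p-value.
#' @export
fisher_rate_comparison <- function(a, b,
                                   mode = c("events_vs_exposure", "carriers")) {
  mode <- match.arg(mode)
  cells <- function(g) {
    if (is.data.frame(g)) {
      if (nrow(g) == 0) abort("empty group in fisher_rate_comparison")
      if (mode == "events_vs_exposure") {
        c(sum(g$m), sum(g$l) - sum(g$m))
      } else {
        c(sum(g$carrier), sum(!g$carrier))
      }
    } else {
      if (mode == "events_vs_exposure") {
        c(g$events, g$exposure - g$events)
      } else {
        c(g$carriers, g$non_carriers)
      }
    }
  }
  tab <- rbind(cells(a), cells(b))
  if (any(tab < 0)) abort("negative cell in 2x2 table")
  stats::fisher.test(round(tab))$p.value
}

#' Mann-Whitney comparison of per-sample mutation counts
#'
#' Two-sided rank-sum test tailored to small integer counts with heavy
#' ties: when both groups have at most `exact_max` observations the exact
#' permutation null of the midrank sum is enumerated (ties included);
#' otherwise a normal approximation with tie-corrected variance is used
#' (no continuity correction).
#'
#' @param a,b Numeric vectors of per-sample event counts.
#' @param exact_max Enumerate exactly when `max(length(a), length(b))` is
#'   at most this (default 10).
#' @return Two-sided p-value.
#' @examples
#' mannwhitney_burden(c(1, 2, 3), c(4, 5, 6)) # 0.1
#' @export
mannwhitney_burden <- function(a, b, exact_max = 10) {
  if (length(a) == 0 || length(b) == 0) abort("empty group")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  ranks <- rank(c(a, b)) # midranks
  w_obs <- sum(ranks[seq_len(n1)])
  mu_w <- n1 * (N + 1) / 2
  if (max(n1, n2) <= exact_max) {
    sets <- utils::combn(N, n1)
    w_all <- colSums(matrix(ranks[sets], nrow = n1))
    mean(abs(w_all - mu_w) >= abs(w_obs - mu_w) - 1e-9)
  } else {
    ties <- table(ranks)
    var_w <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (var_w == 0) return(1)
    z <- (w_obs - mu_w) / sqrt(var_w)
    min(1, 2 * pnorm(-abs(z)))
  }
}

#' Estimate the background truncating-mutation rate
#'
#' The pooled per-position rate `lambda = sum(M) / sum(L)`: total
#' truncating events across individuals divided by total callable
#' positions. This is a pooled ratio, not a mean of per-sample ratios,
#' so individuals with more callable territory weigh proportionally more.
#'
#' @param M Per-sample event counts, or a `population_burden` tibble
#'   (columns `M`, `L`).
#' @param L Per-sample callable lengths (ignored when `M` is a tibble).
#' @return Rate per callable position.
#' @examples
#' estimate_lambda(10, 1e6) # 1e-5
#' @export
estimate_lambda <- function(M, L = NULL) {
  if (is.data.frame(M)) {
    L <- M$L
    M <- M$M
  }
  if (any(M < 0) || any(L < 0)) abort("negative count or length")
  if (sum(L) == 0) abort("total callable length is zero")
  sum(M) / sum(L)
}
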