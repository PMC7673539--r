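# Projection, matching and the congruency score.
#
# A hypothesis (phase rho, period delta) projects the beat grid
# p_k = rho + k*delta, k in Z, clipped to the heard passage. Each projected
# beat is matched to its nearest onset; the concurrence weight
# base^(|p - r| / delta) converts match distance into a soft hit count, and
# congruency = (hits / predictions) * (hits / music events), all three terms
# counted inside the context window ending at the current time.

# integer beat-index range covering [lo - tol, hi + tol]
project_range <- function(phase, period, lo, hi, tol) {
  k_min <- ceiling((lo - tol - phase) / period)
  k_max <- floor((hi + tol - phase) / period)
  c(k_min, k_max)
}

.project <- function(phase, period, lo, hi, tol) {
  kr <- project_range(phase, period, lo, hi, tol)
  if (kr[1L] > kr[2L])
    return(list(index = integer(0), time = numeric(0)))
  k <- seq.int(kr[1L], kr[2L])
  list(index = k, time = phase + k * period)
}

#' Project a hypothesis onto a passage
#'
#' Returns every beat time \eqn{p_k = \rho + k\delta} (integer \eqn{k}, of
#' either sign) falling within `[lower - tol, upper + tol]`. The tolerance
#' keeps beats landing exactly on a passage boundary inside the projection
#' under floating-point arithmetic.
#'
#' @param hypothesis a [tht_hypothesis()] (or a `c(phase, period)` pair).
#' @param lower,upper passage bounds in ms, `lower <= upper`.
#' @param tol boundary tolerance in ms.
#' @return A data frame with columns `index` (integer `k`) and `time` (ms),
#'   strictly increasing, possibly empty.
#' @examples
#' project_beats(tht_hypothesis(1000, 400), 0, 2000)
#' @export
project_beats <- function(hypothesis, lower, upper, tol = 1e-6) {
  h <- as_hypothesis(hypothesis)
  if (!is.finite(lower) || !is.finite(upper) || lower > upper)
    stop("need finite bounds with lower <= upper", call. = FALSE)
  p <- .project(h$phase, h$period, lower, upper, tol)
  data.frame(index = p$index, time = p$time)
}

#' Concurrence weight of a beat/onset pair
#'
#' The weight \eqn{base^{|p - r| / \delta}} with which a projected beat time
#' `p` counts as a hit on onset `r`: 1 at zero distance, `base` (0.01 by
#' default) at one full period, decaying exponentially in between.
#'
#' @param p,r beat and onset times in ms (vectorized).
#' @param period hypothesis period \eqn{\delta} in ms.
#' @param base decay base in (0, 1).
#' @return Weights in (0, 1].
#' @examples
#' concurrence(0, 250, period = 500)  # half a period away -> 0.1
#' @export
concurrence <- function(p, r, period, base = 0.01) {
  if (any(period <= 0)) stop("`period` must be positive", call. = FALSE)
  base^(abs(p - r) / period)
}

# index of the nearest onset for each beat time; ties go to the earlier onset
nearest_onset <- function(beat_times, onsets) {
  idx <- findInterval(beat_times, onsets)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(onsets))
  d_lo <- abs(beat_times - onsets[lo])
  d_hi <- abs(beat_times - onsets[hi])
  ifelse(d_lo <= d_hi, lo, hi)
}

#' Match projected beats to onsets
#'
#' Pairs every projected beat with its nearest onset (ties broken toward the
#' earlier onset). Several beats may share an onset; the formula does not
#' forbid it.
#'
#' @param beat_times projected beat times (ms), increasing.
#' @param onsets onset times (ms), strictly increasing, non-empty.
#' @return A data frame with columns `beat_time`, `onset_index` (1-based into
#'   `onsets`), `onset_time` and `distance` (ms).
#' @export
match_beats <- function(beat_times, onsets) {
  if (length(onsets) == 0L)
    stop("cannot match against an empty onset set", call. = FALSE)
  if (length(beat_times) == 0L)
    return(data.frame(beat_time = numeric(0), onset_index = integer(0),
                      onset_time = numeric(0), distance = numeric(0)))
  j <- nearest_onset(beat_times, onsets)
  data.frame(beat_time = beat_times, onset_index = j,
             onset_time = onsets[j], distance = abs(beat_times - onsets[j]))
}

# scoring window: [max(first onset, now - context), now]
context_bounds <- function(onsets, now, cfg) {
  c(max(onsets[1L], now - cfg$context_window), now)
}

# core congruency on a pre-windowed onset set
.congruency <- function(phase, period, win_onsets, lo, hi, cfg) {
  p <- .project(phase, period, lo, hi, cfg$projection_tol)
  n_pred <- length(p$time)
  if (n_pred == 0L) return(0)
  j <- nearest_onset(p$time, win_onsets)
  hits <- sum(cfg$concurrence_base^(abs(p$time - win_onsets[j]) / period))
  score <- (hits / n_pred) * (hits / length(win_onsets))
  min(max(score, 0), 1)
}

#' Congruency score of a hypothesis
#'
#' The product of the projection's precision and sensitivity against the
#' onsets heard in the context window ending at `now`: with
#' \eqn{hits = \sum_k concurrence(p_k, r_k)},
#' \deqn{congruency = \frac{hits}{predictions} \times \frac{hits}{events},}
#' where `predictions` is the number of projected beats and `events` the
#' number of onsets, both inside
#' `[max(first onset, now - context_window), now]`. The score is clamped to
#' \[0, 1\] (several beats matching one onset can push the sensitivity term
#' marginally above 1). A hypothesis projecting no beat into the window
#' scores 0.
#'
#' @inheritParams project_beats
#' @param onsets onset times in ms, strictly increasing.
#' @param now current time (ms); usually the last onset processed.
#' @param config a [tht_config()].
#' @return A score in \[0, 1\].
#' @examples
#' on <- 1.04167 + 500 * 0:2
#' congruency(tht_hypothesis(on[1], 1000), on, now = on[3])  # 2/2 * 2/3
#' @export
congruency <- function(hypothesis, onsets, now, config = tht_config()) {
  h <- as_hypothesis(hypothesis)
  cfg <- as_config(config)
  onsets <- validate_onsets(onsets, min_length = 1L)
  b <- context_bounds(onsets, now, cfg)
  keep <- onsets >= b[1L] - cfg$projection_tol &
          onsets <= b[2L] + cfg$projection_tol
  win <- onsets[keep]
  if (length(win) == 0L)
    stop("no onsets inside the context window ending at ", format(now),
         call. = FALSE)
  .congruency(h$phase, h$period, win, b[1L], b[2L], cfg)
}
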