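# Hypothesis correction against expressive timing.
#
# The projection error r_k - p_k between each projected beat and its nearest
# onset is attenuated by how far apart they are (so beats with no nearby
# onset contribute almost nothing), then regressed on the integer beat index
# k. The regression slope is the period correction (ms per beat) and the
# intercept, extrapolated to k = 0, the phase correction.

#' Corrected prediction error
#'
#' The signed, distance-attenuated projection error
#' \deqn{ce_k = m (r_k - p_k)\, d^{|p_k - r_k| / \delta}.}
#' It is zero when beat and onset coincide, grows with small distances, and
#' decays back to zero for large ones, so projected beats with no matching
#' onset are effectively ignored by the correction. Its magnitude peaks at
#' distance \eqn{\delta / \ln(1/d)}.
#'
#' @param p projected beat time(s), ms.
#' @param r matched onset time(s), ms.
#' @param period hypothesis period \eqn{\delta}, ms.
#' @param m multiplier (sensitivity of the correction).
#' @param d decay in (0, 1) (how soon a distance is too large to matter).
#' @return Signed error(s) in ms.
#' @examples
#' corrected_error(p = 1500, r = 1480, period = 500)  # about -27.67 ms
#' @export
corrected_error <- function(p, r, period, m = 2, d = 1e-4) {
  if (any(period <= 0)) stop("`period` must be positive", call. = FALSE)
  m * (r - p) * d^(abs(p - r) / period)
}

# closed-form OLS of y on x; returns c(intercept, slope)
ols_line <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  sxx <- sum((x - xb)^2)
  if (sxx == 0) return(c(yb, 0))
  slope <- sum((x - xb) * (y - yb)) / sxx
  c(yb - slope * xb, slope)
}

# core correction on a pre-windowed onset set; returns list(phase, period,
# delta_phase, delta_period, n_points)
.correct <- function(phase, period, win_onsets, lo, hi, cfg) {
  zero <- list(phase = phase, period = period,
               delta_phase = 0, delta_period = 0, n_points = 0L)
  pr <- .project(phase, period, lo, hi, cfg$projection_tol)
  n <- length(pr$time)
  if (n < 2L || length(win_onsets) == 0L) return(zero)
  j <- nearest_onset(pr$time, win_onsets)
  ce <- cfg$corr_multiplier * (win_onsets[j] - pr$time) *
    cfg$corr_decay^(abs(pr$time - win_onsets[j]) / period)
  ab <- ols_line(pr$index, ce)
  new_period <- period + ab[2L]
  if (new_period <= 0) new_period <- .Machine$double.xmin
  list(phase = phase + ab[1L], period = new_period,
       delta_phase = ab[1L], delta_period = ab[2L], n_points = n)
}

#' Correct a hypothesis against the recent passage
#'
#' Projects the hypothesis over the context window ending at `now`, matches
#' each beat to its nearest windowed onset, computes the corrected prediction
#' errors [corrected_error()], and fits an ordinary least-squares line of
#' error against integer beat index. The fitted intercept shifts the phase
#' and the slope adjusts the period, so after correction the projection sits
#' closer to the onsets actually heard. With fewer than two projected beats
#' in the window the correction is zero.
#'
#' @inheritParams congruency
#' @return A list with elements `hypothesis` (the corrected
#'   [tht_hypothesis()]) and `correction` (a list with `delta_phase` (ms),
#'   `delta_period` (ms per beat) and `n_points`).
#' @examples
#' on <- c(0, 500, 1000, 1480, 2000)
#' correct_hypothesis(tht_hypothesis(0, 500), on, now = 2000)
#' @export
correct_hypothesis <- function(hypothesis, onsets, now,
                               config = tht_config()) {
  h <- as_hypothesis(hypothesis)
  cfg <- as_config(config)
  onsets <- validate_onsets(onsets, min_length = 1L)
  b <- context_bounds(onsets, now, cfg)
  win <- onsets[onsets >= b[1L] - cfg$projection_tol &
                onsets <= b[2L] + cfg$projection_tol]
  res <- .correct(h$phase, h$period, win, b[1L], b[2L], cfg)
  list(hypothesis = tht_hypothesis(res$phase, res$period),
       correction = list(delta_phase = res$delta_phase,
                         delta_period = res$delta_period,
                         n_points = res$n_points))
}
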