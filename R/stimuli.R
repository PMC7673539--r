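# Deterministic synthetic rhythm generators: the four scripted passages used
# to probe the clarity dynamics (period change, phase change, rallentando,
# mixed patterns) plus parametric isochronous and jittered fixtures. All
# outputs are valid onset sequences in ms.

#' Isochronous rhythm
#'
#' @param n number of onsets (>= 2).
#' @param ioi inter-onset interval in ms.
#' @param phase time of the first onset in ms.
#' @return Onset times `phase + k * ioi`, `k = 0..n-1`.
#' @examples
#' stim_isochronous(3, 500)
#' @export
stim_isochronous <- function(n, ioi, phase = 0) {
  if (n < 2 || ioi <= 0 || phase < 0)
    stop("need n >= 2, ioi > 0, phase >= 0", call. = FALSE)
  validate_onsets(phase + (seq_len(n) - 1) * ioi)
}

#' Period-changing rhythm
#'
#' An isochronous passage whose pulse switches to a new inter-onset interval
#' part-way through: `n1` onsets at `ioi1`, then `n2` further onsets
#' continuing at `ioi2` from the last time. The defaults switch to a pulse
#' twice as fast half-way, the scenario in which the leading hypothesis is
#' expected to lose congruency and be replaced.
#'
#' @param n1,ioi1 first-section onset count and interval (ms).
#' @param n2,ioi2 onsets appended after the change and their interval (ms).
#' @return Onset times in ms.
#' @examples
#' stim_period_change(2, 500, 2, 250)  # 0 500 750 1000
#' @export
stim_period_change <- function(n1 = 12, ioi1 = 500, n2 = 24, ioi2 = 250) {
  if (n1 < 2 || n2 < 1 || ioi1 <= 0 || ioi2 <= 0)
    stop("need n1 >= 2, n2 >= 1 and positive intervals", call. = FALSE)
  first <- (seq_len(n1) - 1) * ioi1
  validate_onsets(c(first, first[n1] + seq_len(n2) * ioi2))
}

#' Phase-changing rhythm
#'
#' An isochronous grid whose phase jumps forward by `shift` ms at each
#' change point (given as fractions of the passage). With the default
#' half-period shift applied at 1/3 and 2/3, the second jump returns the
#' rhythm to the original phase (two half-period shifts make a full
#' period), producing two clarity valleys. The default length keeps each
#' constant-phase section longer than the model's 6 s context window so the
#' clarity plateau can re-establish between the changes.
#'
#' @param n number of onsets.
#' @param ioi inter-onset interval in ms.
#' @param points fractions in (0, 1) at which the phase jumps.
#' @param shift forward phase jump in ms (default half a period).
#' @return Onset times in ms.
#' @examples
#' stim_phase_change(6, 500)  # 0 500 1250 1750 2500 3000
#' @export
stim_phase_change <- function(n = 42, ioi = 500, points = c(1 / 3, 2 / 3),
                              shift = ioi / 2) {
  if (n < 2 || ioi <= 0 || shift < 0)
    stop("need n >= 2, ioi > 0, shift >= 0", call. = FALSE)
  if (any(points <= 0 | points >= 1))
    stop("`points` must be interior fractions in (0, 1)", call. = FALSE)
  k <- seq_len(n) - 1
  jumps <- vapply(k, function(kk) sum(kk >= floor(n * points)), numeric(1))
  validate_onsets(k * ioi + jumps * shift)
}

#' Rallentando (progressive tempo change)
#'
#' Each inter-onset interval is the previous one scaled by `factor`;
#' `factor > 1` slows down progressively (the expressive rallentando),
#' `factor < 1` accelerates, `factor = 1` is isochronous.
#'
#' @param n number of onsets.
#' @param ioi0 first inter-onset interval in ms.
#' @param factor per-onset interval ratio (> 0).
#' @return Onset times in ms.
#' @examples
#' stim_rallentando(3, 400, 1.03)  # 0 400 812
#' @export
stim_rallentando <- function(n = 30, ioi0 = 400, factor = 1.03) {
  if (n < 2 || ioi0 <= 0 || factor <= 0)
    stop("need n >= 2, ioi0 > 0, factor > 0", call. = FALSE)
  validate_onsets(c(0, cumsum(ioi0 * factor^(0:(n - 2)))))
}

#' Default mixed-pattern bank
#'
#' Five rhythmic subpatterns over a 500 ms tactus: the plain tactus, an
#' eighth-note pickup, the 3-3-2 tresillo, a half-time figure and a
#' syncopated run. Some are not isochronous, so the pattern stream carries
#' less pulse evidence than a plain isochronous rhythm.
#'
#' @return A list of inter-onset-interval vectors (ms).
#' @export
mixed_pattern_bank <- function() {
  list(c(500),
       c(250, 250, 500),
       c(375, 375, 250),
       c(500, 1000),
       c(250, 250, 250, 750))
}

#' Mixed-pattern rhythm
#'
#' Concatenates each subpattern (a vector of inter-onset intervals),
#' repeated `repeats` times, into one passage starting at 0.
#'
#' @param subpatterns list of IOI vectors (ms); at least one non-empty
#'   vector each.
#' @param repeats times each subpattern is repeated before moving on.
#' @return Onset times in ms.
#' @examples
#' stim_mixed_patterns(list(c(500), c(250, 250)), repeats = 2)
#' @export
stim_mixed_patterns <- function(subpatterns = mixed_pattern_bank(),
                                repeats = 4) {
  if (!is.list(subpatterns) || length(subpatterns) < 1L ||
      any(!vapply(subpatterns, length, 0L)))
    stop("`subpatterns` must be a non-empty list of non-empty IOI vectors",
         call. = FALSE)
  iois <- unlist(lapply(subpatterns, function(p) rep(p, repeats)))
  if (any(iois <= 0)) stop("all IOIs must be positive", call. = FALSE)
  validate_onsets(c(0, cumsum(iois)))
}

#' Jitter an onset sequence
#'
#' Adds an independent uniform perturbation in `[-amplitude, amplitude]` ms
#' to every onset — a test fixture emulating expressive/motor timing noise.
#' The amplitude must stay below half the smallest inter-onset interval so
#' ordering is preserved. Deterministic given `seed`; the caller's RNG state
#' is left untouched.
#'
#' @param onsets onset times in ms, strictly increasing.
#' @param amplitude maximum absolute perturbation in ms.
#' @param seed integer seed (NULL uses — and advances — the current RNG).
#' @return Jittered onset times, strictly increasing.
#' @export
jitter_onsets <- function(onsets, amplitude, seed = NULL) {
  onsets <- validate_onsets(onsets)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (amplitude >= min(diff(onsets)) / 2)
    stop("`amplitude` must be below half the smallest inter-onset interval",
         call. = FALSE)
  if (amplitude == 0) return(onsets)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  out <- onsets + stats::runif(length(onsets), -amplitude, amplitude)
  validate_onsets(out)
  out
}
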