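#' Model configuration
#'
#' Bundles every tunable parameter of the tracker. Defaults are the model's
#' published operating point: a 6000 ms context window, concurrence base
#' 0.01, correction multiplier \eqn{m = 2} and decay \eqn{d = 10^{-4}}, and
#' hypothesis periods between 187 and 1500 ms (320–40 bpm). The similarity
#' thresholds that govern collapsing of near-duplicate hypotheses and the
#' projection boundary tolerance are implementation parameters.
#'
#' @param context_window ms of passage before the current onset used for
#'   correction and scoring.
#' @param concurrence_base base of the distance weight
#'   \eqn{base^{|p-r|/\delta}}; must lie in (0, 1).
#' @param corr_multiplier multiplier \eqn{m} of the corrected prediction
#'   error.
#' @param corr_decay decay \eqn{d} of the corrected prediction error; must
#'   lie in (0, 1).
#' @param min_period,max_period ms bounds on generated hypothesis periods.
#' @param similarity_rel_period relative period difference below which two
#'   hypotheses are considered the same pulse.
#' @param similarity_rel_phase phase difference, as a fraction of the mean
#'   period (circular), below which two hypotheses share their phase.
#' @param projection_tol ms tolerance applied at projection bounds so beats
#'   falling exactly on a passage boundary are kept under floating point.
#' @param max_trackers optional cap on live trackers; when finite, the
#'   lowest-scoring trackers are pruned after collapsing (off by default).
#' @return An object of class `tht_config` (a named list).
#' @examples
#' cfg <- tht_config()
#' cfg$context_window
#' @export
tht_config <- function(context_window = 6000,
                       concurrence_base = 0.01,
                       corr_multiplier = 2,
                       corr_decay = 1e-4,
                       min_period = 187,
                       max_period = 1500,
                       similarity_rel_period = 0.02,
                       similarity_rel_phase = 0.02,
                       projection_tol = 1e-6,
                       max_trackers = Inf) {
  cfg <- list(
    context_window = as.numeric(context_window),
    concurrence_base = as.numeric(concurrence_base),
    corr_multiplier = as.numeric(corr_multiplier),
    corr_decay = as.numeric(corr_decay),
    min_period = as.numeric(min_period),
    max_period = as.numeric(max_period),
    similarity_rel_period = as.numeric(similarity_rel_period),
    similarity_rel_phase = as.numeric(similarity_rel_phase),
    projection_tol = as.numeric(projection_tol),
    max_trackers = as.numeric(max_trackers)
  )
  for (nm in setdiff(names(cfg), "max_trackers")) {
    v <- cfg[[nm]]
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single positive finite number", call. = FALSE)
  }
  if (cfg$concurrence_base >= 1)
    stop("`concurrence_base` must lie in (0, 1)", call. = FALSE)
  if (cfg$corr_decay >= 1)
    stop("`corr_decay` must lie in (0, 1)", call. = FALSE)
  if (cfg$min_period >= cfg$max_period)
    stop("`min_period` must be smaller than `max_period`", call. = FALSE)
  if (length(cfg$max_trackers) != 1L || is.na(cfg$max_trackers) ||
      cfg$max_trackers < 1)
    stop("`max_trackers` must be a number >= 1 (or Inf)", call. = FALSE)
  structure(cfg, class = "tht_config")
}

#' @export
print.tht_config <- function(x, ...) {
  cat("<tht_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Tactus hypothesis
#'
#' An isochronous pulse candidate: a phase (the time of one of its beats, in
#' ms) and a period (inter-beat interval, ms).
#'
#' @param phase beat time in ms.
#' @param period inter-beat interval in ms; must be positive.
#' @return An object of class `tht_hypothesis`.
#' @examples
#' tht_hypothesis(phase = 0, period = 500)
#' @export
tht_hypothesis <- function(phase, period) {
  phase <- as.numeric(phase)
  period <- as.numeric(period)
  if (length(phase) != 1L || !is.finite(phase))
    stop("`phase` must be a single finite number", call. = FALSE)
  if (length(period) != 1L || !is.finite(period) || period <= 0)
    stop("`period` must be a single positive number", call. = FALSE)
  structure(list(phase = phase, period = period), class = "tht_hypothesis")
}

#' @export
print.tht_hypothesis <- function(x, ...) {
  cat(sprintf("<tht_hypothesis> phase %g ms, period %g ms\n",
              x$phase, x$period))
  invisible(x)
}

as_config <- function(config) {
  if (is.null(config)) return(tht_config())
  if (!inherits(config, "tht_config"))
    stop("`config` must be created with tht_config()", call. = FALSE)
  config
}

as_hypothesis <- function(h) {
  if (inherits(h, "tht_hypothesis")) return(h)
  if (is.numeric(h) && length(h) == 2L) return(tht_hypothesis(h[[1]], h[[2]]))
  if (is.list(h) && all(c("phase", "period") %in% names(h)))
    return(tht_hypothesis(h$phase, h$period))
  stop("`hypothesis` must be a tht_hypothesis (or phase/period pair)",
       call. = FALSE)
}
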