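# The causal main loop. Per onset, in order: spawn new hypothesis trackers
# from onset pairs, correct every live tracker against the context window,
# score every tracker and record its state, then collapse trackers that have
# converged onto the same pulse (keeping the oldest). Only information up to
# the current onset is ever used.

#' Generate candidate hypotheses at an onset
#'
#' At onset index `t` (0-based), every earlier onset `a` forms a candidate
#' hypothesis with phase \eqn{\rho = r_a} and period
#' \eqn{\delta = r_t - r_a}, kept only when the period lies within the
#' configured bounds (187–1500 ms by default, i.e. 320–40 bpm).
#'
#' @param onsets onset times in ms, strictly increasing.
#' @param t 0-based index of the onset being processed; `t >= 1`.
#' @param config a [tht_config()].
#' @return A data frame with columns `a`, `b` (0-based onset indices) and
#'   `phase`, `period` (ms); zero rows when no inter-onset interval is in
#'   bounds.
#' @examples
#' generate_hypotheses(c(0, 500, 1000), t = 2)
#' @export
generate_hypotheses <- function(onsets, t, config = tht_config()) {
  cfg <- as_config(config)
  onsets <- validate_onsets(onsets)
  t <- as.integer(t)
  if (t < 1L || t >= length(onsets))
    stop("`t` must be a 0-based onset index in [1, n-1]", call. = FALSE)
  a <- seq_len(t) - 1L
  period <- onsets[t + 1L] - onsets[a + 1L]
  keep <- period >= cfg$min_period & period <= cfg$max_period
  data.frame(a = a[keep], b = rep.int(t, sum(keep)),
             phase = onsets[a + 1L][keep], period = period[keep])
}

.is_similar <- function(phase1, period1, phase2, period2, cfg) {
  dbar <- (period1 + period2) / 2
  if (abs(period1 - period2) / dbar > cfg$similarity_rel_period)
    return(FALSE)
  dd <- abs(phase1 %% dbar - phase2 %% dbar)
  dd <- min(dd, dbar - dd)
  dd <= cfg$similarity_rel_phase * dbar
}

#' Are two hypotheses tracking the same pulse?
#'
#' True when the periods differ by at most `similarity_rel_period` of their
#' mean and the phases agree modulo the mean period (circular distance at
#' most `similarity_rel_phase` of the mean period). Trackers satisfying this
#' are collapsed during tracking, preserving the oldest.
#'
#' @param h1,h2 hypotheses ([tht_hypothesis()] or `c(phase, period)` pairs).
#' @param config a [tht_config()].
#' @return Logical scalar.
#' @examples
#' is_similar(tht_hypothesis(0, 500), tht_hypothesis(1, 503))
#' @export
is_similar <- function(h1, h2, config = tht_config()) {
  h1 <- as_hypothesis(h1)
  h2 <- as_hypothesis(h2)
  cfg <- as_config(config)
  .is_similar(h1$phase, h1$period, h2$phase, h2$period, cfg)
}

new_tracker <- function(a, b, phase, period) {
  list(a = a, b = b, created = b, phase = phase, period = period,
       onset_index = integer(0), onset_time = numeric(0),
       phase_hist = numeric(0), period_hist = numeric(0),
       score_hist = numeric(0))
}

#' Run the tactus tracker on an onset sequence
#'
#' Processes onsets causally. For each onset index `t = 1..n-1`, in order:
#' (1) spawn new trackers from every prior onset whose distance to the
#' current onset is an admissible period ([generate_hypotheses()]);
#' (2) correct every live tracker's phase and period against the context
#' window ending at the current onset ([correct_hypothesis()]);
#' (3) score every tracker ([congruency()]) and append a state to its
#' history; (4) collapse trackers that track the same pulse
#' ([is_similar()]), keeping the oldest (creation order, then lower
#' `(a, b)`). The per-step top score and its tracker are recorded as they
#' happen, which makes the clarity curve strictly causal.
#'
#' @param onsets onset times in ms, strictly increasing, length >= 2.
#' @param config a [tht_config()].
#' @return An object of class `tht_tracking`: a list with `onsets`,
#'   `config`, `trackers` (surviving trackers, each with its full state
#'   history) and `timeline` (per-step top hypothesis; see
#'   [top_hypothesis_timeline()]).
#' @examples
#' res <- tht_track(stim_isochronous(10, 500))
#' overall_clarity(res)
#' @export
tht_track <- function(onsets, config = tht_config()) {
  cfg <- as_config(config)
  x <- validate_onsets(onsets)
  n <- length(x)
  trackers <- list()
  any_created <- FALSE
  tl <- vector("list", n - 1L)

  for (t in 2:n) {
    now <- x[t]
    b0 <- t - 1L                       # 0-based index of this onset
    # (1) spawn
    ioi <- now - x[seq_len(t - 1L)]
    for (ai in which(ioi >= cfg$min_period & ioi <= cfg$max_period)) {
      trackers[[length(trackers) + 1L]] <-
        new_tracker(ai - 1L, b0, x[ai], ioi[ai])
      any_created <- TRUE
    }
    if (length(trackers) == 0L) next   # nothing trackable yet

    bnds <- context_bounds(x, now, cfg)
    lo <- bnds[1L]
    hi <- bnds[2L]
    win <- x[x >= lo - cfg$projection_tol & x <= hi + cfg$projection_tol]

    # (2) correct and (3) score every live tracker, recording its state
    for (i in seq_along(trackers)) {
      tr <- trackers[[i]]
      cr <- .correct(tr$phase, tr$period, win, lo, hi, cfg)
      tr$phase <- cr$phase
      tr$period <- cr$period
      s <- .congruency(tr$phase, tr$period, win, lo, hi, cfg)
      tr$onset_index <- c(tr$onset_index, b0)
      tr$onset_time <- c(tr$onset_time, now)
      tr$phase_hist <- c(tr$phase_hist, tr$phase)
      tr$period_hist <- c(tr$period_hist, tr$period)
      tr$score_hist <- c(tr$score_hist, s)
      trackers[[i]] <- tr
    }

    # (4) collapse near-duplicates; list order is creation order so the
    # first survivor of each similarity class is the oldest
    kept <- integer(0)
    for (i in seq_along(trackers)) {
      sim <- FALSE
      for (j in kept) {
        if (.is_similar(trackers[[i]]$phase, trackers[[i]]$period,
                        trackers[[j]]$phase, trackers[[j]]$period, cfg)) {
          sim <- TRUE
          break
        }
      }
      if (!sim) kept <- c(kept, i)
    }
    trackers <- trackers[kept]

    if (is.finite(cfg$max_trackers) &&
        length(trackers) > cfg$max_trackers) {
      sc <- vapply(trackers, function(tr) tr$score_hist[length(tr$score_hist)],
                   numeric(1))
      # keep the highest-scoring cap, stable in age order
      keep_idx <- sort(order(-sc)[seq_len(cfg$max_trackers)])
      message("tht_track: pruning ", length(trackers) - cfg$max_trackers,
              " tracker(s) at onset index ", b0)
      trackers <- trackers[keep_idx]
    }

    sc <- vapply(trackers, function(tr) tr$score_hist[length(tr$score_hist)],
                 numeric(1))
    top <- which.max(sc)               # first maximum -> oldest tracker
    tr <- trackers[[top]]
    tl[[t - 1L]] <- data.frame(
      onset_index = b0, onset_time = now, a = tr$a, b = tr$b,
      phase = tr$phase, period = tr$period, score = sc[top])
  }

  if (!any_created)
    stop("no trackable pulse: no inter-onset interval lies within [",
         cfg$min_period, ", ", cfg$max_period, "] ms", call. = FALSE)

  timeline <- do.call(rbind, tl[!vapply(tl, is.null, logical(1))])
  rownames(timeline) <- NULL
  names(trackers) <- vapply(trackers,
                            function(tr) paste0(tr$a, "-", tr$b),
                            character(1))
  structure(list(onsets = x, config = cfg, trackers = trackers,
                 timeline = timeline),
            class = "tht_tracking")
}

#' @export
print.tht_tracking <- function(x, ...) {
  cat(sprintf(paste0("<tht_tracking> %d onsets over %.0f ms, ",
                     "%d surviving tracker(s), overall clarity %.4f\n"),
              length(x$onsets), diff(range(x$onsets)),
              length(x$trackers), mean(x$timeline$score)))
  invisible(x)
}

#' Top hypothesis per processed onset
#'
#' The highest-scoring live tracker at each onset index (ties broken toward
#' the older tracker), with its post-correction parameters and score. The
#' timeline is recorded during the causal pass, so a tracker collapsed at a
#' later step still appears at the steps where it led.
#'
#' @param result a [tht_track()] result.
#' @return A data frame with columns `onset_index`, `onset_time`, `a`, `b`,
#'   `phase`, `period`, `score`.
#' @export
top_hypothesis_timeline <- function(result) {
  stopifnot(inherits(result, "tht_tracking"))
  result$timeline
}
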