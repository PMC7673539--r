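# Beat-track extraction: projecting the leading hypothesis through the
# passage. Beats are emitted predictively from hypothesis parameters, never
# snapped to onsets, so no future information is used.

# Beats of (phase, period) over one inter-onset segment [lo, hi); `seam`
# extends both ends so a beat sitting exactly on a segment boundary cannot
# fall between two segments when the owning grid's parameters differ by a
# hair on either side (duplicate emissions are merged downstream). The
# final segment is closed at hi and not extended past it.
segment_beats <- function(phase, period, lo, hi, closed, tol, seam = 5) {
  up <- if (closed) hi + tol else hi + seam
  p <- .project(phase, period, lo - seam, up, tol)$time
  if (closed) p else p[p < hi + seam - tol]
}

# drop beats closer than eps to the previously kept one (keep the earlier)
merge_close <- function(times, eps) {
  out <- numeric(0)
  for (t in times) {
    if (length(out) == 0L || t - out[length(out)] >= eps) out <- c(out, t)
  }
  out
}

#' Naive beat track
#'
#' Walks the processed onsets in order; each inter-onset segment
#' `[r_t, r_{t+1})` is owned by the hypothesis that led (post-correction)
#' when `r_t` was processed, and that hypothesis' projected beats in the
#' segment are emitted. After the final onset, beats are emitted up to the
#' final onset time. Beats closer than 10 ms (segment-seam duplicates) are
#' merged keeping the earlier.
#'
#' @param result a [tht_track()] result.
#' @return Strictly increasing beat times in ms, with an attribute
#'   `segments` (data frame `onset_index`, `tracker`) recording which
#'   tracker generated each inter-onset segment.
#' @examples
#' extract_beats_naive(tht_track(stim_isochronous(10, 500)))
#' @export
extract_beats_naive <- function(result) {
  tl <- top_hypothesis_timeline(result)
  tol <- result$config$projection_tol
  k <- nrow(tl)
  beats <- vector("list", k)
  for (i in seq_len(k)) {
    final <- i == k
    hi <- if (final) tl$onset_time[i] else tl$onset_time[i + 1L]
    beats[[i]] <- segment_beats(tl$phase[i], tl$period[i],
                                tl$onset_time[i], hi, closed = final, tol)
  }
  structure(merge_close(sort(unlist(beats)), eps = 10),
            segments = data.frame(onset_index = tl$onset_index,
                                  tracker = paste0(tl$a, "-", tl$b)))
}

# smallest power-of-two multiple of `period` strictly above `floor_ms`
tap_multiplier <- function(period, floor_ms) {
  mult <- 1
  while (period * mult <= floor_ms) mult <- mult * 2
  mult
}

# circular distance from each time in b to the grid (phase, period)
grid_distance <- function(b, phase, period) {
  d <- (b - phase) %% period
  pmin(d, period - d)
}

#' Tempo- and continuity-adapted beat track
#'
#' As [extract_beats_naive()], with two adaptations aimed at tapping-like
#' output: (i) *hysteresis* — a challenger hypothesis replaces the incumbent
#' only after its score has exceeded the incumbent's continuously for more
#' than `adoption_lag` ms of onset time (an incumbent that disappears by
#' collapse is replaced immediately); (ii) *tempo floor* — the emitted
#' period is the hypothesis period doubled as often as needed to exceed
#' `min_tap_period` ms (beat slower than 160 bpm). When doubling, the
#' emitted phase is chosen between the hypothesis phase and the phase offset
#' by one original period, whichever lies closer on average to the last
#' emitted beats. Emitted beats closer than `min_tap_period` to the previous
#' beat (possible only at adoption seams) are suppressed, so the output's
#' inter-beat intervals always exceed the floor.
#'
#' @param result a [tht_track()] result.
#' @param min_tap_period ms floor on the emitted beat period (default 375).
#' @param adoption_lag ms a challenger must continuously outscore the
#'   incumbent before being adopted (default 3000).
#' @return Strictly increasing beat times in ms, with an attribute
#'   `segments` (data frame `onset_index`, `tracker`) recording the
#'   incumbent tracker of each inter-onset segment.
#' @export
extract_beats_adapted <- function(result, min_tap_period = 375,
                                  adoption_lag = 3000) {
  tl <- top_hypothesis_timeline(result)
  trs <- result$trackers
  tol <- result$config$projection_tol
  ids <- names(trs)
  state_at <- function(id, oi) {
    tr <- trs[[id]]
    j <- match(oi, tr$onset_index)
    if (is.na(j)) return(NULL)
    list(phase = tr$phase_hist[j], period = tr$period_hist[j],
         score = tr$score_hist[j])
  }

  incumbent <- NULL
  offset_beats <- 0
  exceed_since <- numeric(0)          # named by tracker id
  emitted <- numeric(0)

  adopt <- function(id, oi) {
    st <- state_at(id, oi)
    mult <- tap_multiplier(st$period, min_tap_period)
    off <- 0
    if (mult > 1 && length(emitted)) {
      recent <- utils::tail(emitted, 3L)
      cand <- c(0, 1)
      cost <- vapply(cand, function(o) {
        mean(grid_distance(recent, st$phase + o * st$period,
                           mult * st$period))
      }, numeric(1))
      off <- cand[which.min(cost)]
    }
    incumbent <<- id
    offset_beats <<- off
    exceed_since <<- numeric(0)
  }

  k <- nrow(tl)
  seg_tracker <- character(k)
  for (i in seq_len(k)) {
    oi <- tl$onset_index[i]
    now <- tl$onset_time[i]
    top_id <- paste0(tl$a[i], "-", tl$b[i])

    inc_st <- if (is.null(incumbent)) NULL else state_at(incumbent, oi)
    if (is.null(inc_st)) {
      adopt(top_id, oi)               # first onset, or incumbent collapsed
      inc_st <- state_at(incumbent, oi)
    } else {
      # challenge bookkeeping over every tracker live at this onset
      for (id in ids) {
        if (id == incumbent) next
        st <- state_at(id, oi)
        if (!is.null(st) && st$score > inc_st$score) {
          if (is.na(exceed_since[id])) exceed_since[id] <- now
        } else {
          exceed_since <- exceed_since[names(exceed_since) != id]
        }
      }
      ok <- names(exceed_since)[now - exceed_since > adoption_lag]
      if (length(ok)) {
        sc <- vapply(ok, function(id) state_at(id, oi)$score, numeric(1))
        # ties resolved toward the older tracker (creation order of ids)
        best <- ok[order(-sc, match(ok, ids))][1L]
        adopt(best, oi)
        inc_st <- state_at(incumbent, oi)
      }
    }

    seg_tracker[i] <- incumbent
    mult <- tap_multiplier(inc_st$period, min_tap_period)
    em_phase <- inc_st$phase + offset_beats * inc_st$period
    em_period <- mult * inc_st$period
    final <- i == k
    hi <- if (final) now else tl$onset_time[i + 1L]
    p <- segment_beats(em_phase, em_period, now, hi, closed = final, tol)
    for (b in p) {
      if (length(emitted) == 0L ||
          b - emitted[length(emitted)] > min_tap_period)
        emitted <- c(emitted, b)
    }
  }
  structure(emitted,
            segments = data.frame(onset_index = tl$onset_index,
                                  tracker = seg_tracker))
}

#' Extract a beat track
#'
#' Front-end over [extract_beats_naive()] and [extract_beats_adapted()].
#'
#' @param result a [tht_track()] result.
#' @param method `"naive"` or `"adapted"`.
#' @param ... passed to [extract_beats_adapted()].
#' @return Strictly increasing beat times in ms.
#' @export
tht_beats <- function(result, method = c("naive", "adapted"), ...) {
  method <- match.arg(method)
  switch(method,
         naive = extract_beats_naive(result),
         adapted = extract_beats_adapted(result, ...))
}
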