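# Table, clarity-curve and summary outputs of a tracking run.

#' Tracker-state table
#'
#' One row per recorded tracker state: the tracker's identifying onset pair
#' `(a, b)`, the onset index and time of the state, and the tracker's
#' post-correction period, phase and congruency score at that onset. Rows
#' are grouped by tracker and ordered by `(a, b, onset_index)`.
#'
#' @param result a [tht_track()] result.
#' @return A data frame with columns `a`, `b`, `onset_index`, `onset_time`,
#'   `period`, `phase`, `score`.
#' @examples
#' head(tht_table(tht_track(stim_isochronous(6, 500))))
#' @export
tht_table <- function(result) {
  stopifnot(inherits(result, "tht_tracking"))
  rows <- lapply(result$trackers, function(tr) {
    data.frame(a = tr$a, b = tr$b, onset_index = tr$onset_index,
               onset_time = tr$onset_time, period = tr$period_hist,
               phase = tr$phase_hist, score = tr$score_hist)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$a, out$b, out$onset_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the tracker-state table as CSV
#'
#' Numeric columns are written with 6 significant digits, the table's
#' display convention.
#'
#' @param x a [tht_track()] result or a [tht_table()] data frame.
#' @param path output file.
#' @param header optional character vector written first as `#` comments.
#' @return `path`, invisibly.
#' @export
write_tht_table <- function(x, path, header = NULL) {
  tab <- if (inherits(x, "tht_tracking")) tht_table(x) else x
  out <- tab
  for (nm in c("onset_time", "period", "phase", "score"))
    out[[nm]] <- sprintf("%.6g", out[[nm]])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Pulse-clarity curve
#'
#' The congruency score of the top hypothesis after each processed onset —
#' the model's pulse-clarity signal over time — together with the identity
#' of the leading tracker.
#'
#' @param result a [tht_track()] result.
#' @return A data frame of class `tht_clarity` with columns `onset_index`,
#'   `onset_time`, `score` and `tracker` (the leading tracker's `"a-b"`
#'   label).
#' @examples
#' clarity_curve(tht_track(stim_isochronous(8, 500)))
#' @export
clarity_curve <- function(result) {
  tl <- top_hypothesis_timeline(result)
  out <- data.frame(onset_index = tl$onset_index,
                    onset_time = tl$onset_time,
                    score = tl$score,
                    tracker = paste0(tl$a, "-", tl$b))
  class(out) <- c("tht_clarity", "data.frame")
  out
}

#' Overall pulse clarity
#'
#' The arithmetic mean of the top hypothesis' congruency score over all
#' processed onsets — a scalar summary of how clearly the passage induces a
#' pulse (1 for a perfectly isochronous rhythm).
#'
#' @param result a [tht_track()] result or a [clarity_curve()] data frame.
#' @return A score in \[0, 1\].
#' @export
overall_clarity <- function(result) {
  cur <- if (inherits(result, "tht_tracking")) clarity_curve(result)
         else result
  if (!is.data.frame(cur) || !nrow(cur))
    stop("empty clarity curve", call. = FALSE)
  mean(cur$score)
}

#' Clarity dips
#'
#' Identifies the valleys of a clarity curve: maximal runs of consecutive
#' points whose score lies at least `min_depth` below the curve's plateau
#' (its maximum score). Shallow fluctuations — e.g. scoring noise when a
#' window boundary slides across the onset grid — are not dips; losing
#' `min_depth` of clarity is. Used to characterize responses to beat
#' changes (a period change produces one dip, a double phase change two).
#'
#' @param x a [clarity_curve()] data frame or a [tht_track()] result.
#' @param min_depth minimum clarity loss, relative to the plateau, for a
#'   run to count as a dip (default 0.2).
#' @return A data frame with one row per dip: `start`, `end` (row indices
#'   into the curve), `t_start`, `t_end` (ms), `min_score`, and `recovered`
#'   (TRUE when some later point returns to within `min_depth` of the
#'   plateau).
#' @export
clarity_dips <- function(x, min_depth = 0.2) {
  cur <- if (inherits(x, "tht_tracking")) clarity_curve(x) else x
  thr <- max(cur$score) - min_depth
  below <- cur$score < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start = starts[keep], end = ends[keep],
    t_start = cur$onset_time[starts[keep]],
    t_end = cur$onset_time[ends[keep]],
    min_score = vapply(keep, function(i) {
      min(cur$score[starts[i]:ends[i]])
    }, numeric(1)),
    recovered = ends[keep] < nrow(cur))
}

#' Write a clarity curve as CSV
#'
#' @param x a [clarity_curve()] data frame or a [tht_track()] result.
#' @param path output file.
#' @param header optional character vector written first as `#` comments.
#' @return `path`, invisibly.
#' @export
write_clarity <- function(x, path, header = NULL) {
  cur <- if (inherits(x, "tht_tracking")) clarity_curve(x) else x
  out <- data.frame(onset_time = sprintf("%.6g", cur$onset_time),
                    score = sprintf("%.6g", cur$score),
                    tracker = cur$tracker)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Plot a pulse-clarity curve
#'
#' Convenience base-graphics plot: score of the leading hypothesis over
#' time, with a marker wherever the leading tracker changes identity.
#'
#' @param x a [clarity_curve()] data frame.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tht_clarity <- function(x, ...) {
  graphics::plot(x$onset_time / 1000, x$score, type = "l", ylim = c(0, 1),
                 xlab = "time (s)", ylab = "congruency of top hypothesis",
                 ...)
  chg <- which(x$tracker != c(x$tracker[1L], x$tracker[-nrow(x)]))
  if (length(chg))
    graphics::points(x$onset_time[chg] / 1000, x$score[chg], pch = 4)
  invisible(x)
}
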