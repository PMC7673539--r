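# Tapping-variability statistic: the coefficient of variability (CV) of an
# annotator's inter-tap intervals, the empirical proxy for pulse clarity
# (steadier tapping = clearer pulse). Intervals longer than 3000 ms
# (a beat slower than 20 bpm, i.e. pauses) are filtered before computing.

#' Inter-tap-interval coefficient of variability
#'
#' Computes the CV (standard deviation over mean) of the inter-tap intervals
#' of one annotator, after removing intervals strictly larger than
#' `max_iti` ms. The normalization by the mean makes the statistic relative
#' to the tapping rate the annotator chose, so it is invariant under both
#' time translation and uniform time scaling.
#'
#' @param taps tap times in ms, strictly increasing.
#' @param max_iti ms; intervals larger than this are discarded (default
#'   3000).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Non-negative CV (unitless).
#' @examples
#' intertap_cv(c(0, 400, 1000))  # intervals 400, 600 -> about 0.283
#' @export
intertap_cv <- function(taps, max_iti = 3000,
                        sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  taps <- validate_onsets(taps, what = "tap")
  iti <- diff(taps)
  iti <- iti[iti <= max_iti]
  if (length(iti) < 2L)
    stop("CV undefined: fewer than 2 inter-tap intervals survive the ",
         max_iti, " ms filter", call. = FALSE)
  s <- stats::sd(iti)
  if (sd_type == "population")
    s <- s * sqrt((length(iti) - 1) / length(iti))
  s / mean(iti)
}

#' Mean tapping variability across annotators
#'
#' Per-annotator CVs ([intertap_cv()]) averaged over a track. Annotators
#' whose CV is undefined after filtering are excluded from the mean and
#' reported as such.
#'
#' @param records list of tap-time vectors (ms), optionally named by
#'   annotator.
#' @param max_iti passed to [intertap_cv()].
#' @param sd_type passed to [intertap_cv()].
#' @return A list of class `tht_cv_summary` with `mean_cv`, `summary` (data
#'   frame: `record`, `n_taps`, `cv`, `defined`) and `n_excluded`.
#' @examples
#' mean_intertap_cv(list(a = c(0, 500, 1000), b = c(0, 400, 1000)))
#' @export
mean_intertap_cv <- function(records, max_iti = 3000,
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!is.list(records) || !length(records))
    stop("`records` must be a non-empty list of tap-time vectors",
         call. = FALSE)
  nm <- names(records)
  if (is.null(nm)) nm <- as.character(seq_along(records))
  cv <- vapply(records, function(r) {
    tryCatch(intertap_cv(r, max_iti, sd_type), error = function(e) NA_real_)
  }, numeric(1))
  summary <- data.frame(record = nm,
                        n_taps = vapply(records, length, 0L),
                        cv = cv, defined = !is.na(cv))
  rownames(summary) <- NULL
  if (!any(summary$defined))
    stop("no record has a defined CV after filtering", call. = FALSE)
  structure(list(mean_cv = mean(cv, na.rm = TRUE), summary = summary,
                 n_excluded = sum(!summary$defined)),
            class = "tht_cv_summary")
}

#' @export
print.tht_cv_summary <- function(x, ...) {
  cat(sprintf("<tht_cv_summary> mean CV %.4f over %d record(s)",
              x$mean_cv, sum(x$summary$defined)))
  if (x$n_excluded)
    cat(sprintf(" (%d excluded: CV undefined)", x$n_excluded))
  cat("\n")
  invisible(x)
}
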