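# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: explicit loops, no windowing shortcuts, stats::lm for
# regression — so they share no code path with the package internals.

# brute-force congruency: enumerate a generous k range, filter, match each
# beat by scanning all windowed onsets
oracle_congruency <- function(phase, period, onsets, now,
                              cfg = tht_config()) {
  tol <- cfg$projection_tol
  lo <- max(onsets[1], now - cfg$context_window)
  hi <- now
  win <- onsets[onsets >= lo - tol & onsets <= hi + tol]
  ks <- seq(floor((lo - phase) / period) - 3,
            ceiling((hi - phase) / period) + 3)
  p <- phase + ks * period
  p <- p[p >= lo - tol & p <= hi + tol]
  if (length(p) == 0) return(0)
  hits <- 0
  for (pp in p) {
    d <- abs(pp - win)
    hits <- hits + cfg$concurrence_base^(min(d) / period)
  }
  min(max((hits / length(p)) * (hits / length(win)), 0), 1)
}

# correction via explicit matching and stats::lm
oracle_correction <- function(phase, period, onsets, now,
                              cfg = tht_config()) {
  tol <- cfg$projection_tol
  lo <- max(onsets[1], now - cfg$context_window)
  hi <- now
  win <- onsets[onsets >= lo - tol & onsets <= hi + tol]
  ks <- seq(floor((lo - phase) / period) - 3,
            ceiling((hi - phase) / period) + 3)
  p <- phase + ks * period
  keep <- p >= lo - tol & p <= hi + tol
  ks <- ks[keep]
  p <- p[keep]
  if (length(p) < 2 || length(win) == 0)
    return(c(delta_phase = 0, delta_period = 0))
  r <- vapply(p, function(pp) {
    d <- abs(pp - win)
    win[which(d == min(d))[1]]          # earliest onset on ties
  }, numeric(1))
  ce <- cfg$corr_multiplier * (r - p) *
    cfg$corr_decay^(abs(p - r) / period)
  fit <- stats::lm(ce ~ ks)
  c(delta_phase = unname(coef(fit)[1]), delta_period = unname(coef(fit)[2]))
}

# random small test instance: onsets and a hypothesis whose projection
# overlaps them
random_instance <- function() {
  n <- sample(3:12, 1)
  onsets <- sort(stats::runif(n, 0, 4000))
  while (any(diff(onsets) < 1))
    onsets <- sort(stats::runif(n, 0, 4000))
  list(onsets = onsets,
       phase = stats::runif(1, 0, 2000),
       period = stats::runif(1, 187, 1500),
       now = onsets[n])
}

table1_onsets <- function(k_max = 4) 1.04167 + 500 * (0:k_max)
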