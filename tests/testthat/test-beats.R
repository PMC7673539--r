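test_that("the naive track on an isochronous pulse lands on the onsets", {
  res <- tht_track(stim_isochronous(12, 500))
  b <- extract_beats_naive(res)
  dist <- vapply(b, function(x) min(abs(x - res$onsets)), numeric(1))
  expect_lt(max(dist), 1)
  # covers every processed onset, one beat each
  expect_equal(length(b), 11)
})

test_that("a constant top hypothesis emits exactly its own projection", {
  res <- tht_track(stim_isochronous(9, 600))
  b <- extract_beats_naive(res)
  tl <- top_hypothesis_timeline(res)
  proj <- project_beats(tht_hypothesis(tl$phase[1], tl$period[1]),
                        tl$onset_time[1], tl$onset_time[nrow(tl)])
  expect_equal(unclass(b), proj$time, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("both extraction modes emit strictly increasing in-passage beats
           on all scripted stimuli", {
  fixtures <- list(stim_period_change(), stim_phase_change(),
                   stim_rallentando(), stim_mixed_patterns())
  for (on in fixtures) {
    res <- tht_track(on)
    for (b in list(extract_beats_naive(res), extract_beats_adapted(res))) {
      expect_true(all(diff(b) > 0))
      expect_gte(min(b), min(on))
      expect_lte(max(b), max(on) + 1e-6)
    }
  }
})

test_that("the adapted track never beats faster than the tapping floor", {
  fixtures <- list(stim_period_change(), stim_phase_change(),
                   stim_rallentando(), stim_mixed_patterns(),
                   stim_isochronous(30, 250))
  for (on in fixtures) {
    res <- tht_track(on)
    expect_gt(min(diff(extract_beats_adapted(res))), 375)
  }
})

test_that("a fast pulse is emitted at its doubled, tap-range period", {
  # top hypothesis period 250 -> emitted inter-beat interval 500
  res <- tht_track(stim_isochronous(30, 250))
  expect_equal(tail(top_hypothesis_timeline(res)$period, 1), 250)
  ibi <- diff(extract_beats_adapted(res))
  expect_equal(unique(round(ibi)), 500)
  # a 500 ms pulse is already in range and stays unchanged
  res2 <- tht_track(stim_isochronous(12, 500))
  expect_equal(unique(round(diff(extract_beats_adapted(res2)))), 500)
})

test_that("on the period-change passage the naive track follows the fast
           pulse and the adapted track keeps the tap rate", {
  res <- tht_track(stim_period_change())
  expect_equal(tail(diff(extract_beats_naive(res)), 1), 250, tolerance = 0.01)
  expect_equal(tail(diff(extract_beats_adapted(res)), 1), 500,
               tolerance = 0.01)
})

test_that("hysteresis: a challenger leading for under 3000 ms is never
           adopted, and adaptation never switches more than naive", {
  # 500 ms grid with a 2000 ms burst of 250 ms subdivision, then back
  on <- c(seq(0, 6000, by = 500), seq(6250, 8000, by = 250),
          seq(8500, 14000, by = 500))
  res <- tht_track(on)
  ba <- extract_beats_adapted(res)
  expect_equal(unique(attr(ba, "segments")$tracker), "0-1")

  for (stim in list(on, stim_period_change(), stim_phase_change())) {
    r <- tht_track(stim)
    switches <- function(x) {
      s <- attr(x, "segments")$tracker
      sum(s != c(s[1], s[-length(s)]))
    }
    expect_lte(switches(extract_beats_adapted(r)),
               switches(extract_beats_naive(r)))
  }
})

test_that("a challenger leading beyond the lag is adopted with a
           continuous, tap-range beat", {
  res <- tht_track(stim_period_change(n2 = 40))
  ba <- extract_beats_adapted(res)
  seg <- attr(ba, "segments")
  expect_equal(unique(seg$tracker), c("0-1", "11-12"))
  expect_gt(min(diff(ba)), 375)
  # adoption only after the challenger has led for > 3000 ms
  tab <- tht_table(res)
  m <- merge(tab[tab$a == 11 & tab$b == 12, c("onset_index", "score")],
             tab[tab$a == 0 & tab$b == 1, c("onset_index", "score")],
             by = "onset_index")
  first_lead <- min(m$onset_index[m$score.x > m$score.y])
  t_lead <- res$onsets[first_lead + 1]
  t_adopt <- res$onsets[seg$onset_index[match("11-12", seg$tracker)] + 1]
  expect_gt(t_adopt - t_lead, 3000)
})
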