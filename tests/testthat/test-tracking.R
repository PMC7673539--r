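test_that("hypothesis generation pairs the current onset with every prior
           onset within the period bounds", {
  g <- generate_hypotheses(c(0, 500, 1000), t = 2)
  expect_equal(g$a, c(0, 1))
  expect_equal(g$b, c(2, 2))
  expect_equal(g$phase, c(0, 500))
  expect_equal(g$period, c(1000, 500))

  expect_equal(nrow(generate_hypotheses(c(0, 100), t = 1)), 0)   # too fast
  expect_equal(nrow(generate_hypotheses(c(0, 1600), t = 1)), 0)  # too slow
  expect_equal(nrow(generate_hypotheses(c(0, 187), t = 1)), 1)   # boundary
  expect_equal(nrow(generate_hypotheses(c(0, 1500), t = 1)), 1)
})

test_that("similarity requires close periods and the same relative phase", {
  expect_true(is_similar(tht_hypothesis(100, 500), tht_hypothesis(100, 500)))
  expect_false(is_similar(tht_hypothesis(0, 500), tht_hypothesis(0, 1000)))
  expect_true(is_similar(tht_hypothesis(0, 500), tht_hypothesis(1, 503)))
  # same period, opposite phase: a distinct (counter-phase) pulse
  expect_false(is_similar(tht_hypothesis(0, 500), tht_hypothesis(250, 500)))
  # phase congruence is circular: offsets by whole periods are identical
  expect_true(is_similar(tht_hypothesis(0, 500), tht_hypothesis(2000, 500)))
})

test_that("tracking the reconstructed worked example reproduces the
           published tracker states", {
  res <- tht_track(table1_onsets(4))
  tab <- tht_table(res)
  h01 <- tab[tab$a == 0 & tab$b == 1, ]
  expect_equal(h01$onset_index, 1:4)
  expect_equal(h01$score, rep(1, 4))
  expect_equal(h01$period, rep(500, 4))
  expect_equal(h01$phase, rep(1.04167, 4))
  h02 <- tab[tab$a == 0 & tab$b == 2, ]
  expect_equal(h02$onset_index, 2:4)
  expect_equal(signif(h02$score, 6), c(0.666667, 0.5, 0.6))
  expect_equal(h02$period, rep(1000, 3))
})

test_that("a two-onset passage yields a single tracker with one perfect
           state", {
  res <- tht_track(c(0, 500))
  expect_length(res$trackers, 1)
  tr <- res$trackers[[1]]
  expect_equal(tr$a, 0)
  expect_equal(tr$b, 1)
  expect_equal(tr$score_hist, 1)
})

test_that("inputs with no admissible inter-onset interval raise a
           no-trackable-pulse error", {
  expect_error(tht_track(c(0, 100)), "no trackable pulse")
  expect_error(tht_track(c(0, 1600, 3200)), "no trackable pulse")
  expect_error(tht_track(1000), "at least 2")
})

test_that("collapse keeps the tracker population sub-quadratic and never
           displaces the founding tracker on an isochronous pulse", {
  on <- stim_isochronous(20, 600)
  res <- tht_track(on)
  n_states <- sum(vapply(res$trackers, function(tr) length(tr$score_hist),
                         numeric(1)))
  expect_lt(length(res$trackers), 20)          # vs ~190 unchecked pairs
  tl <- top_hypothesis_timeline(res)
  expect_true(all(tl$a == 0 & tl$b == 1))
  expect_true(all(tl$score == 1))
  expect_gte(min(n_states), nrow(tl))
})

test_that("surviving trackers are pairwise dissimilar and their histories
           are contiguous and bounded", {
  for (on in list(stim_period_change(6, 500, 8, 250),
                  stim_mixed_patterns(list(c(500), c(250, 250, 500)), 3))) {
    res <- tht_track(on)
    trs <- res$trackers
    for (tr in trs) {
      expect_equal(tr$onset_index, seq(tr$onset_index[1],
                                       tr$onset_index[length(tr$onset_index)]))
      expect_true(all(tr$score_hist >= 0 & tr$score_hist <= 1))
      expect_lt(tr$a, tr$b)
    }
    if (length(trs) > 1) {
      for (i in seq_along(trs)[-1]) {
        for (j in seq_len(i - 1)) {
          expect_false(is_similar(
            tht_hypothesis(trs[[i]]$phase, trs[[i]]$period),
            tht_hypothesis(trs[[j]]$phase, trs[[j]]$period),
            res$config))
        }
      }
    }
  }
})

test_that("tracking is causal: a truncated input reproduces the prefix of
           every surviving history", {
  on <- jitter_onsets(stim_isochronous(16, 450, phase = 20), 9, seed = 5)
  full <- tht_track(on)
  for (t in c(6, 10, 13)) {
    part <- tht_track(on[1:t])
    for (id in names(part$trackers)) {
      if (!id %in% names(full$trackers)) next
      a <- part$trackers[[id]]
      b <- full$trackers[[id]]
      k <- length(a$score_hist)
      expect_identical(a$onset_index, b$onset_index[1:k])
      expect_identical(a$score_hist, b$score_hist[1:k])
      expect_identical(a$phase_hist, b$phase_hist[1:k])
      expect_identical(a$period_hist, b$period_hist[1:k])
    }
    k <- nrow(part$timeline)
    expect_equal(part$timeline, full$timeline[1:k, ],
                 ignore_attr = "row.names")
  }
})

test_that("a gentle tempo drift is absorbed by correction: one tracker
           holds the top while its period glides", {
  # the corrected-error pull range is about period/ln(1/d) ~ 5% of the
  # period, so a drift well inside it (0.5% per onset) is followed
  on <- stim_rallentando(30, 400, 1.005)
  cc <- clarity_curve(tht_track(on))
  settled <- cc[cc$onset_time > 2000, ]
  expect_equal(length(unique(settled$tracker)), 1)
  expect_gt(min(settled$score), 0.5)
  tl <- top_hypothesis_timeline(tht_track(on))
  expect_gt(tl$period[nrow(tl)], tl$period[5])   # period glides upward
})

test_that("tracking is deterministic", {
  on <- stim_mixed_patterns(list(c(500), c(375, 375, 250)), 3)
  r1 <- tht_track(on)
  r2 <- tht_track(on)
  expect_identical(r1$timeline, r2$timeline)
  expect_identical(r1$trackers, r2$trackers)
})
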