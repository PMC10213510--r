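test_that("altered gap arithmetic follows T(1 -/+ delta)", {
  male <- sentence_template("male")
  female <- sentence_template("female")
  expect_equal(male$gap_ms, 1661)
  expect_equal(female$gap_ms, 1603)
  # a 100% decrease leaves no gap at all
  expect_equal(altered_gap_ms(male, "early", 1), 0)
  expect_equal(altered_gap_ms(male, "late", 0), 1661)
  expect_equal(altered_gap_ms(female, "late", 0.5), 2404.5)
  expect_error(altered_gap_ms(male, "early", 1.2), "outside")
  expect_error(altered_gap_ms(male, "late", 2.1), "outside")
  expect_error(altered_gap_ms(male, "late", -0.1), "outside")
})

test_that("trial randomization has the declared distributions", {
  tpl <- sentence_template("male")
  set.seed(101)
  trials <- replicate(10000, {
    tr <- make_trial(tpl, "low_rate", "early", 0.5)
    c(tr$altered_position, tr$isi_ms, tr$modulator_phase)
  })
  # altered comparison first on half the trials
  expect_lt(abs(mean(trials[1, ] == 1) - 0.5), 0.015)
  # ISI jitter confined to 400-800 ms and spanning it
  expect_gte(min(trials[2:3, ]), 400)
  expect_lte(max(trials[2:3, ]), 800)
  expect_lt(min(trials[2:3, ]), 420)
  expect_gt(max(trials[2:3, ]), 780)
  # phases drawn from the eight allowed values only
  expect_true(all(trials[4, ] %in% modulator_phases()))
  expect_equal(sort(unique(trials[4, ])), modulator_phases())
})

test_that("unaltered trials carry an identity warp schedule", {
  set.seed(1)
  tr <- make_trial(sentence_template("male"), "unaltered", "late", 0.3)
  expect_equal(tr$schedule$new_durations_ms,
               rep(50, tr$schedule$n_frames))
})

test_that("rendered comparisons differ by exactly the gap deviation", {
  tpl <- sentence_template("male", early_ms = 500, final_word_ms = 200)
  sr <- 16000
  set.seed(2)
  tr <- make_trial(tpl, "high_rate", "early", 0.4)
  aud <- render_trial_audio(tr, tpl, sr)
  correct <- if (aud$altered_position == 1) aud$comparison2 else aud$comparison1
  altered <- if (aud$altered_position == 1) aud$comparison1 else aud$comparison2
  expect_lte(abs((length(correct) - length(altered)) -
                   round(1661 * 0.4 * sr / 1000)), 1)
  # zero deviation: both comparisons have identical duration
  tr0 <- make_trial(tpl, "unaltered", "early", 0)
  aud0 <- render_trial_audio(tr0, tpl, sr)
  expect_equal(length(aud0$comparison1), length(aud0$comparison2))
})

test_that("a lengthened gap renders at T(1 + delta) to one sample", {
  tpl <- sentence_template("male", early_ms = 500, final_word_ms = 200)
  sr <- 16000
  set.seed(3)
  tr <- make_trial(tpl, "unaltered", "late", 0.2)
  aud <- render_trial_audio(tr, tpl, sr)
  altered <- if (aud$altered_position == 1) aud$comparison1 else aud$comparison2
  early_n <- length(warp_waveform(am_noise_word(500, sr), sr, tr$schedule))
  gap_n <- length(altered) - early_n - round(200 * sr / 1000)
  expect_lte(abs(gap_n - round(1661 * 1.2 * sr / 1000)), 1)
})

test_that("reference and comparisons share one warp schedule within a trial", {
  tpl <- sentence_template("female", early_ms = 600, final_word_ms = 150)
  set.seed(4)
  tr <- make_trial(tpl, "low_rate", "late", 0.5)
  aud <- render_trial_audio(tr, tpl, 16000)
  warped_n <- length(warp_waveform(am_noise_word(600, 16000), 16000, tr$schedule))
  # all three intervals start with the same warped early-region length
  final_n <- round(150 * 16)
  expect_equal(length(aud$reference),
               warped_n + round(tpl$gap_ms * 16) + final_n)
  expect_setequal(c(length(aud$comparison1), length(aud$comparison2)),
                  c(warped_n + round(tpl$gap_ms * 16) + final_n,
                    warped_n + round(tpl$gap_ms * 1.5 * 16) + final_n))
})

test_that("synth duration mismatches are caught", {
  tpl <- sentence_template("male", early_ms = 500)
  set.seed(5)
  tr <- make_trial(tpl, "unaltered", "early", 0.2)
  bad_synth <- function(dur_ms, sr) numeric(100)
  expect_error(render_trial_audio(tr, tpl, 16000, synth = bad_synth),
               "expected")
})

test_that("blocks hold equal shuffled numbers of early and late trials", {
  set.seed(6)
  for (i in 1:50) {
    ord <- block_trial_order(40)
    expect_equal(unname(table(ord)["early"]), 20L)
    expect_equal(unname(table(ord)["late"]), 20L)
  }
  # order is genuinely shuffled, not blocked
  firsts <- replicate(200, block_trial_order(40)[1])
  expect_true(all(c("early", "late") %in% firsts))
})
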