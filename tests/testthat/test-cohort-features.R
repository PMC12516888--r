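sig_df <- function(signal, times, values = seq_along(times)) {
  data.frame(stay_id = "s1", signal = signal, time_h = times, value = values,
             stringsAsFactors = FALSE)
}

test_that("MV onset is the first PEEP sample; absent PEEP signals no MV", {
  expect_equal(mv_onset(sig_df("peep", c(5, 6))), 5)
  expect_equal(mv_onset(sig_df("peep", 0)), 0)
  expect_true(is.na(mv_onset(sig_df("heart_rate", c(1, 2)))))
})

test_that("cohort criteria exclude by age, early death and short ventilation", {
  stays <- data.frame(
    stay_id = c("a", "b", "c", "d", "e"),
    age = c(17, 70, 70, 70, NA),
    death_h = c(NA, 20, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  signals <- rbind(
    data.frame(stay_id = "a", signal = "peep", time_h = c(0, 48), value = 5),
    data.frame(stay_id = "b", signal = "peep", time_h = c(0, 48), value = 5),
    data.frame(stay_id = "c", signal = "peep", time_h = c(0, 23), value = 5),
    data.frame(stay_id = "d", signal = "peep", time_h = c(0, 30), value = 5),
    data.frame(stay_id = "e", signal = "peep", time_h = c(0, 30), value = 5)
  )
  out <- apply_cohort_criteria(stays, signals)
  disp <- setNames(out$disposition$status, out$disposition$stay_id)
  expect_identical(unname(disp[c("a", "b", "c", "d", "e")]),
                   c("excluded_age", "excluded_early_death",
                     "excluded_short_mv", "included", "unevaluable"))
  # the counts partition the input
  expect_equal(with(out$counts, unevaluable + excluded_no_mv + excluded_age +
                      excluded_early_death + excluded_short_mv + included),
               out$counts$total)
  expect_identical(out$included, "d")
})

test_that("window aggregation: hand arithmetic, empty and singleton cases", {
  agg <- aggregate_window(c(1, 2, 3), c(1, 2, 3), start = 0)
  expect_equal(unname(agg[c("mean", "median", "min", "max")]), c(2, 2, 1, 3))
  expect_equal(unname(agg["sd"]), 1)

  empty <- aggregate_window(numeric(0), numeric(0), start = 0)
  expect_true(all(is.na(empty)))

  one <- aggregate_window(5, 7, start = 0)
  expect_equal(unname(one[c("mean", "median", "min", "max")]), rep(7, 4))
  expect_true(is.na(one["sd"]))
})

test_that("samples outside the window never change aggregates", {
  t_in <- c(2, 10, 20)
  v_in <- c(4, 6, 8)
  base <- aggregate_window(t_in, v_in, start = 0)
  shifted <- aggregate_window(c(t_in, 25, 30, -1), c(v_in, 100, 200, 300),
                              start = 0)
  expect_equal(base, shifted)
})

test_that("ARDS flag honours the sustained-span rule and closed thresholds", {
  pf_low <- data.frame(time_h = 0, value = 250)
  peep_hi <- data.frame(time_h = 0, value = 8)
  # condition holds the whole window
  expect_equal(ards_flag(pf_low, peep_hi, start = 0), 1)
  # condition holds 7.5 h then breaks
  pf_break <- data.frame(time_h = c(0, 7.5), value = c(250, 400))
  expect_equal(ards_flag(pf_break, peep_hi, start = 0), 0)
  # exactly 8 h qualifies (closed span convention)
  pf_eight <- data.frame(time_h = c(0, 8), value = c(250, 400))
  expect_equal(ards_flag(pf_eight, peep_hi, start = 0), 1)
  # joint condition: low ratio alone is not enough
  peep_lo <- data.frame(time_h = 0, value = 4)
  expect_equal(ards_flag(pf_low, peep_lo, start = 0), 0)
  # boundary values qualify: ratio exactly 300, PEEP exactly 5
  expect_equal(ards_flag(data.frame(time_h = 0, value = 300),
                         data.frame(time_h = 0, value = 5), start = 0), 1)
  # missing series give a missing flag
  expect_true(is.na(ards_flag(pf_low[0, ], peep_hi, start = 0)))
})

test_that("extending a qualifying span never turns the flag off", {
  peep <- data.frame(time_h = 0, value = 8)
  for (len in c(8, 10, 15, 24)) {
    pf <- data.frame(time_h = c(0, len), value = c(250, 400))
    expect_equal(ards_flag(pf, peep, start = 0), 1)
  }
})

test_that("ARDS flag agrees with the fine-grid oracle on random step series", {
  set.seed(42)
  for (i in 1:150) {
    pf <- random_step_series(sample(1:8, 1), 150, 450)
    peep <- random_step_series(sample(1:8, 1), 2, 12)
    got <- ards_flag(pf, peep, start = 0)
    want <- ards_oracle(pf, peep, start = 0)
    expect_equal(got, want, info = sprintf("series %d", i))
  }
})

test_that("organ dysfunction flag is a strict disjunction over available inputs", {
  expect_equal(organ_dysfunction_flag(90, 1.0, 1.0), 1)
  expect_equal(organ_dysfunction_flag(100, 2.0, 1.5), 0)  # strict inequalities
  expect_equal(organ_dysfunction_flag(NA, 3.0, NA), 1)
  expect_equal(organ_dysfunction_flag(150, NA, NA), 0)
  expect_true(is.na(organ_dysfunction_flag(NA, NA, NA)))
})

test_that("race-free CKD-EPI eGFR matches the closed form and is monotone", {
  # independent evaluation: female, Scr 0.7 mg/dL (= kappa), age 40
  expect_equal(egfr_ckdepi(0.7, 40, "female"),
               142 * 0.9938^40 * 1.012, tolerance = 1e-12)
  expect_equal(egfr_ckdepi(0.7, 40, "female"), 112.06, tolerance = 0.01)
  # doubling creatinine strictly lowers eGFR
  expect_lt(egfr_ckdepi(1.8, 60, "male"), egfr_ckdepi(0.9, 60, "male"))
  # older age strictly lowers eGFR
  expect_lt(egfr_ckdepi(0.9, 80, "male"), egfr_ckdepi(0.9, 40, "male"))
  # umol/L mode matches the converted mg/dL value
  expect_equal(egfr_ckdepi(0.7 * 88.42, 40, "female", units = "umol_l"),
               egfr_ckdepi(0.7, 40, "female"), tolerance = 1e-9)
  expect_error(egfr_ckdepi(0, 40, "female"), "positive")
})

test_that("BMI bins are left-closed at the WHO cutpoints", {
  expect_identical(bmi_category(c(15, 22, 27, 32, 37, 41)),
                   c(0L, 1L, 2L, 3L, 4L, 5L))
  expect_identical(bmi_category(c(18.5, 25, 30, 35, 40)),
                   c(1L, 2L, 3L, 4L, 5L))
  expect_error(bmi_category(-1), "positive")
})

test_that("outcome label is death in ICU within seven days of MV onset", {
  expect_equal(outcome_label(6 * 24 + 2, discharge_h = 400, mv_onset_h = 2), 1)
  expect_equal(outcome_label(8 * 24 + 2, discharge_h = 400, mv_onset_h = 2), 0)
  expect_equal(outcome_label(NA, discharge_h = 200, mv_onset_h = 2), 0)
})

test_that("feature table assembly from planted time series is faithful", {
  ts <- simulate_timeseries(n_stays = 6, ards_span_h = c(9, 7, 0),
                            seed = 21)
  ft <- build_feature_table(ts$stays, ts$signals)
  expect_s3_class(ft, "feature_table")
  expect_equal(ft$consort$included, length(ft$stay_ids))
  expect_false(anyDuplicated(names(ft$features)) > 0)
  # planted ARDS truth is recovered per stay
  truth <- ts$truth$ards_expected[match(ft$stay_ids, ts$truth$stay_id)]
  expect_equal(unname(ft$features$ards_flag), truth)
  # aggregation of a planted constant signal returns the constant
  const <- ts$signals[ts$signals$stay_id == ft$stay_ids[1] &
                        ts$signals$signal == "peep", ]
  if (length(unique(const$value)) == 1L) {
    expect_equal(ft$features$peep_mean[1], const$value[1])
  }
  # manifest covers every column
  expect_setequal(ft$manifest$column, names(ft$features))
})
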