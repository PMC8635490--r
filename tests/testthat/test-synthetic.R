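test_that("stimulus follows the onset-apex-offset ramp profile", {
  tpl <- expression_template("anger", au_peaks = c(AU4 = 4))
  s <- generate_stimulus_series(tpl)
  expect_equal(nrow(s), 150)
  expect_true(all(s[31:120, "AU4"] == 4))            # full apex at peak
  other <- setdiff(au_channels(), "AU4")
  expect_true(all(s[, other] == 0))
  expect_equal(unname(s[150, "AU4"]), 0)             # decays back to neutral

  # all-zero peaks give an all-zero series
  z <- generate_stimulus_series(
    expression_template("anger", au_peaks = c(AU4 = 0)))
  expect_true(all(z == 0))
})

test_that("onset ramp values match an independently coded ramp", {
  ramp_oracle <- function(peak, i, onset) floor(peak * i / onset + 0.5)
  tpl <- expression_template("anger", au_peaks = c(AU4 = 4))
  s <- generate_stimulus_series(tpl)
  for (i in 1:30) {
    expect_equal(unname(s[i, "AU4"]), ramp_oracle(4, i, 30))
  }
  expect_equal(unname(s[15, "AU4"]), 2)  # round(4 * 15/30)
})

test_that("templates validate their frame partition and peaks", {
  expect_error(expression_template("anger", onset_frames = 40), "total")
  expect_error(expression_template("anger", au_peaks = c(AU4 = 9)), "0, 5")
  expect_error(expression_template("anger", au_peaks = c(XX = 2)), "named")
})

test_that("schedules never repeat an emotion back to back and stay balanced", {
  cfg <- cohort_config(n_participants = 6, group_sizes = c(2, 2, 2))
  sch <- generate_schedule(cfg, seed = 31)
  key <- interaction(sch$participant_id, sch$phase, sch$embodiment)
  for (blk in split(sch, key)) {
    blk <- blk[order(blk$position), ]
    expect_false(any(blk$emotion[-1] == blk$emotion[-12]))
    expect_equal(sort(table(blk$emotion)), sort(table(rep(emotions(), 2))),
                 ignore_attr = TRUE)
    expect_equal(sort(blk$trial), rep(1:2, each = 6), ignore_attr = TRUE)
  }
  expect_identical(generate_schedule(cfg, seed = 31), sch)
  expect_false(identical(generate_schedule(cfg, seed = 32), sch))
})

test_that("null spontaneous response is silence; injections are subtle", {
  stim <- generate_stimulus_series(expression_template("happiness"))
  off <- response_params(p_mimic_rfr = 0, p_mimic_cfr = 0,
                         baseline_flicker_rate = 0)
  expect_true(all(generate_spontaneous_response(stim, off, seed = 1) == 0))

  on <- response_params(p_mimic_rfr = 1, p_mimic_cfr = 1,
                        baseline_flicker_rate = 0)
  for (seed in 1:25) {
    r <- generate_spontaneous_response(stim, on, seed = seed)
    expect_lte(max(r), 2)   # low-intensity regime: peaks in [1, 2]
    expect_gte(max(r), 1)
  }
})

test_that("guaranteed CFR injections are always detected downstream", {
  stim <- generate_stimulus_series(expression_template("sadness"))
  on <- response_params(p_mimic_rfr = 0, p_mimic_cfr = 1,
                        baseline_flicker_rate = 0)
  hits <- vapply(1:50, function(seed) {
    r <- generate_spontaneous_response(stim, on, seed = seed)
    detect_mimicry(r, "sadness")$cfr
  }, logical(1))
  expect_true(all(hits))
})

test_that("perfect-fidelity instructed response reproduces the stimulus", {
  stim <- generate_stimulus_series(expression_template("fear"))
  exact <- response_params(instructed_lag_frames = c(0, 0),
                           instructed_gain_sd = 0, instructed_noise_sd = 0)
  r <- generate_instructed_response(stim, exact, seed = 5)
  expect_equal(unclass(r), unclass(stim), ignore_attr = TRUE)
  cq <- crqa(r, stim, emotion = "fear")
  expect_equal(cq$l_max, 150)          # unbroken main diagonal
  expect_false(cq$empty)
})

test_that("a pure lag offsets the longest diagonal by the lag", {
  stim <- generate_stimulus_series(expression_template("fear"))
  lagged <- response_params(instructed_lag_frames = c(8, 8),
                            instructed_gain_sd = 0, instructed_noise_sd = 0)
  r <- generate_instructed_response(stim, lagged, seed = 5)
  chans <- unique(unlist(emotion_patterns()$fear))
  crp <- cross_recurrence_matrix(unclass(r)[, chans],
                                 unclass(stim)[, chans])
  # oracle scan: per-offset longest run
  best_len <- 0L; best_off <- NA_integer_
  for (k in -(nrow(crp) - 1):(ncol(crp) - 1)) {
    i <- seq(max(1, 1 - k), min(nrow(crp), ncol(crp) - k))
    run <- rle(crp[cbind(i, i + k)] == 1L)
    m <- if (any(run$values)) max(run$lengths[run$values]) else 0L
    if (m > best_len) { best_len <- m; best_off <- k }
  }
  expect_equal(best_off, -8L)
  expect_equal(best_len, 150L - 8L)
})

test_that("mean cRR decreases monotonically with copy noise", {
  stim <- generate_stimulus_series(expression_template("happiness"))
  mean_crr <- vapply(c(0, 0.5, 1.5), function(ns) {
    p <- response_params(instructed_lag_frames = c(0, 0),
                         instructed_gain_sd = 0, instructed_noise_sd = ns)
    mean(vapply(1:40, function(seed) {
      crqa(generate_instructed_response(stim, p, seed = seed), stim,
           emotion = "happiness")$crr
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_crr) < 0))
})

test_that("default cohort matches the study design counts", {
  cfg <- cohort_config()
  expect_equal(cfg$n_participants, 45)
  co <- generate_cohort(cfg, seed = 41)
  expect_equal(nrow(co$participants), 45)
  cnt <- table(co$manifest$participant_id, co$manifest$phase)
  expect_true(all(cnt == 48))   # 12 snippets x 4 embodiments per phase
  blk <- subset(co$manifest, participant_id == "P07" &
                  phase == "spontaneous" & embodiment == "virtual")
  expect_equal(sort(table(blk$emotion)), sort(table(rep(emotions(), 2))),
               ignore_attr = TRUE)
})

test_that("occlusion flags follow the configured rate", {
  cfg <- cohort_config(n_participants = 45,
                       embodiments = c("virtual", "physical", "video_robot"),
                       phases = "spontaneous")
  p0 <- response_params(p_occlusion = 0)
  co0 <- generate_cohort(cfg, p0, qmodel = NULL, seed = 42)
  expect_equal(sum(co0$manifest$occluded), 0)

  p2 <- response_params(p_occlusion = 0.2)
  co2 <- generate_cohort(cfg, p2, qmodel = NULL, seed = 42)
  n <- nrow(co2$manifest)
  mc_sd <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(mean(co2$manifest$occluded) - 0.2), 3 * mc_sd)
})

test_that("cohorts are deterministic and file output is byte-identical", {
  cfg <- cohort_config(n_participants = 3, group_sizes = c(1, 1, 1))
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_equal(a, b)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("ground truth seeds reconstruct each response series exactly", {
  cfg <- cohort_config(n_participants = 3, group_sizes = c(1, 1, 1))
  co <- generate_cohort(cfg, seed = 13)
  man <- co$manifest
  for (s in sample(nrow(man), 12)) {
    stim <- co$stimuli[[man$emotion[s]]]
    if (man$phase[s] == "instructed") {
      r <- generate_instructed_response(stim, co$params,
                                        seed = man$snippet_seed[s])
      r <- aumimic:::pad_buffers(r, 30L)
    } else {
      u <- co$participants$propensity[
        match(man$participant_id[s], co$participants$participant_id)]
      pp <- co$params
      pp$p_mimic_rfr <- aumimic:::clip01(
        aumimic:::resolve_param(co$params$p_mimic_rfr, man$embodiment[s]) + u)
      pp$p_mimic_cfr <- aumimic:::clip01(
        aumimic:::resolve_param(co$params$p_mimic_cfr, man$embodiment[s]) + u)
      r <- generate_spontaneous_response(stim, pp,
                                         seed = man$snippet_seed[s])
    }
    expect_equal(unclass(r), unclass(co$snippets[[s]]), ignore_attr = TRUE)
  }
})

test_that("written cohorts read back into a working pipeline", {
  cfg <- cohort_config(n_participants = 3, group_sizes = c(1, 1, 1))
  co <- generate_cohort(cfg, seed = 17)
  d <- file.path(tempdir(), "coh_rt")
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(length(back$snippets), length(co$snippets))
  i <- 5L
  expect_equal(unclass(back$snippets[[i]]), unclass(co$snippets[[i]]),
               ignore_attr = TRUE)
  sp1 <- spontaneous_outcomes(co)
  sp2 <- spontaneous_outcomes(back)
  expect_equal(sp2$rates$rate, sp1$rates$rate)
  unlink(d, recursive = TRUE)
})
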