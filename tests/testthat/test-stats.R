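# balanced toy cohort table: 9 participants (3 per group) x 3 embodiments
toy_table <- function(seed = 1, effect = 0) {
  set.seed(seed)
  d <- expand.grid(participant_id = sprintf("P%d", 1:9),
                   embodiment = c("virtual", "physical", "video_robot"),
                   stringsAsFactors = FALSE)
  d$group <- rep(c("characterlike", "humanlike", "morph"), 3)[
    match(d$participant_id, sprintf("P%d", 1:9))]
  d$y <- round(rnorm(nrow(d), 0.6, 0.15), 3) +
    effect * (d$embodiment == "virtual")
  d
}

test_that("mixed 3x3 ANOVA agrees with the balanced-design SS oracle", {
  for (seed in c(1, 2, 3)) {
    tab <- toy_table(seed, effect = if (seed == 3) 0.3 else 0)
    got <- mixed_anova_3x3(tab, "y")
    want <- oracle_mixed_anova(
      data.frame(s = tab$participant_id, g = tab$group,
                 w = tab$embodiment, y = tab$y))
    for (eff in c("between", "within", "interaction")) {
      g <- got[got$effect == eff, ]
      w <- want[[eff]]
      expect_equal(g$F, w$F, tolerance = 1e-10)
      expect_equal(g$df1, w$df1)
      expect_equal(g$df2, w$df2)
      expect_equal(g$p, w$p, tolerance = 1e-10)
      expect_equal(g$partial_eta_sq, w$pes, tolerance = 1e-10)
    }
  }
})

test_that("F statistics are invariant to adding a constant", {
  tab <- toy_table(4)
  a <- mixed_anova_3x3(tab, "y")
  tab$y <- tab$y + 5
  b <- mixed_anova_3x3(tab, "y")
  expect_equal(a$F, b$F)
  expect_equal(a$p, b$p)
})

test_that("mixed ANOVA drops incomplete participants and refuses tiny groups", {
  tab <- toy_table(5)
  tab <- tab[!(tab$participant_id == "P1" & tab$embodiment == "virtual"), ]
  full <- mixed_anova_3x3(tab, "y")
  expect_equal(full[full$effect == "between", "df2"], 5)  # 8 subjects - 3

  tiny <- toy_table(6)
  tiny <- tiny[tiny$participant_id %in% c("P1", "P2", "P3", "P4"), ]
  expect_error(mixed_anova_3x3(tiny, "y"), "at least 2")
})

test_that("artificiality ANOVA collapses the three artificial embodiments", {
  d <- expand.grid(participant_id = sprintf("P%d", 1:6),
                   embodiment = c("virtual", "physical", "video_robot",
                                  "video_human"),
                   stringsAsFactors = FALSE)
  d$group <- rep(c("characterlike", "humanlike", "morph"), each = 2)[
    match(d$participant_id, sprintf("P%d", 1:6))]
  set.seed(9)
  d$y <- rnorm(nrow(d), 0.5, 0.1)
  d$y[d$participant_id == "P1" & d$embodiment != "video_human"] <-
    c(0.5, 0.6, 0.7)
  got <- mixed_anova_2x3_artificiality(d, "y")
  # oracle on the manually collapsed 2-level table
  art <- aggregate(y ~ participant_id + group,
                   d[d$embodiment != "video_human", ], mean)
  expect_equal(art$y[art$participant_id == "P1"], 0.6)
  art$w <- "artificial"
  hum <- d[d$embodiment == "video_human",
           c("participant_id", "group", "y")]
  hum$w <- "human"
  long <- rbind(art[c("participant_id", "group", "y", "w")], hum)
  want <- oracle_mixed_anova(
    data.frame(s = long$participant_id, g = long$group, w = long$w,
               y = long$y))
  for (eff in c("between", "within", "interaction")) {
    expect_equal(got[got$effect == eff, "F"], want[[eff]]$F,
                 tolerance = 1e-10)
  }
  expect_error(
    mixed_anova_2x3_artificiality(d[d$embodiment != "video_human", ], "y"),
    "human-control")
})

test_that("Bonferroni post-hocs multiply by the number of pairs and cap at 1", {
  tab <- toy_table(7)
  ph <- bonferroni_posthoc(tab, "y", "embodiment")
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p_bonferroni >= ph$p_raw))
  expect_true(all(ph$p_bonferroni <= 1))
  expect_equal(ph$p_bonferroni, pmin(1, ph$p_raw * 3))
})

test_that("post-hocs single out an extreme level, matching paired t tests", {
  tab <- toy_table(8)
  tab$y[tab$embodiment == "virtual"] <- tab$y[tab$embodiment == "virtual"] + 1
  ph <- bonferroni_posthoc(tab, "y", "embodiment")
  involves_virtual <- ph$level_a == "virtual" | ph$level_b == "virtual"
  expect_true(all(ph$p_bonferroni[involves_virtual] < 0.05))
  expect_true(all(ph$p_bonferroni[!involves_virtual] > 0.05))
  # hand-computed paired t for one pair
  a <- tab[tab$embodiment == "virtual", ]
  b <- tab[tab$embodiment == "physical", ]
  dd <- a$y[order(a$participant_id)] - b$y[order(b$participant_id)]
  t_hand <- mean(dd) / (sd(dd) / sqrt(length(dd)))
  row <- ph[involves_virtual & (ph$level_a == "physical" |
                                  ph$level_b == "physical"), ]
  expect_equal(abs(row$t), abs(t_hand), tolerance = 1e-10)
})

test_that("standardized regression matches the closed form", {
  x <- c(0.1, 0.4, 0.2, 0.8, 0.5)
  y <- c(2.0, 3.1, 2.2, 4.9, 3.0)
  got <- simple_regression(x, y)
  want <- oracle_regression(x, y)
  expect_equal(got$beta_std, want$beta_std, tolerance = 1e-12)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(got$r_sq, got$beta_std^2)

  ident <- suppressWarnings(simple_regression(x, x))  # perfect-fit lm note
  expect_equal(ident$beta_std, 1)
  expect_equal(ident$r_sq, 1)

  set.seed(10)
  null <- simple_regression(rnorm(500), rnorm(500))
  expect_lt(abs(null$beta_std), 0.15)
})

test_that("zero-variance regressions are flagged, not silently zero", {
  r <- simple_regression(rep(1, 10), rnorm(10))
  expect_false(r$defined)
  expect_true(is.na(r$beta_std))
  r2 <- simple_regression(rnorm(10), rep(2, 10))
  expect_false(r2$defined)
})

test_that("r_sq equals beta^2 across random single-predictor fits", {
  set.seed(11)
  for (i in 1:30) {
    x <- rnorm(20); y <- 0.5 * x + rnorm(20)
    r <- simple_regression(x, y)
    expect_equal(r$r_sq, r$beta_std^2, tolerance = 1e-14)
    expect_equal(sign(r$beta_std), sign(r$t))
  }
})

test_that("results bundle is deterministic and carries every stage", {
  cfg <- cohort_config(n_participants = 6, group_sizes = c(2, 2, 2))
  run <- function() {
    co <- generate_cohort(cfg, seed = 23)
    out <- run_cohort_pipeline(co)
    rq_report(out, ground_truth = co$ground_truth)
  }
  b1 <- run(); b2 <- run()
  expect_equal(b1, b2)
  expect_true(all(c("alpha", "exclusions", "anova_3x3", "anova_2x3",
                    "regressions_rq3", "regressions_rq4", "ground_truth")
                  %in% names(b1)))
  f <- tempfile(fileext = ".json")
  rq_report(run_cohort_pipeline(generate_cohort(cfg, seed = 23)),
            file = f)
  parsed <- jsonlite::read_json(f)
  expect_true("anova_3x3" %in% names(parsed))
  unlink(f)
})
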