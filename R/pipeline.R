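#' Score spontaneous mimicry across a cohort
#'
#' Applies the spontaneous-phase validity rules (occluded snippets invalid;
#' a participant x embodiment block with more than half of its snippets
#' missing is dropped entirely), then scores each valid snippet's RFR and
#' CFR windows against the stimulus emotion's AU pattern. Detection runs on
#' the raw (unsmoothed) ordinal series by default, since activation is
#' binarized and intensity ignored; set `smooth_window` to filter first and
#' threshold the smoothed values.
#'
#' @param cohort An `au_cohort` from [generate_cohort()] (or an object with
#'   the same `manifest`/`snippets` shape read from disk).
#' @param windows A [mimicry_windows()].
#' @param patterns Emotion pattern table, default [emotion_patterns()].
#' @param threshold Activation threshold (0.5 is the natural choice on
#'   smoothed series).
#' @param smooth_window `NULL` (default, raw series) or a window size passed
#'   to [smooth_au()] before thresholding.
#' @param nominal_n Nominal block size for the more-than-half rule.
#' @return List with `outcomes` (snippet-level data frame with `valid`,
#'   `rfr`, `cfr`), `rates` (the [mimicry_rates()] table) and `exclusions`.
#' @export
spontaneous_outcomes <- function(cohort, windows = mimicry_windows(),
                                 patterns = emotion_patterns(),
                                 threshold = 1, smooth_window = NULL,
                                 nominal_n = NULL) {
  man <- cohort$manifest
  idx <- which(man$phase == "spontaneous")
  if (!length(idx)) stop("cohort contains no spontaneous-phase snippets")
  rec <- man[idx, c("snippet_id", "participant_id", "group", "embodiment",
                    "emotion", "trial", "occluded")]
  rec$missing <- rec$occluded
  if (is.null(nominal_n)) {
    nominal_n <- cohort$config$snippets_per_embodiment_per_phase
  }
  rec <- filter_spontaneous_validity(rec, nominal_n = nominal_n)
  rec$rfr <- NA
  rec$cfr <- NA
  for (j in which(rec$valid)) {
    series <- cohort$snippets[[idx[j]]]
    if (!is.null(smooth_window)) series <- smooth_au(series, smooth_window)
    hit <- detect_mimicry(series, rec$emotion[j], windows = windows,
                          patterns = patterns, threshold = threshold)
    rec$rfr[j] <- hit$rfr
    rec$cfr[j] <- hit$cfr
  }
  list(outcomes = rec, rates = mimicry_rates(rec),
       exclusions = exclusion_summary(rec))
}

#' Quantify instructed mimicry across a cohort via CRQA
#'
#' Applies the instructed-phase validity rules (occluded or too-short
#' snippets invalid; blocks retaining 5 or fewer valid snippets dropped),
#' low-pass filters both the participant response and the agent stimulus,
#' removes the 1 s cut buffers from the response, computes per-snippet CRQA
#' measures on the stimulus emotion's AU channels, and averages them per
#' participant x embodiment.
#'
#' @param cohort An `au_cohort`.
#' @param config A [crqa_config()].
#' @param smooth_window Moving-average window applied to both series
#'   (`NULL` to skip filtering).
#' @param buffer Buffer frames trimmed from each end of the response.
#' @param min_valid Block-level validity threshold, see
#'   [filter_instructed_validity()].
#' @return List with `results` (per-snippet data frame of CRQA measures),
#'   `aggregates` (the [aggregate_instructed()] table) and `exclusions`.
#' @export
instructed_crqa_results <- function(cohort, config = crqa_config(),
                                    smooth_window = 10L, buffer = 30L,
                                    min_valid = 5L) {
  man <- cohort$manifest
  idx <- which(man$phase == "instructed")
  if (!length(idx)) stop("cohort contains no instructed-phase snippets")
  rec <- man[idx, c("snippet_id", "participant_id", "group", "embodiment",
                    "emotion", "trial", "occluded")]
  too_short <- man$n_frames[idx] <= 2L * buffer
  rec$missing <- rec$occluded | too_short
  rec <- filter_instructed_validity(rec, min_valid = min_valid)

  agents <- lapply(cohort$stimuli, function(s) {
    if (!is.null(smooth_window)) smooth_au(s, smooth_window) else s
  })

  keep <- which(rec$valid)
  res <- rec[keep, c("snippet_id", "participant_id", "group", "embodiment",
                     "emotion", "trial")]
  res$crr <- res$l_mean <- res$l_max <- res$det <- NA_real_
  for (r in seq_along(keep)) {
    j <- keep[r]
    series <- cohort$snippets[[idx[j]]]
    if (!is.null(smooth_window)) series <- smooth_au(series, smooth_window)
    trimmed <- trim_instructed_buffers(series, buffer)
    cq <- crqa(trimmed, agents[[rec$emotion[j]]], config,
               emotion = rec$emotion[j])
    res$crr[r] <- cq$crr
    res$l_mean[r] <- cq$l_mean
    res$l_max[r] <- cq$l_max
    res$det[r] <- cq$det
  }
  list(results = res, aggregates = aggregate_instructed(res),
       exclusions = exclusion_summary(rec))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Chains spontaneous-mimicry scoring, instructed-mimicry CRQA and the
#' mixed-design statistical stage, mirroring the study's analysis plan:
#' 3 (humanlikeness) x 3 (artificial embodiment) mixed ANOVAs and 2
#' (artificiality) x 3 ANOVAs on every dependent variable, plus the
#' mimicry-perception and instructed-to-spontaneous regressions.
#'
#' @param cohort An `au_cohort`.
#' @param crqa_cfg A [crqa_config()].
#' @param windows A [mimicry_windows()].
#' @param alpha Significance level echoed into the report.
#' @param ... Passed on to [spontaneous_outcomes()].
#' @return List with `rates`, `crqa`, `exclusions`, `anova_3x3`,
#'   `anova_2x3`, `regressions_rq3`, `regressions_rq4`.
#' @export
run_cohort_pipeline <- function(cohort, crqa_cfg = crqa_config(),
                                windows = mimicry_windows(),
                                alpha = 0.05, ...) {
  has_sp <- "spontaneous" %in% cohort$manifest$phase
  has_in <- "instructed" %in% cohort$manifest$phase
  sp <- if (has_sp) spontaneous_outcomes(cohort, windows = windows, ...)
        else NULL
  ins <- if (has_in) instructed_crqa_results(cohort, config = crqa_cfg)
         else NULL
  arts <- artificial_embodiments(cohort$config)

  wide <- cohort_table(sp$rates, ins$aggregates, cohort$questionnaire)
  dvs <- setdiff(names(wide), c("participant_id", "group", "embodiment"))

  anova_3x3 <- lapply(stats::setNames(dvs, dvs), function(dv) {
    tab <- wide[wide$embodiment %in% arts, ]
    tryCatch(mixed_anova_3x3(tab, dv), error = function(e) NULL)
  })
  anova_2x3 <- lapply(stats::setNames(dvs, dvs), function(dv) {
    tryCatch(mixed_anova_2x3_artificiality(wide, dv, artificial = arts),
             error = function(e) NULL)
  })

  regressions_rq3 <- regressions_rq4 <- NULL
  if (has_sp && !is.null(cohort$questionnaire)) {
    scales <- names(cohort$qmodel$coupling)
    art <- wide[wide$embodiment %in% arts, ]
    regressions_rq3 <- list()
    for (w in intersect(c("rate_rfr", "rate_cfr"), names(art))) {
      for (sc in intersect(scales, names(art))) {
        key <- paste(w, sc, sep = "~")
        regressions_rq3[[key]] <- simple_regression(art[[w]], art[[sc]])
      }
    }
  }
  if (has_sp && has_in) {
    regressions_rq4 <- list()
    for (w in intersect(c("rate_rfr", "rate_cfr"), names(wide))) {
      for (m in intersect(c("avg_crr", "avg_l", "avg_lmax", "avg_det"),
                          names(wide))) {
        key <- paste(m, w, sep = "->")
        regressions_rq4[[key]] <- simple_regression(wide[[m]], wide[[w]])
      }
    }
  }

  list(rates = sp$rates, crqa = ins$aggregates,
       table = wide,
       exclusions = list(spontaneous = sp$exclusions,
                         instructed = ins$exclusions),
       anova_3x3 = anova_3x3, anova_2x3 = anova_2x3,
       regressions_rq3 = regressions_rq3,
       regressions_rq4 = regressions_rq4,
       alpha = alpha)
}

#' Join pipeline outputs into one participant x embodiment table
#'
#' Builds the wide dependent-variable table feeding the statistics stage:
#' one row per participant x embodiment with spontaneous rates (`rate_rfr`,
#' `rate_cfr`), CRQA aggregates (`avg_crr`, `avg_l`, `avg_lmax`, `avg_det`)
#' and questionnaire scale means. Missing cells stay `NA` (handled by
#' listwise deletion downstream).
#'
#' @param rates [mimicry_rates()] output (or `NULL`).
#' @param crqa_aggregates [aggregate_instructed()] output (or `NULL`).
#' @param questionnaire Questionnaire data frame (or `NULL`).
#' @return Wide data frame keyed by `participant_id`, `group`, `embodiment`.
#' @export
cohort_table <- function(rates = NULL, crqa_aggregates = NULL,
                         questionnaire = NULL) {
  key <- c("participant_id", "group", "embodiment")
  parts <- list()
  if (!is.null(rates) && nrow(rates)) {
    for (w in c("RFR", "CFR")) {
      sub <- rates[rates$window == w, c(key, "rate")]
      names(sub)[4] <- paste0("rate_", tolower(w))
      parts[[length(parts) + 1L]] <- sub
    }
  }
  if (!is.null(crqa_aggregates) && nrow(crqa_aggregates)) {
    parts[[length(parts) + 1L]] <-
      crqa_aggregates[c(key, "avg_crr", "avg_l", "avg_lmax", "avg_det")]
  }
  if (!is.null(questionnaire) && nrow(questionnaire)) {
    parts[[length(parts) + 1L]] <- questionnaire
  }
  if (!length(parts)) stop("nothing to join")
  out <- Reduce(function(a, b) merge(a, b, by = key, all = TRUE), parts)
  out[order(out$participant_id, out$embodiment), , drop = FALSE]
}
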