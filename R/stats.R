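#' Mixed-design 3 x 3 ANOVA (humanlikeness x embodiment)
#'
#' The study's core omnibus test: humanlikeness group as between-subject
#' factor, artificial embodiment as within-subject factor, one dependent
#' variable per call. Uses the standard mixed-design sum-of-squares
#' decomposition (between-subjects effects tested against subjects-within-
#' groups, within-subject effects against the subject-by-treatment
#' residual), with uncorrected degrees of freedom (no sphericity
#' correction, matching the reporting convention the analysis mirrors) and
#' partial eta squared per effect. Participants missing any within-factor
#' cell are dropped listwise.
#'
#' @param data Wide data frame with `participant_id`, `group`, `embodiment`
#'   and the dependent-variable column.
#' @param dv Name of the dependent-variable column.
#' @param within,between,subject Column names of the design factors.
#' @return Data frame with one row per effect (`between`, `within`,
#'   `interaction`): `effect`, `term`, `F`, `df1`, `df2`, `p`,
#'   `partial_eta_sq`.
#' @export
mixed_anova_3x3 <- function(data, dv, within = "embodiment",
                            between = "group",
                            subject = "participant_id") {
  d <- data.frame(y = data[[dv]],
                  g = factor(data[[between]]),
                  w = factor(data[[within]]),
                  s = factor(data[[subject]]))
  d <- d[!is.na(d$y), , drop = FALSE]
  # listwise deletion: subjects observed in every within level
  n_lev <- nlevels(droplevels(d$w))
  counts <- table(d$s)
  keep <- names(counts)[counts == n_lev]
  d <- droplevels(d[d$s %in% keep, , drop = FALSE])
  per_group <- table(unique(d[c("s", "g")])$g)
  if (!nrow(d) || any(per_group < 2)) {
    stop("mixed ANOVA needs at least 2 complete participants per group")
  }
  fit <- stats::aov(y ~ g * w + Error(s), data = d)
  sm <- summary(fit)
  btab <- sm[["Error: s"]][[1]]
  wtab <- sm[["Error: Within"]][[1]]
  row_of <- function(tab, term) tab[trimws(rownames(tab)) == term, ]
  mk <- function(effect, term, tab) {
    eff <- row_of(tab, term)
    res <- row_of(tab, "Residuals")
    data.frame(effect = effect, term = term,
               F = eff[["F value"]],
               df1 = eff[["Df"]], df2 = res[["Df"]],
               p = eff[["Pr(>F)"]],
               partial_eta_sq =
                 eff[["Sum Sq"]] / (eff[["Sum Sq"]] + res[["Sum Sq"]]))
  }
  out <- rbind(mk("between", "g", btab),
               mk("within", "w", wtab),
               mk("interaction", "g:w", wtab))
  out$term <- c(between, within, paste(between, within, sep = ":"))
  rownames(out) <- NULL
  out
}

#' Mixed-design 2 x 3 ANOVA on agent artificiality
#'
#' Collapses the three artificial embodiments to their per-participant mean,
#' contrasts it with the human-control value (artificiality as the 2-level
#' within-subject factor), keeping humanlikeness as the between-subject
#' factor.
#'
#' @inheritParams mixed_anova_3x3
#' @param artificial Labels of the artificial embodiments.
#' @param human Label of the human-control embodiment.
#' @return As [mixed_anova_3x3()], with `artificiality` as the within term.
#' @export
mixed_anova_2x3_artificiality <- function(data, dv,
                                          artificial = c("virtual",
                                                         "physical",
                                                         "video_robot"),
                                          human = "video_human",
                                          between = "group",
                                          subject = "participant_id") {
  if (!any(data$embodiment == human)) {
    stop("human-control rows (embodiment ", dQuote(human), ") are required")
  }
  d <- data.frame(s = data[[subject]], g = data[[between]],
                  embodiment = data$embodiment, y = data[[dv]])
  art <- d[d$embodiment %in% artificial & !is.na(d$y), ]
  art_mean <- stats::aggregate(list(y = art$y),
                               by = list(s = art$s, g = art$g), FUN = mean)
  art_mean$artificiality <- "artificial"
  hum <- d[d$embodiment == human & !is.na(d$y),
           c("s", "g", "y")]
  hum$artificiality <- "human"
  long <- rbind(art_mean[c("s", "g", "y", "artificiality")], hum)
  long$participant_id <- long$s
  long$group <- long$g
  mixed_anova_3x3(long, "y", within = "artificiality",
                  between = "group", subject = "participant_id")
}

#' Bonferroni-corrected pairwise post-hoc comparisons
#'
#' Enumerates all level pairs of a factor and runs pairwise t tests (paired
#' on participant for within-subject factors, two-sample for between), then
#' multiplies each p value by the number of pairs, capping at 1.
#'
#' @inheritParams mixed_anova_3x3
#' @param factor_name Factor column to compare ("embodiment" or "group").
#' @param paired Paired comparisons matched on participant (default TRUE,
#'   appropriate for within-subject factors).
#' @return Data frame with `level_a`, `level_b`, `mean_diff`, `t`, `df`,
#'   `p_raw`, `p_bonferroni`.
#' @export
bonferroni_posthoc <- function(data, dv, factor_name = "embodiment",
                               paired = TRUE,
                               subject = "participant_id") {
  lev <- unique(as.character(data[[factor_name]]))
  pairs <- utils::combn(lev, 2L)
  n_pairs <- ncol(pairs)
  rows <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    a <- pairs[1, k]; b <- pairs[2, k]
    da <- data[data[[factor_name]] == a, c(subject, dv)]
    db <- data[data[[factor_name]] == b, c(subject, dv)]
    if (paired) {
      m <- merge(da, db, by = subject)
      m <- m[stats::complete.cases(m), ]
      tt <- stats::t.test(m[[2]], m[[3]], paired = TRUE)
      diff <- mean(m[[2]] - m[[3]])
    } else {
      xa <- da[[dv]][!is.na(da[[dv]])]
      xb <- db[[dv]][!is.na(db[[dv]])]
      tt <- stats::t.test(xa, xb, var.equal = TRUE)
      diff <- mean(xa) - mean(xb)
    }
    rows[[k]] <- data.frame(level_a = a, level_b = b, mean_diff = diff,
                            t = unname(tt$statistic),
                            df = unname(tt$parameter),
                            p_raw = tt$p.value)
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * n_pairs)
  out
}

#' Standardized simple regression
#'
#' Ordinary least squares of one outcome on one predictor after
#' standardizing both, as used to link spontaneous mimicry to perception
#' scales and instructed to spontaneous mimicry. Observations are
#' participant x embodiment rows pooled across embodiments. For a single
#' predictor the standardized slope equals the Pearson correlation, so
#' `r_sq = beta_std^2`.
#'
#' @param x Predictor vector.
#' @param y Outcome vector (pairs with NA dropped).
#' @return A `regression_result` list: `beta_std`, `t`, `df` (n - 2), `p`,
#'   `r_sq`, `n`, `defined` (FALSE when either variable has zero variance,
#'   in which case the estimates are NA, not silently 0).
#' @export
simple_regression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(beta_std = NA_real_, t = NA_real_,
                          df = max(0L, n - 2L), p = NA_real_,
                          r_sq = NA_real_, n = n, defined = FALSE),
                     class = "regression_result"))
  }
  fit <- stats::lm(scale(y) ~ scale(x))
  co <- summary(fit)$coefficients
  beta <- co[2, "Estimate"]
  structure(list(beta_std = unname(beta),
                 t = unname(co[2, "t value"]),
                 df = n - 2L,
                 p = unname(co[2, "Pr(>|t|)"]),
                 r_sq = unname(beta^2),
                 n = n, defined = TRUE),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  if (!x$defined) {
    cat("<regression_result> undefined (zero variance or n < 3)\n")
  } else {
    cat(sprintf("<regression_result> beta=%.3f t(%d)=%.3f p=%.4f r2=%.3f\n",
                x$beta_std, x$df, x$t, x$p, x$r_sq))
  }
  invisible(x)
}

#' Machine-readable results bundle
#'
#' Collects the pipeline's statistical outputs (ANOVA tables, regressions,
#' exclusion accounting) plus, when available, the generator's ground truth
#' into one JSON-serializable bundle, and optionally writes it to disk.
#' Deterministic: two runs from the same seed produce identical bundles.
#'
#' @param pipeline Output of [run_cohort_pipeline()].
#' @param ground_truth Optional `ground_truth` element of an `au_cohort`.
#' @param file Optional path; when given the bundle is written as JSON.
#' @return The bundle list, invisibly when written.
#' @export
rq_report <- function(pipeline, ground_truth = NULL, file = NULL) {
  strip <- function(x) {
    if (inherits(x, "regression_result")) return(unclass(x))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  bundle <- list(
    alpha = pipeline$alpha,
    exclusions = pipeline$exclusions,
    anova_3x3 = strip(pipeline$anova_3x3[
      !vapply(pipeline$anova_3x3, is.null, logical(1))]),
    anova_2x3 = strip(pipeline$anova_2x3[
      !vapply(pipeline$anova_2x3, is.null, logical(1))]),
    regressions_rq3 = strip(pipeline$regressions_rq3),
    regressions_rq4 = strip(pipeline$regressions_rq4)
  )
  if (!is.null(ground_truth)) {
    bundle$ground_truth <- list(
      seed = ground_truth$seed,
      participants = ground_truth$participants,
      questionnaire_latent = ground_truth$questionnaire_latent
    )
  }
  if (!is.null(file)) {
    jsonlite::write_json(bundle, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(bundle))
  }
  bundle
}
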