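#' Write a synthetic cohort to disk
#'
#' Writes the full synthetic study in the documented plain-text layout:
#' `au_series.csv` (one row per frame: design coordinates, 0-based `frame`,
#' the nine AU intensity columns, `occluded`), `agent_series.csv` (the
#' agent-side stimulus series per emotion), `manifest.json` (config echo and
#' per-snippet records), `questionnaire.csv`, and `ground_truth.json` (every
#' sampled latent quantity, including per-snippet RNG seeds that make each
#' response series exactly reconstructible). Output is byte-identical for a
#' fixed seed.
#'
#' @param cohort An `au_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.create(dir, showWarnings = FALSE, recursive = TRUE) &&
      !dir.exists(dir)) {
    stop("cannot create output directory ", dir)
  }
  man <- cohort$manifest
  frames <- lapply(seq_len(nrow(man)), function(s) {
    m <- unclass(cohort$snippets[[s]])
    data.frame(participant_id = man$participant_id[s],
               group = man$group[s],
               embodiment = man$embodiment[s],
               phase = man$phase[s],
               emotion = man$emotion[s],
               trial = man$trial[s],
               frame = seq_len(nrow(m)) - 1L,
               m,
               occluded = as.integer(man$occluded[s]),
               check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, frames),
                   file.path(dir, "au_series.csv"), row.names = FALSE)

  agent <- lapply(names(cohort$stimuli), function(e) {
    m <- unclass(cohort$stimuli[[e]])
    data.frame(emotion = e, frame = seq_len(nrow(m)) - 1L, m,
               check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, agent),
                   file.path(dir, "agent_series.csv"), row.names = FALSE)

  jsonlite::write_json(
    list(config = unclass(cohort$config), seed = cohort$seed,
         snippets = man),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!is.null(cohort$questionnaire)) {
    utils::write.csv(cohort$questionnaire,
                     file.path(dir, "questionnaire.csv"), row.names = FALSE)
  }
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Reconstructs an `au_cohort`-shaped object (manifest, per-snippet
#' [au_series()] list, agent stimuli, questionnaire) from the plain-text
#' layout, sufficient to run every downstream pipeline stage.
#'
#' @param dir Directory written by [write_cohort()].
#' @return An `au_cohort` object (without the generator's parameter echo).
#' @export
read_cohort <- function(dir) {
  path <- function(f) file.path(dir, f)
  for (f in c("au_series.csv", "agent_series.csv", "manifest.json")) {
    if (!file.exists(path(f))) stop("missing cohort file: ", f)
  }
  long <- utils::read.csv(path("au_series.csv"), check.names = FALSE)
  meta <- jsonlite::read_json(path("manifest.json"), simplifyVector = TRUE)
  man <- meta$snippets
  fps <- meta$config$fps
  keycols <- c("participant_id", "phase", "embodiment", "emotion", "trial")
  longkey <- do.call(paste, c(long[keycols], sep = "\r"))
  mankey <- do.call(paste, c(man[keycols], sep = "\r"))
  ord <- order(match(longkey, mankey), long$frame)
  long <- long[ord, ]
  longkey <- longkey[ord]
  snippets <- lapply(seq_along(mankey), function(s) {
    rows <- long[longkey == mankey[s], au_channels(), drop = FALSE]
    au_series(as.matrix(rows), fps = fps, emotion = man$emotion[s])
  })
  agent <- utils::read.csv(path("agent_series.csv"), check.names = FALSE)
  stimuli <- lapply(split(agent, agent$emotion), function(d) {
    au_series(as.matrix(d[order(d$frame), au_channels()]), fps = fps,
              emotion = d$emotion[1])
  })
  questionnaire <- if (file.exists(path("questionnaire.csv"))) {
    utils::read.csv(path("questionnaire.csv"), check.names = FALSE)
  }
  cfg <- cohort_config(
    n_participants = meta$config$n_participants,
    group_sizes = unlist(meta$config$group_sizes),
    embodiments = meta$config$embodiments,
    snippets_per_embodiment_per_phase =
      meta$config$snippets_per_embodiment_per_phase,
    phases = meta$config$phases, fps = fps)
  structure(list(config = cfg, params = NULL, qmodel = NULL,
                 seed = meta$seed,
                 participants = unique(man[c("participant_id", "group")]),
                 manifest = man, snippets = snippets,
                 stimuli = stimuli[emotions()],
                 questionnaire = questionnaire,
                 ground_truth = NULL),
            class = "au_cohort")
}
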