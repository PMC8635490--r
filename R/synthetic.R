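#' Synthetic cohort design configuration
#'
#' The study design emulated by the generator: 45 participants split evenly
#' across three humanlikeness groups (between-subject), four embodiments
#' (three artificial agents plus a video-recorded human control,
#' within-subject), two phases (spontaneous, then instructed mimicry), and
#' 12 snippets (2 trials x 6 emotions) per embodiment per phase, i.e. 48
#' observed expressions per participant per phase.
#'
#' @param n_participants Total participants.
#' @param group_sizes Named or unnamed counts per humanlikeness group
#'   (characterlike, humanlike, morph); must sum to `n_participants`.
#' @param embodiments Embodiment labels; the last is treated as the human
#'   control by [artificial_embodiments()].
#' @param snippets_per_embodiment_per_phase Must equal 2 x number of
#'   emotions.
#' @param phases Which phases to generate.
#' @param fps Frame rate in Hz.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 45L,
                          group_sizes = c(characterlike = 15L,
                                          humanlike = 15L,
                                          morph = 15L),
                          embodiments = c("virtual", "physical",
                                          "video_robot", "video_human"),
                          snippets_per_embodiment_per_phase = 12L,
                          phases = c("spontaneous", "instructed"),
                          fps = 30) {
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- c("characterlike", "humanlike", "morph")[
      seq_along(group_sizes)]
  }
  if (sum(group_sizes) != n_participants) {
    stop("group_sizes must sum to n_participants")
  }
  if (snippets_per_embodiment_per_phase != 2L * length(emotions())) {
    stop("snippets_per_embodiment_per_phase must equal 2 x 6 emotions")
  }
  if (fps <= 0) stop("fps must be positive")
  phases <- match.arg(phases, c("spontaneous", "instructed"),
                      several.ok = TRUE)
  structure(list(n_participants = as.integer(n_participants),
                 group_sizes = group_sizes,
                 embodiments = embodiments,
                 snippets_per_embodiment_per_phase =
                   as.integer(snippets_per_embodiment_per_phase),
                 phases = phases, fps = fps),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @param config A `cohort_config`.
#' @export
artificial_embodiments <- function(config) {
  setdiff(config$embodiments, "video_human")
}

#' Response-generation parameters
#'
#' Controls how synthetic participants respond. Spontaneous responses are
#' probabilistic, low-intensity injections of the stimulus emotion's AU
#' pattern inside the RFR and/or CFR window; instructed responses copy the
#' stimulus trajectory with a sampled lag, gain and additive noise before
#' re-quantization to the ordinal scale. Mimicry probabilities may be a
#' scalar or a vector named by embodiment; defaults reflect the magnitudes
#' the study reports (artificial agents mimicked in roughly 53-66% of RFR
#' and 66-74% of CFR trials, the human control more; ~18% of spontaneous and
#' ~9% of instructed snippets unusable).
#'
#' @param p_mimic_rfr,p_mimic_cfr Injection probability per window, scalar
#'   or named by embodiment.
#' @param mimic_peak_range Integer interval of injected peak intensities
#'   (default 1-2: "subtle", trace-to-slight).
#' @param rfr_latency_ms,cfr_latency_ms Uniform latency intervals of the
#'   injection start, each inside its window.
#' @param mimic_duration_frames Integer interval of injection durations.
#' @param instructed_lag_frames Integer interval of the copy lag.
#' @param instructed_gain_sd,instructed_noise_sd Dispersion of the copy gain
#'   (around 1) and of the per-frame additive noise.
#' @param p_occlusion Probability a snippet is unusable (occluded / detector
#'   failure); scalar or named by phase.
#' @param baseline_flicker_rate Per-frame, per-channel probability of a
#'   1-frame spurious trace activation.
#' @param participant_sd SD of a per-participant propensity shift added to
#'   the mimicry probabilities (clipped to [0.02, 0.98]); captures stable
#'   individual differences in mimicry tendency.
#' @return A `response_params` list.
#' @export
response_params <- function(p_mimic_rfr = c(virtual = 0.56, physical = 0.53,
                                            video_robot = 0.66,
                                            video_human = 0.84),
                            p_mimic_cfr = c(virtual = 0.74, physical = 0.66,
                                            video_robot = 0.73,
                                            video_human = 0.79),
                            mimic_peak_range = c(1L, 2L),
                            rfr_latency_ms = c(100, 800),
                            cfr_latency_ms = c(1100, 4000),
                            mimic_duration_frames = c(3L, 15L),
                            instructed_lag_frames = c(0L, 10L),
                            instructed_gain_sd = 0.15,
                            instructed_noise_sd = 0.3,
                            p_occlusion = c(spontaneous = 0.18,
                                            instructed = 0.09),
                            baseline_flicker_rate = 0.01,
                            participant_sd = 0.12) {
  chk01 <- function(x, nm) {
    if (any(x < 0 | x > 1)) stop(nm, " must lie in [0, 1]")
  }
  chk01(p_mimic_rfr, "p_mimic_rfr"); chk01(p_mimic_cfr, "p_mimic_cfr")
  chk01(p_occlusion, "p_occlusion")
  chk01(baseline_flicker_rate, "baseline_flicker_rate")
  if (mimic_duration_frames[1] < 1L) stop("duration lower bound must be >= 1")
  if (rfr_latency_ms[1] < 0 || rfr_latency_ms[2] >= 1000) {
    stop("rfr_latency_ms must lie inside the RFR window [0, 1000) ms")
  }
  if (cfr_latency_ms[1] < 1000 || cfr_latency_ms[2] > 5000) {
    stop("cfr_latency_ms must lie inside the CFR window [1000, 5000] ms")
  }
  structure(list(p_mimic_rfr = p_mimic_rfr, p_mimic_cfr = p_mimic_cfr,
                 mimic_peak_range = as.integer(mimic_peak_range),
                 rfr_latency_ms = rfr_latency_ms,
                 cfr_latency_ms = cfr_latency_ms,
                 mimic_duration_frames = as.integer(mimic_duration_frames),
                 instructed_lag_frames = as.integer(instructed_lag_frames),
                 instructed_gain_sd = instructed_gain_sd,
                 instructed_noise_sd = instructed_noise_sd,
                 p_occlusion = p_occlusion,
                 baseline_flicker_rate = baseline_flicker_rate,
                 participant_sd = participant_sd),
            class = "response_params")
}

# resolve a scalar-or-named parameter for one level
resolve_param <- function(p, level) {
  if (length(p) == 1L && is.null(names(p))) return(unname(p))
  if (!is.null(names(p)) && level %in% names(p)) return(unname(p[[level]]))
  if (length(p) == 1L) return(unname(p))
  stop("parameter has no entry for level ", dQuote(level))
}

#' Questionnaire generation model
#'
#' Emulates the post-block 5-point questionnaire scales (anthropomorphism,
#' likability, perceived threat, co-presence, attentional allocation,
#' affective understanding, emotional and behavioral interdependence). Each
#' scale mean is a linear function of the participant x embodiment latent
#' mimicry propensity (standardized across the cohort) plus Gaussian noise,
#' clipped to the 1-5 bounds, so a signed coupling is recoverable by the
#' regression stage.
#'
#' @param coupling Named numeric vector: signed coefficient per scale.
#' @param noise_sd Residual SD of each scale mean.
#' @param scale_bounds Two-element clipping bounds.
#' @return A `questionnaire_model` list.
#' @export
questionnaire_model <- function(coupling = c(anthropomorphism = 0.3,
                                             likability = 0.3,
                                             perceived_threat = -0.2,
                                             co_presence = 0.3,
                                             attentional_allocation = 0.2,
                                             affective_understanding = 0.3,
                                             emotional_interdependence = 0.2,
                                             behavioral_interdependence = 0.2),
                                noise_sd = 0.6,
                                scale_bounds = c(1, 5)) {
  if (is.null(names(coupling))) stop("coupling must be named by scale")
  structure(list(coupling = coupling, noise_sd = noise_sd,
                 scale_bounds = scale_bounds),
            class = "questionnaire_model")
}

# round half away from zero, clip to the ordinal scale
requantize <- function(x) {
  pmin(5L, pmax(0L, as.integer(trunc(abs(x) + 0.5) * sign(x))))
}

#' Generate an agent stimulus AU series from a template
#'
#' Per AU: linear ramp 0 to peak over the onset frames, hold at peak over the
#' apex, linear decay back to 0 over the offset, rounded (half away from
#' zero) to the ordinal 0-5 scale. Channels the template does not recruit
#' stay zero.
#'
#' @param template An [expression_template()].
#' @param fps Frame rate in Hz.
#' @return An [au_series()] of `template$total_frames` frames, with the
#'   emotion attached as attribute.
#' @export
#' @examples
#' s <- generate_stimulus_series(expression_template("anger"))
#' max(s[, "AU4"])
generate_stimulus_series <- function(template, fps = 30) {
  if (!inherits(template, "expression_template")) {
    stop("template must be an expression_template")
  }
  on <- template$onset_frames; ap <- template$apex_frames
  off <- template$offset_frames
  profile <- c(
    if (on > 0) seq_len(on) / on else numeric(0),
    rep(1, ap),
    if (off > 0) (off - seq_len(off)) / off else numeric(0)
  )
  vals <- matrix(0L, template$total_frames, length(au_channels()),
                 dimnames = list(NULL, au_channels()))
  for (au in names(template$au_peaks)) {
    vals[, au] <- requantize(profile * template$au_peaks[[au]])
  }
  au_series(vals, fps = fps, emotion = template$emotion)
}

# shuffle of `items` with no two equal adjacent labels (rejection sampling;
# for 2 copies of each of 6 emotions a valid order is abundant)
non_adjacent_shuffle <- function(items, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    perm <- sample(items)
    if (!any(perm[-1] == perm[-length(perm)])) return(perm)
  }
  stop("could not find a non-repeating order") # unreachable for 2x6 items
}

#' Generate the randomized trial schedule
#'
#' Per participant, phase and embodiment: a randomized order of the 12
#' emotion trials (2 x 6 emotions) in which no emotion immediately repeats;
#' the embodiment order is shuffled independently per participant and phase.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer; when given, seeds the RNG (deterministic
#'   schedules). When `NULL` the current RNG state is used.
#' @return Data frame with one row per snippet: `participant_id`, `group`,
#'   `phase`, `embodiment`, `position` (1-12 within block), `emotion`,
#'   `trial` (1 or 2, the occurrence of that emotion in the block).
#' @export
generate_schedule <- function(config = cohort_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  groups <- rep(names(config$group_sizes), config$group_sizes)
  items <- rep(emotions(), each = 2L)
  nb <- config$snippets_per_embodiment_per_phase
  rows <- vector("list",
                 config$n_participants * length(config$phases) *
                   length(config$embodiments))
  k <- 0L
  for (i in seq_len(config$n_participants)) {
    for (ph in config$phases) {
      emb_order <- sample(config$embodiments)
      for (emb in emb_order) {
        emo <- non_adjacent_shuffle(items)
        trial <- stats::ave(seq_along(emo), emo, FUN = seq_along)
        k <- k + 1L
        rows[[k]] <- data.frame(
          participant_id = ids[i], group = groups[i], phase = ph,
          embodiment = emb, position = seq_len(nb), emotion = emo,
          trial = as.integer(trial))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# frame range of an injection: start sampled from a ms latency interval
sample_injection <- function(latency_ms, duration_range, fps, n_frames) {
  lat <- stats::runif(1, latency_ms[1], latency_ms[2])
  start <- min(n_frames, floor(lat / 1000 * fps) + 1L)
  dur <- sample(duration_range[1]:duration_range[2], 1L)
  c(start = start, end = min(n_frames, start + dur - 1L),
    duration = dur)
}

#' Generate a spontaneous (uninstructed) response series
#'
#' Starts from a neutral face; with probability `p_mimic_rfr` injects a
#' subtle activation of the stimulus emotion's AU pattern starting inside
#' the RFR window, and independently with `p_mimic_cfr` inside the CFR
#' window; adds 1-frame baseline flicker. Intensities never exceed 5.
#'
#' @param stimulus Stimulus [au_series()] (supplies length, fps, emotion).
#' @param params A [response_params()].
#' @param seed Optional integer RNG seed (set when given).
#' @param embodiment Embodiment label used to resolve per-embodiment
#'   probabilities; `NULL` for scalar parameters.
#' @param pattern_choice "first" (default) uses the first alternative AU set
#'   of the emotion; "sample" picks one alternative at random.
#' @return An [au_series()] with a `draws` attribute recording every sampled
#'   latent quantity (injection flags, starts, durations, peaks, flicker
#'   positions).
#' @export
generate_spontaneous_response <- function(stimulus, params = response_params(),
                                          seed = NULL, embodiment = NULL,
                                          pattern_choice = c("first",
                                                             "sample")) {
  if (!is.null(seed)) set.seed(seed)
  pattern_choice <- match.arg(pattern_choice)
  emotion <- attr(stimulus, "emotion")
  if (is.null(emotion)) stop("stimulus carries no emotion attribute")
  fps <- series_fps(stimulus)
  n <- nrow(stimulus)
  vals <- matrix(0L, n, length(au_channels()),
                 dimnames = list(NULL, au_channels()))
  alts <- emotion_patterns()[[emotion]]
  draws <- list(emotion = emotion)
  for (w in c("rfr", "cfr")) {
    p <- resolve_param(params[[paste0("p_mimic_", w)]],
                       embodiment %||% "")
    hit <- stats::runif(1) < p
    draws[[paste0(w, "_injected")]] <- hit
    if (hit) {
      aus <- if (pattern_choice == "first") alts[[1]]
             else alts[[sample(length(alts), 1L)]]
      inj <- sample_injection(params[[paste0(w, "_latency_ms")]],
                              params$mimic_duration_frames, fps, n)
      peak <- sample(params$mimic_peak_range[1]:params$mimic_peak_range[2],
                     1L)
      rng <- inj[["start"]]:inj[["end"]]
      vals[rng, aus] <- pmax(vals[rng, aus], peak)
      draws[[paste0(w, "_start")]] <- inj[["start"]]
      draws[[paste0(w, "_duration")]] <- inj[["duration"]]
      draws[[paste0(w, "_peak")]] <- peak
      draws[[paste0(w, "_aus")]] <- aus
    }
  }
  if (params$baseline_flicker_rate > 0) {
    ncell <- length(vals)
    nflick <- stats::rbinom(1L, ncell, params$baseline_flicker_rate)
    if (nflick > 0) {
      pos <- sample.int(ncell, nflick)
      vals[pos] <- pmax(vals[pos], 1L)
      draws$flicker_cells <- sort(pos)
    }
  }
  out <- au_series(pmin(vals, 5L), fps = fps, emotion = emotion)
  attr(out, "draws") <- draws
  out
}

#' Generate an instructed (deliberate copy) response series
#'
#' The response is the stimulus trajectory delayed by a sampled integer lag
#' (zeros fill the start), scaled by a gain drawn around 1, perturbed with
#' i.i.d. Gaussian noise, and re-quantized (round half away from zero, clip)
#' to the ordinal 0-5 scale. With lag 0, unit gain and zero noise the copy
#' is exact.
#'
#' @inheritParams generate_spontaneous_response
#' @return An [au_series()] of the stimulus length with a `draws` attribute
#'   (`lag`, `gain`).
#' @export
generate_instructed_response <- function(stimulus, params = response_params(),
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(stimulus)
  lagr <- params$instructed_lag_frames
  lag <- if (lagr[1] == lagr[2]) lagr[1] else sample(lagr[1]:lagr[2], 1L)
  gain <- if (params$instructed_gain_sd > 0) {
    max(0, stats::rnorm(1, 1, params$instructed_gain_sd))
  } else 1
  m <- unclass(stimulus)
  shifted <- if (lag > 0) {
    rbind(matrix(0, lag, ncol(m)), m[seq_len(n - lag), , drop = FALSE])
  } else m
  noisy <- shifted * gain
  if (params$instructed_noise_sd > 0) {
    noisy <- noisy + stats::rnorm(length(noisy), 0,
                                  params$instructed_noise_sd)
  }
  vals <- matrix(requantize(noisy), n, ncol(m),
                 dimnames = dimnames(m))
  out <- au_series(vals, fps = series_fps(stimulus),
                   emotion = attr(stimulus, "emotion"))
  attr(out, "draws") <- list(lag = lag, gain = gain)
  out
}

# pad an instructed response with the 1 s cut buffers at both ends
pad_buffers <- function(series, buffer = 30L) {
  m <- unclass(series)
  z <- matrix(0L, buffer, ncol(m), dimnames = list(NULL, colnames(m)))
  au_series(rbind(z, m, z), fps = series_fps(series),
            emotion = attr(series, "emotion"))
}

#' Generate a full synthetic cohort
#'
#' Runs the whole synthetic study: builds stimulus series for the six
#' emotions, draws the randomized schedule, generates each snippet's
#' participant response (spontaneous injections or instructed copies, with
#' occlusion flags), and samples questionnaire scores coupled to the latent
#' mimicry propensity. Every snippet response is generated under its own
#' recorded RNG seed, so the ground-truth record suffices to reconstruct
#' each series exactly.
#'
#' @param config A [cohort_config()].
#' @param params A [response_params()].
#' @param qmodel A [questionnaire_model()], or `NULL` to skip questionnaires.
#' @param seed Integer master seed; the run is fully deterministic given it.
#' @param templates Stimulus templates, default [default_templates()].
#' @param instructed_buffer Buffer frames padded around instructed snippets
#'   (emulating the 1 s cut margins; default 30).
#' @return An `au_cohort` object: list with `config`, `params`, `seed`,
#'   `participants` (id, group, propensity shift), `manifest` (one row per
#'   snippet incl. `occluded` and `snippet_seed`), `snippets` (list of
#'   response [au_series()]), `stimuli` (per emotion), `questionnaire`
#'   (participant x embodiment x scale data frame or `NULL`), and
#'   `ground_truth` (all sampled latent quantities).
#' @export
generate_cohort <- function(config = cohort_config(),
                            params = response_params(),
                            qmodel = questionnaire_model(),
                            seed = 1L,
                            templates = default_templates(),
                            instructed_buffer = 30L) {
  set.seed(seed)
  stimuli <- lapply(templates, generate_stimulus_series, fps = config$fps)
  participants <- data.frame(
    participant_id = sprintf("P%02d", seq_len(config$n_participants)),
    group = rep(names(config$group_sizes), config$group_sizes),
    propensity = stats::rnorm(config$n_participants, 0,
                              params$participant_sd)
  )
  manifest <- generate_schedule(config, seed = NULL)
  n_snip <- nrow(manifest)
  manifest$snippet_id <- sprintf("S%05d", seq_len(n_snip))
  manifest$snippet_seed <- sample.int(.Machine$integer.max, n_snip)
  p_occ <- vapply(manifest$phase, resolve_param, numeric(1),
                  p = params$p_occlusion)
  manifest$occluded <- stats::runif(n_snip) < p_occ
  u <- participants$propensity[match(manifest$participant_id,
                                     participants$participant_id)]

  snippets <- vector("list", n_snip)
  draws <- vector("list", n_snip)
  for (s in seq_len(n_snip)) {
    emb <- manifest$embodiment[s]
    stim <- stimuli[[manifest$emotion[s]]]
    if (manifest$phase[s] == "spontaneous") {
      pp <- params
      pp$p_mimic_rfr <- clip01(resolve_param(params$p_mimic_rfr, emb) + u[s])
      pp$p_mimic_cfr <- clip01(resolve_param(params$p_mimic_cfr, emb) + u[s])
      resp <- generate_spontaneous_response(stim, pp,
                                            seed = manifest$snippet_seed[s])
    } else {
      resp <- generate_instructed_response(stim, params,
                                           seed = manifest$snippet_seed[s])
      if (instructed_buffer > 0) resp_p <- pad_buffers(resp,
                                                       instructed_buffer)
      else resp_p <- resp
      attr(resp_p, "draws") <- attr(resp, "draws")
      resp <- resp_p
    }
    snippets[[s]] <- resp
    draws[[s]] <- attr(resp, "draws")
    attr(snippets[[s]], "draws") <- NULL
  }
  manifest$n_frames <- vapply(snippets, nrow, integer(1))

  questionnaire <- NULL
  q_latent <- NULL
  if (!is.null(qmodel)) {
    grid <- expand.grid(participant_id = participants$participant_id,
                        embodiment = config$embodiments,
                        stringsAsFactors = FALSE)
    grid$group <- participants$group[match(grid$participant_id,
                                           participants$participant_id)]
    up <- participants$propensity[match(grid$participant_id,
                                        participants$participant_id)]
    pe <- vapply(grid$embodiment, resolve_param, numeric(1),
                 p = params$p_mimic_cfr)
    latent <- clip01(pe + up)
    z <- if (stats::sd(latent) > 0) as.numeric(scale(latent))
         else latent * 0
    for (sc in names(qmodel$coupling)) {
      raw <- 3 + qmodel$coupling[[sc]] * z +
        stats::rnorm(nrow(grid), 0, qmodel$noise_sd)
      grid[[sc]] <- pmin(qmodel$scale_bounds[2],
                         pmax(qmodel$scale_bounds[1], raw))
    }
    questionnaire <- grid
    q_latent <- data.frame(grid[c("participant_id", "embodiment")],
                           latent = latent, latent_z = z)
  }

  structure(list(
    config = config, params = params, qmodel = qmodel, seed = seed,
    participants = participants, manifest = manifest,
    snippets = snippets, stimuli = stimuli,
    questionnaire = questionnaire,
    ground_truth = list(seed = seed,
                        participants = participants,
                        snippet_draws = draws,
                        questionnaire_latent = q_latent)
  ), class = "au_cohort")
}

clip01 <- function(p) pmin(1, pmax(0, p))

#' @export
print.au_cohort <- function(x, ...) {
  cat(sprintf(
    "<au_cohort> %d participants, %d snippets (%s), seed %s\n",
    x$config$n_participants, nrow(x$manifest),
    paste(x$config$phases, collapse = " + "), format(x$seed)))
  invisible(x)
}
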