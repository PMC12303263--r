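#' Simulation configuration for the synthetic study
#'
#' Defaults restate the study design: 24 speakers (mean age 21.04, SD 3.26,
#' 3 male of 24), 24 listeners each rating 10 speakers with every speaker
#' covered by at least 10 listeners, five recording conditions rated on the
#' three social-trait 7-point scales, QCAE/SD3 questionnaires with a
#' Machiavellianism-psychopathy correlation of 0.60, and 8 mm-FWHM smooth
#' contrast volumes on a 2 mm grid (desk-scale 32^3 by default).
#'
#' @param n_speakers,n_listeners design sizes.
#' @param speakers_per_listener speakers heard by each listener.
#' @param min_listeners_per_speaker required coverage per speaker.
#' @param likert_min,likert_max rating scale bounds.
#' @param conditions,scales recording condition and trait-scale labels.
#' @param neutral_mean latent mean rating of an unmodulated voice, Likert
#'   points (mid-scale).
#' @param specificity_range interval in `[0,1]` for the latent speaker
#'   skill s (1 = perfectly specific trait expression).
#' @param effect_gain Likert points moved per unit s on a targeted scale.
#' @param noise_sd rating noise, Likert points.
#' @param questionnaire_loadings named correlations of each reactivity
#'   index with s. Default: cognitive empathy 0.45 (high skill goes with
#'   high cognitive empathy, i.e. a negative empathy-ED association),
#'   others 0.
#' @param index_intercorrelations 4x4 correlation matrix of the indices in
#'   order (machiavellianism, psychopathy, cognitive_empathy,
#'   affective_empathy); default identity except Mach-psych 0.60.
#' @param item_loadings named within-subscale item loadings, calibrated so
#'   simulated Cronbach alphas land near the reported instrument alphas
#'   (0.74, 0.61, 0.91, 0.81).
#' @param age_mean,age_sd,prop_male speaker demographics.
#' @param grid_shape,fwhm_mm,voxel_size_mm volume geometry and smoothing.
#' @param volume_noise_sd contrast-map noise scale (after smoothing and
#'   re-standardization).
#' @param beta_map_gain contrast units per unit centered ED inside the
#'   planted region (negative: greater activation with lower ED, matching
#'   the reported direction).
#' @param planted_betas named coefficients (per z-scored index) of the
#'   directly planted questionnaire-to-ED linear model used by
#'   [plant_ed()].
#' @param ed_intercept,ed_sigma intercept and residual SD of that model.
#' @param seed global integer seed; all sub-generators derive their own
#'   stream via [derive_seed()].
#' @return A validated `vm_sim_config` list.
#' @export
sim_config <- function(n_speakers = 24, n_listeners = 24,
                       speakers_per_listener = 10,
                       min_listeners_per_speaker = 10,
                       likert_min = 1, likert_max = 7,
                       conditions = VM_CONDITIONS,
                       scales = VM_SOCIAL_TRAITS,
                       neutral_mean = 4,
                       specificity_range = c(0, 1),
                       effect_gain = 3, noise_sd = 1,
                       questionnaire_loadings = c(machiavellianism = 0,
                                                  psychopathy = 0,
                                                  cognitive_empathy = 0.45,
                                                  affective_empathy = 0),
                       index_intercorrelations = NULL,
                       item_loadings = c(machiavellianism = 0.49,
                                         psychopathy = 0.40,
                                         cognitive_empathy = 0.60,
                                         affective_empathy = 0.51,
                                         narcissism = 0.45),
                       age_mean = 21.04, age_sd = 3.26, prop_male = 3 / 24,
                       grid_shape = c(32, 32, 32), fwhm_mm = 8,
                       voxel_size_mm = 2, volume_noise_sd = 1,
                       beta_map_gain = -1,
                       planted_betas = c(machiavellianism = 0,
                                         psychopathy = 0,
                                         cognitive_empathy = -0.45,
                                         affective_empathy = 0),
                       ed_intercept = 0.74, ed_sigma = 0.47,
                       seed = 1L) {
  idx <- c("machiavellianism", "psychopathy", "cognitive_empathy",
           "affective_empathy")
  if (is.null(index_intercorrelations)) {
    index_intercorrelations <- diag(4)
    dimnames(index_intercorrelations) <- list(idx, idx)
    index_intercorrelations["machiavellianism", "psychopathy"] <-
      index_intercorrelations["psychopathy", "machiavellianism"] <- 0.60
  }
  cfg <- list(n_speakers = as.integer(n_speakers),
              n_listeners = as.integer(n_listeners),
              speakers_per_listener = as.integer(speakers_per_listener),
              min_listeners_per_speaker = as.integer(min_listeners_per_speaker),
              likert_min = likert_min, likert_max = likert_max,
              conditions = conditions, scales = scales,
              neutral_mean = neutral_mean,
              specificity_range = specificity_range,
              effect_gain = effect_gain, noise_sd = noise_sd,
              questionnaire_loadings = questionnaire_loadings[idx],
              index_intercorrelations = index_intercorrelations,
              item_loadings = item_loadings,
              age_mean = age_mean, age_sd = age_sd, prop_male = prop_male,
              grid_shape = as.integer(grid_shape), fwhm_mm = fwhm_mm,
              voxel_size_mm = voxel_size_mm,
              volume_noise_sd = volume_noise_sd,
              beta_map_gain = beta_map_gain,
              planted_betas = planted_betas[idx],
              ed_intercept = ed_intercept, ed_sigma = ed_sigma,
              seed = as.integer(seed))
  # invariants
  if (cfg$likert_min >= cfg$likert_max) {
    vm_stop("likert_min must be < likert_max", class = "voicemod_config_error")
  }
  if (cfg$specificity_range[1] < 0 || cfg$specificity_range[2] > 1 ||
      diff(cfg$specificity_range) < 0) {
    vm_stop("specificity_range must be an interval within [0,1]",
            class = "voicemod_config_error")
  }
  if (!all(VM_SOCIAL_TRAITS %in% cfg$scales)) {
    vm_stop("scales must include likeable, hostile, intelligent",
            class = "voicemod_config_error")
  }
  if (any(abs(cfg$questionnaire_loadings) > 1) ||
      anyNA(cfg$questionnaire_loadings)) {
    vm_stop("questionnaire loadings must lie in [-1,1] and cover all four indices",
            class = "voicemod_config_error")
  }
  R <- cfg$index_intercorrelations
  if (!isTRUE(all.equal(R, t(R))) ||
      min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    vm_stop("index_intercorrelations must be symmetric positive semi-definite",
            class = "voicemod_config_error")
  }
  if (any(cfg$grid_shape <= 0)) {
    vm_stop("grid_shape must be positive", class = "voicemod_config_error")
  }
  structure(cfg, class = "vm_sim_config")
}

#' Assign listeners to speaker subsets
#'
#' Balanced cyclic block design: listener l (0-based, after a seed-driven
#' relabeling of both listeners and speakers) rates the
#' `speakers_per_listener` consecutive speakers starting at offset
#' `floor(l * n_speakers / n_listeners)`, modulo `n_speakers`. This meets
#' the coverage guarantee deterministically rather than by rejection
#' sampling; the emitted assignment is tallied and the coverage invariant
#' re-checked explicitly.
#'
#' @param config a [sim_config()].
#' @return Named list mapping listener id (`"l01"`, ...) to a character
#'   vector of speaker ids, with a `coverage` attribute (tally per
#'   speaker).
#' @export
assign_listeners <- function(config) {
  stopifnot(inherits(config, "vm_sim_config"))
  S <- config$n_speakers; L <- config$n_listeners
  spl <- config$speakers_per_listener; mc <- config$min_listeners_per_speaker
  if (spl > S) {
    vm_stop("speakers_per_listener (%d) exceeds n_speakers (%d)", spl, S,
            class = "voicemod_design_error")
  }
  if (L * spl < S * mc) {
    vm_stop("infeasible design: %d listener slots (%d listeners x %d speakers each) < %d required (%d speakers x coverage %d)",
            L * spl, L, spl, S * mc, S, mc, class = "voicemod_design_error")
  }
  speakers <- sprintf("s%02d", seq_len(S))
  listeners <- sprintf("l%02d", seq_len(L))
  perm <- vm_with_seed(derive_seed(config$seed, "assignment"), {
    list(sp = sample(S), li = sample(L))
  })
  out <- vector("list", L)
  for (l in seq_len(L) - 1L) {
    start <- floor(l * S / L)
    block <- (start + 0:(spl - 1)) %% S + 1L
    out[[perm$li[l + 1L]]] <- speakers[perm$sp[block]]
  }
  names(out) <- listeners
  coverage <- table(factor(unlist(out), levels = speakers))
  if (min(coverage) < mc) {
    vm_stop("design error: speaker %s covered by %d listeners < required %d",
            names(coverage)[which.min(coverage)], min(coverage), mc,
            class = "voicemod_design_error")
  }
  attr(out, "coverage") <- coverage
  out
}

#' Draw the latent ground truth for a simulation
#'
#' @param config a [sim_config()].
#' @return A `vm_ground_truth` list: `speaker_ids`, `speaker_specificity`
#'   (s, uniform over `specificity_range`), `assignment`, `planted_betas`,
#'   and `planted_voxel_beta_map` (a centered cube spanning the middle
#'   third of the grid at height `beta_map_gain`).
#' @export
draw_ground_truth <- function(config) {
  stopifnot(inherits(config, "vm_sim_config"))
  assignment <- assign_listeners(config)
  s <- vm_with_seed(derive_seed(config$seed, "specificity"), {
    stats::runif(config$n_speakers, config$specificity_range[1],
                 config$specificity_range[2])
  })
  shape <- config$grid_shape
  beta_map <- array(0, shape)
  lo <- pmax(1, floor(shape / 3) + 1)
  hi <- pmin(shape, ceiling(2 * shape / 3))
  beta_map[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- config$beta_map_gain
  structure(list(speaker_ids = sprintf("s%02d", seq_len(config$n_speakers)),
                 speaker_specificity = s, assignment = assignment,
                 planted_betas = config$planted_betas,
                 planted_voxel_beta_map = beta_map),
            class = "vm_ground_truth")
}

# target pattern: rows = recording condition, cols = scale; entries are the
# direction a perfectly skilled speaker moves each scale on each recording
vm_target_pattern <- function() {
  T <- matrix(0, 5, 3, dimnames = list(VM_CONDITIONS, VM_SOCIAL_TRAITS))
  T["likeable", "likeable"] <- 1
  T["likeable", "hostile"] <- -1
  T["hostile", "hostile"] <- 1
  T["hostile", "likeable"] <- -1
  T["intelligent", "intelligent"] <- 1
  T
}

#' Generate listener ratings
#'
#' Latent rating for (listener, speaker, condition, scale) is
#' `neutral_mean + effect_gain * s * target(condition, scale) + noise`,
#' rounded to the nearest integer and clipped to the Likert bounds. The
#' target pattern moves the matched scale up by one unit of
#' `effect_gain * s`, moves likeable and hostile scales against each other
#' on each other's recordings, and leaves the intelligent scale orthogonal
#' to both (the s -> 1, noise -> 0 limit realizes the theoretical RSM).
#'
#' @param config a [sim_config()].
#' @param ground_truth from [draw_ground_truth()].
#' @return Long-format data.frame: `listener_id`, `speaker_id`,
#'   `condition`, `scale`, `rating`.
#' @export
generate_ratings <- function(config, ground_truth) {
  stopifnot(inherits(config, "vm_sim_config"),
            inherits(ground_truth, "vm_ground_truth"))
  Tm <- vm_target_pattern()
  asg <- ground_truth$assignment
  grid <- do.call(rbind, lapply(names(asg), function(l) {
    expand.grid(listener_id = l, speaker_id = asg[[l]],
                condition = config$conditions, scale = config$scales,
                stringsAsFactors = FALSE)
  }))
  s <- ground_truth$speaker_specificity[match(grid$speaker_id,
                                              ground_truth$speaker_ids)]
  latent <- config$neutral_mean +
    config$effect_gain * s * Tm[cbind(grid$condition, grid$scale)]
  noise <- vm_with_seed(derive_seed(config$seed, "ratings"), {
    stats::rnorm(nrow(grid), 0, config$noise_sd)
  })
  grid$rating <- pmin(config$likert_max,
                      pmax(config$likert_min, round(latent + noise)))
  grid
}

#' Generate questionnaire responses and speaker demographics
#'
#' Index-level latents are drawn from a multivariate normal whose
#' correlation matrix combines `index_intercorrelations` with the
#' `questionnaire_loadings` on the (standardized) latent skill s, via the
#' conditional distribution given s. Item latents load on their index with
#' the per-subscale `item_loadings` and are thresholded into equal-width
#' bins spanning +/- 2 SD to give item responses; subscale sums then fall
#' in the instrument ranges by construction (QCAE cognitive 19-76,
#' affective 12-48; SD3 scales 9-45).
#'
#' @inheritParams generate_ratings
#' @return List with `items` (long-format: `speaker_id`, `instrument`,
#'   `item`, `response`), `speakers` (`speaker_id`, `age`, `sex`), and
#'   `index_latents` (the pre-item z-scores, for calibration tests).
#' @export
generate_reactivity <- function(config, ground_truth) {
  stopifnot(inherits(config, "vm_sim_config"),
            inherits(ground_truth, "vm_ground_truth"))
  loads <- config$questionnaire_loadings
  C <- config$index_intercorrelations
  full <- rbind(c(1, loads), cbind(loads, C))
  ev <- eigen(full, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    vm_stop("loadings + index correlations do not form a PSD latent correlation matrix (min eigenvalue %.3g)",
            min(ev), class = "voicemod_config_error")
  }
  n <- config$n_speakers
  s <- ground_truth$speaker_specificity
  s_std <- if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else rep(0, n)
  cond_cov <- C - tcrossprod(loads)
  # guard tiny negative eigenvalues from the boundary
  ec <- eigen(cond_cov, symmetric = TRUE)
  ec$values <- pmax(ec$values, 0)
  half <- ec$vectors %*% diag(sqrt(ec$values), 4) %*% t(ec$vectors)
  km <- default_keymap()
  vm_with_seed(derive_seed(config$seed, "reactivity"), {
    z <- tcrossprod(s_std, loads) +
      matrix(stats::rnorm(n * 4), n, 4) %*% half
    colnames(z) <- names(loads)
    bin <- function(latent, m) {
      pmin(m, pmax(1, 1 + floor((pmin(2, pmax(-2, latent)) + 2) / (4 / m)))) }
    z_full <- cbind(z, narcissism = stats::rnorm(n))  # narcissism: nuisance
    items <- do.call(rbind, lapply(c("qcae", "sd3"), function(instr) {
      meta <- vm_instruments[[instr]]
      sub <- km[km$instrument == instr, ]
      sub <- sub[order(sub$item), ]
      lam <- config$item_loadings[sub$subscale]
      # n x k latents: item j loads lam[j] on its subscale's index latent
      latent <- z_full[, sub$subscale, drop = FALSE] %*% diag(lam) +
        matrix(stats::rnorm(n * nrow(sub)), n) %*% diag(sqrt(1 - lam^2))
      data.frame(speaker_id = rep(ground_truth$speaker_ids, times = nrow(sub)),
                 instrument = instr,
                 item = rep(sub$item, each = n),
                 response = bin(as.vector(latent), meta$hi),
                 stringsAsFactors = FALSE)
    }))
    speakers <- data.frame(
      speaker_id = ground_truth$speaker_ids,
      age = pmax(18, round(stats::rnorm(n, config$age_mean, config$age_sd))),
      sex = ifelse(stats::runif(n) < config$prop_male, "male", "female"),
      stringsAsFactors = FALSE)
    list(items = items, speakers = speakers, index_latents = z)
  })
}

#' Plant a questionnaire-to-ED linear model
#'
#' Generates a modulation-index column directly from the planted linear
#' model `ed = intercept + sum(beta_j * z_j) + N(0, sigma^2)` on the
#' z-scored reactivity indices. This is the recovery target for the
#' association suite: unlike the ratings route, the regression coefficient
#' is exactly known. Values are not clipped to `[0, sqrt(6)]`; the
#' surrogate is for estimator calibration, not for feeding the RSM stage.
#'
#' @param profiles scored profiles from [score_profiles()].
#' @param betas named coefficients per z-scored index.
#' @param intercept,sigma linear-model intercept and residual SD.
#' @param seed integer seed.
#' @return `profiles` with an added `ed` column.
#' @export
plant_ed <- function(profiles, betas, intercept = 0.74, sigma = 0.47,
                     seed = 1L) {
  Z <- sapply(names(betas), function(v) as.numeric(scale(profiles[[v]])))
  mu <- intercept + as.numeric(Z %*% betas)
  profiles$ed <- mu + vm_with_seed(derive_seed(seed, "plant_ed"), {
    stats::rnorm(nrow(profiles), 0, sigma)
  })
  profiles
}

#' Generate per-speaker contrast volumes
#'
#' Each speaker's volume is `planted_voxel_beta_map * centered(ED)` plus
#' white Gaussian noise smoothed to the configured FWHM and re-standardized
#' to unit variance, scaled by `volume_noise_sd`. With
#' `beta_map_gain = 0` the set is pure smooth noise (the planted-null
#' generator used for false-positive-rate calibration).
#'
#' @inheritParams generate_ratings
#' @param ed_scores numeric modulation index, one per speaker.
#' @return A [volume_set()].
#' @export
generate_volumes <- function(config, ground_truth, ed_scores) {
  stopifnot(inherits(config, "vm_sim_config"),
            inherits(ground_truth, "vm_ground_truth"))
  n <- config$n_speakers
  if (length(ed_scores) != n) {
    vm_stop("need one ED score per speaker (%d != %d)", length(ed_scores), n,
            class = "voicemod_config_error")
  }
  shape <- config$grid_shape
  ed_c <- ed_scores - mean(ed_scores)
  data <- vm_with_seed(derive_seed(config$seed, "volumes"), {
    arr <- array(0, c(shape, n))
    for (i in seq_len(n)) {
      vol <- ground_truth$planted_voxel_beta_map * ed_c[i]
      if (config$volume_noise_sd > 0) {
        noise <- smooth_gaussian(array(stats::rnorm(prod(shape)), shape),
                                 config$fwhm_mm, config$voxel_size_mm)
        vol <- vol + config$volume_noise_sd * noise / stats::sd(noise)
      }
      arr[, , , i] <- vol
    }
    arr
  })
  volume_set(data, voxel_size_mm = config$voxel_size_mm,
             speaker_ids = ground_truth$speaker_ids)
}

#' Simulate a full synthetic study
#'
#' Draws the ground truth, listener ratings and questionnaires (volumes are
#' generated downstream once the modulation index has been computed, via
#' [generate_volumes()]).
#'
#' @param config a [sim_config()].
#' @return List: `config`, `ground_truth`, `ratings`, `items`, `speakers`.
#' @export
simulate_study <- function(config = sim_config()) {
  gt <- draw_ground_truth(config)
  react <- generate_reactivity(config, gt)
  list(config = config, ground_truth = gt,
       ratings = generate_ratings(config, gt),
       items = react$items, speakers = react$speakers)
}
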