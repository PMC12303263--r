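test_that("assign_listeners: balanced coverage, determinism, infeasibility error", {
  cfg <- sim_config(seed = 4)
  a <- assign_listeners(cfg)
  # 24 listeners x 10 each over 24 speakers -> every speaker exactly 10 times
  tally <- table(unlist(a))
  expect_identical(length(a), 24L)
  expect_true(all(vapply(a, function(v) length(unique(v)), integer(1)) == 10L))
  expect_true(all(tally == 10))
  # determinism given seed; different seed relabels
  expect_identical(a, assign_listeners(cfg))
  expect_false(identical(a, assign_listeners(sim_config(seed = 5))))
  # slot deficit: 2 listeners x 1 slot < 4 speakers x 1 coverage
  expect_error(
    assign_listeners(sim_config(n_speakers = 4, n_listeners = 2,
                                speakers_per_listener = 1,
                                min_listeners_per_speaker = 1)),
    "2 listener slots", class = "voicemod_design_error")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(likert_min = 7, likert_max = 1),
               class = "voicemod_config_error")
  expect_error(sim_config(specificity_range = c(-0.2, 1)),
               class = "voicemod_config_error")
  bad <- diag(4); bad[1, 2] <- bad[2, 1] <- 1.2  # not PSD
  dimnames(bad) <- list(NULL, NULL)
  expect_error(sim_config(index_intercorrelations = bad),
               class = "voicemod_config_error")
  expect_error(sim_config(grid_shape = c(0, 4, 4)),
               class = "voicemod_config_error")
  # non-PSD loadings + correlation combination caught at generation
  cfg <- sim_config(questionnaire_loadings = c(machiavellianism = 0.9,
                                               psychopathy = -0.9,
                                               cognitive_empathy = 0,
                                               affective_empathy = 0))
  expect_error(generate_reactivity(cfg, draw_ground_truth(cfg)),
               class = "voicemod_config_error")
})

test_that("noiseless ratings realize the planted pattern exactly", {
  cfg <- sim_config(noise_sd = 0, effect_gain = 3, neutral_mean = 4,
                    specificity_range = c(1, 1), seed = 2)
  gt <- draw_ground_truth(cfg)
  r <- generate_ratings(cfg, gt)
  pick <- function(cond, sc) unique(r$rating[r$condition == cond & r$scale == sc])
  expect_identical(pick("likeable", "likeable"), 7)
  expect_identical(pick("likeable", "hostile"), 1)
  expect_identical(pick("intelligent", "likeable"), 4)
  expect_identical(pick("neutral", "intelligent"), 4)
  expect_identical(pick("large", "hostile"), 4)
  # s = 0: no planted effect on any trait
  cfg0 <- sim_config(noise_sd = 0, specificity_range = c(0, 0), seed = 2)
  r0 <- generate_ratings(cfg0, draw_ground_truth(cfg0))
  expect_true(all(r0$rating == 4))
})

test_that("ratings are integer, bounded, deterministic per seed, and clipping is local", {
  cfg <- sim_config(seed = 21, noise_sd = 1.5)
  gt <- draw_ground_truth(cfg)
  r1 <- generate_ratings(cfg, gt)
  r2 <- generate_ratings(cfg, gt)
  expect_identical(r1, r2)
  expect_true(all(r1$rating == round(r1$rating)))
  expect_true(all(r1$rating >= 1 & r1$rating <= 7))
  expect_identical(nrow(r1), 24L * 10L * 5L * 3L)
  # one record per (listener, speaker, condition, scale)
  expect_false(any(duplicated(r1[, 1:4])))
})

test_that("large-sample RSM of high-skill speakers approaches the theoretical matrix", {
  # 500 listeners over 24 speakers at s = 1; attenuation from unit rating
  # noise keeps |r(L,H)| slightly below 1, so test against generous bands
  cfg <- sim_config(n_listeners = 500, speakers_per_listener = 10,
                    specificity_range = c(1, 1), noise_sd = 1, seed = 6)
  gt <- draw_ground_truth(cfg)
  r <- generate_ratings(cfg, gt)
  rsms <- lapply(sprintf("s%02d", 1:8), function(sp) build_rsm(r, sp))
  avg <- Reduce(`+`, rsms) / length(rsms)
  expect_lt(avg["likeable", "hostile"], -0.75)
  expect_lt(abs(avg["likeable", "intelligent"]), 0.1)
  expect_lt(abs(avg["hostile", "intelligent"]), 0.1)
})

test_that("questionnaire generation recovers planted loadings and ranges", {
  cfg <- sim_config(n_speakers = 1000, n_listeners = 1000,
                    questionnaire_loadings = c(machiavellianism = 0,
                                               psychopathy = 0,
                                               cognitive_empathy = -0.9,
                                               affective_empathy = 0),
                    seed = 17)
  gt <- draw_ground_truth(cfg)
  react <- generate_reactivity(cfg, gt)
  prof <- score_profiles(react$items, react$speakers)
  prof <- prof[match(gt$speaker_ids, prof$speaker_id), ]
  s <- gt$speaker_specificity
  # negative loading on s -> cognitive empathy decreases with skill; ED
  # decreases with skill, hence positive empathy-ED association expected
  expect_lt(cor(prof$cognitive_empathy, s), -0.5)
  expect_lt(abs(cor(prof$machiavellianism, s)), 0.1)
  # planted Mach-psych intercorrelation (default 0.60) survives item coarsening
  expect_gt(cor(prof$machiavellianism, prof$psychopathy), 0.35)
  # instrument ranges always respected
  expect_true(all(prof$cognitive_empathy >= 19 & prof$cognitive_empathy <= 76))
  expect_true(all(prof$affective_empathy >= 12 & prof$affective_empathy <= 48))
  expect_true(all(prof$machiavellianism >= 9 & prof$machiavellianism <= 45))
  expect_true(all(prof$psychopathy >= 9 & prof$psychopathy <= 45))
  expect_true(all(prof$age > 0))
  # null loadings -> indices independent of s
  cfg0 <- sim_config(n_speakers = 1000, n_listeners = 1000, seed = 18,
                     questionnaire_loadings = c(machiavellianism = 0,
                                                psychopathy = 0,
                                                cognitive_empathy = 0,
                                                affective_empathy = 0))
  gt0 <- draw_ground_truth(cfg0)
  z0 <- generate_reactivity(cfg0, gt0)$index_latents
  expect_true(all(abs(cor(z0, gt0$speaker_specificity)) < 0.1))
})

test_that("simulated instrument alphas land near the calibrated targets", {
  cfg <- sim_config(n_speakers = 400, n_listeners = 400, seed = 23)
  gt <- draw_ground_truth(cfg)
  items <- generate_reactivity(cfg, gt)$items
  wide <- function(instr, it) {
    sub <- items[items$instrument == instr & items$item %in% it, ]
    matrix(sub$response[order(sub$item, sub$speaker_id)], ncol = length(it))
  }
  expect_equal(cronbach_alpha(wide("qcae", 1:19)), 0.91, tolerance = 0.08)
  expect_equal(cronbach_alpha(wide("sd3", 1:9)), 0.74, tolerance = 0.12)
})

test_that("plant_ed encodes the stated linear model exactly at sigma 0", {
  cfg <- sim_config(n_speakers = 50, n_listeners = 50, seed = 31)
  gt <- draw_ground_truth(cfg)
  react <- generate_reactivity(cfg, gt)
  prof <- score_profiles(react$items, react$speakers)
  betas <- c(machiavellianism = 0.2, psychopathy = -0.1,
             cognitive_empathy = -0.45, affective_empathy = 0)
  p0 <- plant_ed(prof, betas, intercept = 0.7, sigma = 0, seed = 1)
  fit <- fit_ols(model_spec("ed"), cbind(p0))
  got <- fit$coefficients
  expect_equal(got$beta[match(names(betas), got$term)], unname(betas),
               tolerance = 1e-9)
  expect_equal(got$beta[got$term == "(Intercept)"], 0.7, tolerance = 1e-9)
})

test_that("volume generation: planted signal, null noise, determinism", {
  cfg <- sim_config(n_speakers = 10, n_listeners = 10,
                    speakers_per_listener = 5, min_listeners_per_speaker = 5,
                    grid_shape = c(12, 12, 12), volume_noise_sd = 0,
                    beta_map_gain = -1, seed = 41)
  gt <- draw_ground_truth(cfg)
  ed <- seq(0.2, 1.6, length.out = 10)
  vols <- generate_volumes(cfg, gt, ed)
  sm <- voxelwise_regression(vols, ed)
  inside <- gt$planted_voxel_beta_map != 0
  expect_true(all(sm$t_map[inside] < 0))
  # noiseless + zero gain would be all-degenerate; with noise the null map
  # regenerates identically under the same seed
  cfg2 <- sim_config(n_speakers = 6, n_listeners = 6, speakers_per_listener = 3,
                     min_listeners_per_speaker = 3, grid_shape = c(10, 10, 10),
                     beta_map_gain = 0, seed = 42)
  gt2 <- draw_ground_truth(cfg2)
  v1 <- generate_volumes(cfg2, gt2, rep(1, 6) + seq(0, 1, length.out = 6))
  v2 <- generate_volumes(cfg2, gt2, rep(1, 6) + seq(0, 1, length.out = 6))
  expect_identical(v1$data, v2$data)
  expect_error(generate_volumes(cfg2, gt2, 1:3), class = "voicemod_config_error")
})

test_that("fwhm 0 volumes have independent voxels (lag-1 autocorrelation near 0)", {
  cfg <- sim_config(n_speakers = 6, n_listeners = 6, speakers_per_listener = 3,
                    min_listeners_per_speaker = 3, grid_shape = c(20, 20, 20),
                    fwhm_mm = 0, beta_map_gain = 0, seed = 43)
  gt <- draw_ground_truth(cfg)
  v <- generate_volumes(cfg, gt, runif(6))$data[, , , 1]
  r1 <- cor(as.vector(v[-20, , ]), as.vector(v[-1, , ]))
  expect_lt(abs(r1), 0.05)
  # and smoothed volumes do not
  cfg8 <- sim_config(n_speakers = 6, n_listeners = 6, speakers_per_listener = 3,
                     min_listeners_per_speaker = 3, grid_shape = c(20, 20, 20),
                     fwhm_mm = 8, beta_map_gain = 0, seed = 43)
  v8 <- generate_volumes(cfg8, draw_ground_truth(cfg8), runif(6))$data[, , , 1]
  expect_gt(cor(as.vector(v8[-20, , ]), as.vector(v8[-1, , ])), 0.5)
})
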