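#' Pipeline configuration
#'
#' @param out output directory.
#' @param seed global seed (flows to every stochastic stage).
#' @param stages character subset of
#'   `c("simulate", "score", "index", "regress", "voxelglm")`, executed in
#'   dependency order.
#' @param ratings,items,speakers,performance,profiles,volumes input paths
#'   for stages whose upstream producer is not enabled.
#' @param sim a [sim_config()] for the simulate stage.
#' @param rsm_mode,tail,resid_test,voxel_p,alpha,n_iter,connectivity stage
#'   parameters (see the stage functions).
#' @return A `vm_pipeline_config`.
#' @export
pipeline_config <- function(out, seed = 1L,
                            stages = c("simulate", "score", "index",
                                       "regress", "voxelglm"),
                            ratings = NULL, items = NULL, speakers = NULL,
                            performance = NULL, profiles = NULL,
                            volumes = NULL, sim = NULL,
                            rsm_mode = "scalewise", tail = "two.sided",
                            resid_test = "shapiro", voxel_p = 0.001,
                            alpha = 0.05, n_iter = 1000, connectivity = 18) {
  stages <- match.arg(stages, c("simulate", "score", "index", "regress",
                                "voxelglm"), several.ok = TRUE)
  cfg <- list(out = out, seed = as.integer(seed), stages = stages,
              ratings = ratings, items = items, speakers = speakers,
              performance = performance, profiles = profiles,
              volumes = volumes,
              sim = sim %||% sim_config(seed = seed),
              rsm_mode = rsm_mode, tail = tail, resid_test = resid_test,
              voxel_p = voxel_p, alpha = alpha, n_iter = n_iter,
              connectivity = connectivity)
  # inputs must exist up front for stages without an enabled producer
  need <- list(score = c("items", "speakers"), index = "ratings",
               regress = c("performance", "profiles"),
               voxelglm = c("volumes", "performance", "profiles"))
  producer <- list(items = "simulate", speakers = "simulate",
                   ratings = "simulate", performance = "index",
                   profiles = "score", volumes = "simulate")
  for (st in stages) {
    for (inp in need[[st]]) {
      if (producer[[inp]] %in% stages) next  # produced upstream in this run
      if (is.null(cfg[[inp]])) {
        vm_stop("stage '%s' needs input '%s': supply a path or enable stage '%s'",
                st, inp, producer[[inp]], class = "voicemod_config_error")
      }
      if (!file.exists(cfg[[inp]])) {
        vm_stop("stage '%s': input file missing: %s", st, cfg[[inp]],
                class = "voicemod_config_error")
      }
    }
  }
  structure(cfg, class = "vm_pipeline_config")
}

vm_log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[voicemod] %s %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order
#' (simulate -> score -> index -> regress -> voxelglm), writing every
#' stage's outputs under `config$out` and a JSON run manifest
#' (`manifest.json`) recording the configuration snapshot, package
#' version, derived seeds, per-file MD5 checksums, exclusion decisions and
#' warnings. Reruns with an identical config and seed reproduce
#' deterministic outputs bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage timing to standard error.
#' @return The manifest, invisibly (also written to disk).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "vm_pipeline_config"))
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  manifest <- list(
    package = "voicemod",
    version = as.character(utils::packageVersion("voicemod")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    stages = config$stages,
    parameters = config[c("rsm_mode", "tail", "resid_test", "voxel_p",
                          "alpha", "n_iter", "connectivity")],
    files = list(), decisions = list(), warnings = character(0))
  hash <- substr(tools::md5sum(
    vm_config_snapshot(config, file.path(out, "config_snapshot.json")))[[1]],
    1, 12)
  paths <- list(ratings = config$ratings, items = config$items,
                speakers = config$speakers, performance = config$performance,
                profiles = config$profiles, volumes = config$volumes)
  stage_err <- function(st, e) {
    vm_stop("stage '%s' failed: %s (partial outputs in %s are incomplete)",
            st, conditionMessage(e), out, class = "voicemod_stage_error")
  }

  if ("simulate" %in% config$stages) {
    vm_log_stage(verbose, "stage simulate: seed %d", config$seed)
    tryCatch({
      sim <- simulate_study(config$sim)
      paths$ratings <- write_table(sim$ratings, file.path(out, "ratings.csv"), hash)
      paths$items <- write_table(sim$items, file.path(out, "items.csv"), hash)
      paths$speakers <- write_table(sim$speakers, file.path(out, "speakers.csv"), hash)
      truth <- data.frame(speaker_id = sim$ground_truth$speaker_ids,
                          specificity = sim$ground_truth$speaker_specificity)
      write_table(truth, file.path(out, "ground_truth.csv"), hash)
      manifest$decisions$simulate <- sprintf(
        "generated %d speakers x %d listeners (ground_truth.csv is for test harnesses only)",
        config$sim$n_speakers, config$sim$n_listeners)
      sim
    }, error = function(e) stage_err("simulate", e)) -> sim_out
  } else sim_out <- NULL

  if ("score" %in% config$stages) {
    vm_log_stage(verbose, "stage score")
    tryCatch({
      profiles <- score_profiles(read_items(paths$items),
                                 read_speakers(paths$speakers))
      paths$profiles <- write_table(profiles, file.path(out, "profiles.csv"), hash)
    }, error = function(e) stage_err("score", e))
  }

  if ("index" %in% config$stages) {
    vm_log_stage(verbose, "stage index (rsm_mode = %s)", config$rsm_mode)
    tryCatch({
      ratings <- read_ratings(paths$ratings)
      perf <- compute_performance(ratings, mode = config$rsm_mode)
      paths$performance <- write_table(perf, file.path(out, "performance.csv"), hash)
      write_table(rsm_table(ratings, mode = config$rsm_mode),
                  file.path(out, "rsm.csv"), hash)
      tt <- lapply(c(hostility = "delta_hostility",
                     intelligence = "delta_intelligence",
                     likeability = "delta_likeability"), function(cl) {
        two <- delta_ttest(perf[[cl]], "two.sided")
        one <- delta_ttest(perf[[cl]], "greater")
        data.frame(mean = two$mean, sd = two$sd, t = two$t, df = two$df,
                   p_two_sided = two$p, p_greater = one$p)
      })
      tt <- cbind(trait = names(tt), do.call(rbind, tt))
      write_table(tt, file.path(out, "delta_ttests.csv"), hash)
    }, error = function(e) stage_err("index", e))
  }

  if ("regress" %in% config$stages) {
    vm_log_stage(verbose, "stage regress (resid_test = %s)", config$resid_test)
    tryCatch({
      rep <- run_association_suite(read_performance(paths$performance),
                                   read_profiles(paths$profiles),
                                   resid_test = config$resid_test)
      write_table(rep$partial_table, file.path(out, "table1_partial_correlations.csv"), hash)
      coef_rows <- function(fit, label) {
        cbind(model = label, fit$coefficients,
              adj_r_squared = fit$adj_r_squared, f = fit$f,
              df1 = fit$df1, df2 = fit$df2, n_used = fit$n_used)
      }
      write_table(rbind(coef_rows(rep$ols_primary, "ols_primary"),
                        coef_rows(rep$robust, "robust_m"),
                        coef_rows(rep$likeability_model, "delta_likeability_ols")),
                  file.path(out, "table2_regression.csv"), hash)
      writeLines(rep$log, file.path(out, "regression_log.txt"))
      manifest$decisions$regress <- rep$log
    }, error = function(e) stage_err("regress", e))
  }

  if ("voxelglm" %in% config$stages) {
    vm_log_stage(verbose, "stage voxelglm (%d MC iterations)", config$n_iter)
    tryCatch({
      perf <- read_performance(paths$performance)
      prof <- read_profiles(paths$profiles)
      merged <- merge(perf, prof, by = "speaker_id")
      if (!is.null(paths$volumes) && !("simulate" %in% config$stages)) {
        nif <- read_nifti(paths$volumes)
        vols <- volume_set(nif$data, voxel_size_mm = nif$voxel_size_mm,
                           origin = nif$origin,
                           speaker_ids = merged$speaker_id)
      } else {
        vols <- generate_volumes(config$sim, sim_out$ground_truth,
                                 perf$ed[match(sim_out$ground_truth$speaker_ids,
                                               perf$speaker_id)])
        paths$volumes <- file.path(out, "volumes_4d.nii")
        write_nifti(vols$data, paths$volumes, vols$voxel_size_mm, vols$origin)
      }
      sm <- voxelwise_regression(vols, merged$ed[match(vols$speaker_ids,
                                                       merged$speaker_id)],
                                 merged[match(vols$speaker_ids, merged$speaker_id),
                                        c("age", "sex")])
      write_nifti(sm$t_map, file.path(out, "t_map.nii"), sm$voxel_size_mm, sm$origin)
      write_nifti(sm$z_map, file.path(out, "z_map.nii"), sm$voxel_size_mm, sm$origin)
      k_min <- mc_cluster_threshold(dim(sm$t_map), sm$mask,
                                    fwhm_mm = config$sim$fwhm_mm,
                                    voxel_size_mm = sm$voxel_size_mm,
                                    voxel_p = config$voxel_p,
                                    n_iter = config$n_iter,
                                    alpha = config$alpha,
                                    seed = derive_seed(config$seed, "mc"),
                                    connectivity = config$connectivity)
      tabs <- lapply(c("negative", "positive"), function(dir) {
        tab <- extract_clusters(sm, config$voxel_p, k_min, dir,
                                config$connectivity)
        if (nrow(tab)) cbind(direction = dir, tab) else NULL
      })
      tab3 <- do.call(rbind, Filter(Negate(is.null), tabs)) %||%
        data.frame(direction = character(0), cluster = integer(0),
                   k = integer(0), region = character(0),
                   hemisphere = character(0), x = numeric(0), y = numeric(0),
                   z = numeric(0), T = numeric(0), Z = numeric(0))
      write_table(tab3, file.path(out, "table3_clusters.csv"), hash)
      manifest$decisions$voxelglm <- sprintf(
        "k_min = %d (voxel p < %g, alpha = %g, %d iterations)",
        k_min, config$voxel_p, config$alpha, config$n_iter)
    }, error = function(e) stage_err("voxelglm", e))
  }

  files <- list.files(out, pattern = "\\.(csv|txt|nii)$", full.names = TRUE)
  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- basename(files)
  manifest$manifest_hash <- hash
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  vm_log_stage(verbose, "done in %.1f s", manifest$elapsed_s)
  invisible(manifest)
}

# serializable config snapshot (drops matrices into plain lists); the
# output directory is excluded so the manifest hash reflects only the
# analysis-relevant configuration
vm_config_snapshot <- function(config, path) {
  snap <- unclass(config)
  snap$out <- NULL
  snap$sim <- unclass(snap$sim)
  jsonlite::write_json(snap, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  path
}
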