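#' Default pipeline configuration
#'
#' Settings for the end-to-end synthetic analysis: cohort simulation,
#' model fitting and comparison, lagged regressions, ROI RSA, valence-split
#' and cross-timepoint RSA, and the group brain-behavior regression.
#'
#' @param n_participants cohort size.
#' @param generative_model model used to simulate behavior.
#' @param fit_models models entered into the comparison.
#' @param n_starts restarts per fit (kept small for the demo pipeline).
#' @param n_voxels voxels in the simulated ROI patterns.
#' @param identity_signal,kappa,noise_sd,rho neural generator settings
#'   (see [neural_config()]).
#' @param tasks task labels.
#' @return A named list, serializable as JSON.
#' @export
pipeline_config <- function(n_participants = 8,
                            generative_model = "vlr_vca",
                            fit_models = c("baseline", "vlr_vca"),
                            n_starts = 5, n_voxels = 40,
                            identity_signal = 1, kappa = 0.7,
                            noise_sd = 1, rho = 0.2,
                            tasks = c("social", "bandit")) {
  list(n_participants = n_participants,
       generative_model = generative_model,
       fit_models = fit_models, n_starts = n_starts, n_voxels = n_voxels,
       identity_signal = identity_signal, kappa = kappa,
       noise_sd = noise_sd, rho = rho, tasks = tasks)
}

stage_seed <- function(seed, stage) {
  offsets <- c(behavior = 1, fits = 2, lagreg = 3, rsa = 4, crosstime = 5,
               group = 6)
  as.integer(seed + 10007L * offsets[[stage]])
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> fit/compare -> lagged regressions -> ROI RSA ->
#' cross-timepoint RSA -> group brain-behavior regression from one config,
#' writing CSV/JSON outputs in a fixed directory layout (`behavior/`,
#' `fits/`, `lagreg/`, `rsa/`, `crosstime/`, `group/`) plus a `manifest.json`
#' recording the seed, config hash and which stages ran.  A stage whose
#' outputs already exist is skipped unless `force = TRUE`, and per-stage
#' seeds are derived deterministically from the global seed so a resumed
#' run reproduces a fresh one.
#'
#' @param config a [pipeline_config()] list or path to a JSON file of one.
#' @param out_dir output directory (created if needed).
#' @param seed global integer seed.
#' @param force rerun stages whose outputs already exist.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1,
                         force = FALSE) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- pipeline_config()
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  task_cfg <- task_config()
  ran <- character(0)
  outputs <- list()

  stage <- function(name, files, fn) {
    paths <- file.path(out_dir, name, files)
    dir.create(file.path(out_dir, name), showWarnings = FALSE)
    # rerun when forced, when outputs are missing, or when any upstream
    # stage reran (so a deleted stage triggers itself plus downstream)
    if (!force && !length(ran) && all(file.exists(paths))) {
      outputs[[name]] <<- paths
      return(invisible(NULL))
    }
    fn(paths)
    ran <<- c(ran, name)
    outputs[[name]] <<- paths
  }

  # -- behavior ------------------------------------------------------------
  stage("behavior", c("behavior.csv", "true_params.csv"), function(paths) {
    cohort <- generate_cohort(config$n_participants, config$generative_model,
                              task_cfg, tasks = config$tasks,
                              seed = stage_seed(seed, "behavior"))
    write_behavior(cohort$behavior, paths[1])
    utils::write.csv(cohort$true_params, paths[2], row.names = FALSE)
  })
  behavior <- read_behavior(outputs$behavior[1], task_cfg)

  # -- fits ----------------------------------------------------------------
  stage("fits", c("comparison.csv", "best_params.csv"), function(paths) {
    fits <- list()
    sd0 <- stage_seed(seed, "fits")
    i <- 0
    for (pt in split(behavior, list(behavior$participant_id, behavior$task),
                     drop = TRUE)) {
      for (m in config$fit_models) {
        i <- i + 1
        fits[[i]] <- fit_ca_model(pt, m, task_cfg,
                                  n_starts = config$n_starts,
                                  seed = sd0 + i)
      }
    }
    cmp <- compare_ca_models(fits)
    utils::write.csv(cmp$table, paths[1], row.names = FALSE)
    best <- do.call(rbind, lapply(fits, function(f) {
      if (f$model$name != config$generative_model) return(NULL)
      cbind(data.frame(participant_id = f$participant_id, task = f$task),
            as.data.frame(as.list(coef(f))))
    }))
    utils::write.csv(best, paths[2], row.names = FALSE)
  })
  best_params <- utils::read.csv(outputs$fits[2], stringsAsFactors = FALSE)

  # -- lagged regressions --------------------------------------------------
  stage("lagreg", "coefficients.csv", function(paths) {
    out <- do.call(rbind, lapply(
      split(behavior, behavior$participant_id), function(d) {
        fit <- fit_lagged_model(build_lagged_design(d, tasks = config$tasks))
        cbind(participant_id = d$participant_id[1], fit$coefficients)
      }))
    utils::write.csv(out, paths[1], row.names = FALSE)
  })

  # -- ROI RSA (+ valence split) -------------------------------------------
  stage("rsa", c("identity_betas.csv", "valence.csv"), function(paths) {
    ncfg <- neural_config(n_voxels = config$n_voxels,
                          identity_signal = config$identity_signal,
                          kappa = config$kappa, noise_sd = config$noise_sd,
                          rho = config$rho)
    sd0 <- stage_seed(seed, "rsa")
    rows <- val_rows <- list()
    i <- 0
    for (pt in split(behavior, list(behavior$participant_id, behavior$task),
                     drop = TRUE)) {
      i <- i + 1
      bp <- best_params[
        best_params$participant_id == pt$participant_id[1] &
        best_params$task == pt$task[1], , drop = FALSE]
      par <- unlist(bp[, setdiff(names(bp), c("participant_id", "task"))])
      tr <- ca_trajectory(pt, config$generative_model, par, task_cfg)
      v_of_trial <- tr$V[cbind(seq_len(nrow(pt)), pt$stimulus_id)]
      pats <- generate_patterns(pt, ncfg, values = v_of_trial,
                                delta = tr$delta, seed = sd0 + i)
      for (ps in pats) {
        reg <- rdm_regression(neural_rdm(ps))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(participant_id = pt$participant_id[1],
                     task = pt$task[1], phase = ps$phase), reg)
      }
      val_rows[[length(val_rows) + 1L]] <- cbind(
        data.frame(participant_id = pt$participant_id[1],
                   task = pt$task[1]), valence_split_rsa(pats))
    }
    utils::write.csv(do.call(rbind, rows), paths[1], row.names = FALSE)
    utils::write.csv(do.call(rbind, val_rows), paths[2], row.names = FALSE)
  })

  # -- cross-timepoint RSA --------------------------------------------------
  stage("crosstime", "scores.csv", function(paths) {
    ncfg <- neural_config(n_voxels = config$n_voxels,
                          identity_signal = config$identity_signal,
                          kappa = config$kappa, noise_sd = config$noise_sd,
                          rho = config$rho)
    sd0 <- stage_seed(seed, "crosstime")
    rows <- list()
    i <- 0
    for (pt in split(behavior, list(behavior$participant_id, behavior$task),
                     drop = TRUE)) {
      i <- i + 1
      pats <- generate_patterns(pt, ncfg, seed = sd0 + i)
      res <- cross_timepoint_rsa(pats$choice, pats$feedback)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pt$participant_id[1], task = pt$task[1],
        score = res$score)
    }
    utils::write.csv(do.call(rbind, rows), paths[1], row.names = FALSE)
  })

  # -- group ---------------------------------------------------------------
  stage("group", "brain_behavior.csv", function(paths) {
    rsab <- utils::read.csv(outputs$rsa[1], stringsAsFactors = FALSE)
    idb <- rsab[rsab$term == "identity" & rsab$phase == "choice", ]
    idb <- stats::aggregate(beta ~ participant_id, idb, mean)
    ca_cols <- intersect(c("ca", "ca_pos", "ca_neg"), names(best_params))
    ca_mean <- stats::aggregate(
      best_params[, ca_cols, drop = FALSE],
      by = list(participant_id = best_params$participant_id),
      FUN = mean)
    ca_mean$ca_overall <- rowMeans(ca_mean[, ca_cols, drop = FALSE])
    m <- merge(idb, ca_mean, by = "participant_id")
    reg <- brain_behavior_regression(m$beta, m$ca_overall)
    utils::write.csv(reg, paths[1], row.names = FALSE)
  })

  manifest <- list(seed = seed, config = config,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   package_version = as.character(utils::packageVersion(
                     "credassign")),
                   stages_run = ran,
                   outputs = lapply(outputs, basename),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
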