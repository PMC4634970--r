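#' Lossless save / load of fitted objects and presets
#'
#' Serializes any package object (fits, models, presets, configs) to JSON
#' with full type information and maximal numeric precision, so that
#' `load_model(save_model(x))` round-trips bit-exactly for integers and to
#' within one ulp for doubles.
#'
#' @param x object to save.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored object.
#' @export
save_model <- function(x, path) {
  # 17 significant digits round-trips IEEE doubles exactly
  writeLines(jsonlite::serializeJSON(x, digits = 17), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}

#' Export a dynamical-system preset as plain JSON
#'
#' Writes the physical parameters and noise model under stable keys
#' (`m`, `c`, `k`, `dt`, `Sigma_theta`, `alpha`, `sigma_u2`, `ranges`), a
#' language-portable description of the preset.
#'
#' @param st an `"lds"` object.
#' @param path file path.
#' @export
preset_to_json <- function(st, path) {
  p <- st$params
  x <- list(m = p$m, c = p$c, k = p$k, dt = p$dt,
            Sigma_theta = st$Sigma_theta,
            alpha = st$alpha, sigma_u2 = st$sigma_u2,
            ranges = list(angle = st$angle_range,
                          torque = st$torque_range,
                          init_margin = st$init_margin))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

#' @rdname preset_to_json
#' @export
preset_from_json <- function(path) {
  x <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"))
  oscillator_transition(
    oscillator_params(m = x$m, c = x$c, k = x$k, dt = x$dt),
    Sigma_theta = matrix(unlist(x$Sigma_theta), 2, 2),
    alpha = x$alpha, sigma_u2 = x$sigma_u2,
    angle_range = x$ranges$angle, torque_range = x$ranges$torque,
    init_margin = x$ranges$init_margin)
}

#' Validate and normalize an experiment configuration
#'
#' Fills unspecified fields with the standard full-scale defaults of the
#' chosen preset (240 hidden units and 120 exponential-decay epochs for the
#' uncontrolled system; 180 and 1200 sigmoidal epochs for the controlled
#' one), enforces that the number of recurrent units equals the number of
#' hidden units, and at `scale = "desk"` caps the runtime-determining sizes
#' so the experiment is runnable interactively.
#'
#' @param cfg named list; recognized fields: `preset`, `n_hidden`,
#'   `n_recurrent`, `epochs`, `T`, `n_traj`, `K` (restarts), `n_tokens`,
#'   `scale` (`"desk"` or `"paper"`), `seed`, `em_orders`, `eps0`.
#' @return the normalized configuration (class `"refh_config"`), or an
#'   error describing the inconsistency.
#' @export
validate_config <- function(cfg = list()) {
  known <- c("preset", "n_hidden", "n_recurrent", "epochs", "T", "n_traj",
             "K", "n_tokens", "scale", "seed", "em_orders", "eps0")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop_invalid("unknown config field(s): %s", paste(bad, collapse = ", "))
  presets <- c("uncontrolled", "controlled", "no_spring", "sweep_stiffness",
               "sweep_damping", "sweep_inertia", "damping_variants")
  cfg$preset <- cfg$preset %||% "uncontrolled"
  if (!cfg$preset %in% presets)
    stop_invalid("unknown preset '%s'; valid presets: %s", cfg$preset,
                 paste(presets, collapse = ", "))
  controlled <- cfg$preset == "controlled"
  cfg$scale <- cfg$scale %||% "paper"
  if (!cfg$scale %in% c("desk", "paper"))
    stop_invalid("scale must be 'desk' or 'paper'")
  cfg$n_hidden <- cfg$n_hidden %||% (if (controlled) 180L else 240L)
  if (!is.null(cfg$n_recurrent) && cfg$n_recurrent != cfg$n_hidden)
    stop_invalid("the number of recurrent units must equal the number of hidden units (got %d != %d)",
                 cfg$n_recurrent, cfg$n_hidden)
  cfg$n_recurrent <- cfg$n_hidden
  cfg$epochs <- cfg$epochs %||% (if (controlled) 1200L else 120L)
  cfg$T <- cfg$T %||% 1000L
  cfg$n_traj <- cfg$n_traj %||% 40L
  cfg$K <- cfg$K %||% (if (cfg$scale == "desk") 5L else 20L)
  cfg$n_tokens <- cfg$n_tokens %||% (if (cfg$scale == "desk") 3L else 12L)
  cfg$seed <- cfg$seed %||% 1L
  cfg$eps0 <- cfg$eps0 %||% 5e-4
  cfg$em_orders <- cfg$em_orders %||% (if (controlled) c(2L, 3L)
                                       else c(1L, 2L))
  if (cfg$scale == "desk") {
    cfg$n_hidden <- min(cfg$n_hidden, 120L)
    cfg$n_recurrent <- cfg$n_hidden
    cfg$epochs <- min(cfg$epochs, 40L)
    cfg$K <- min(cfg$K, 5L)
    cfg$n_tokens <- min(cfg$n_tokens, 3L)
  }
  structure(cfg, class = "refh_config")
}

#' Run a full experiment end to end
#'
#' Simulate, encode, train a harmonium, fit the benchmark filters, and
#' evaluate everything on a common held-out test set.  With an output
#' directory, results tables are written as CSV, models as JSON, and a
#' manifest lists every artifact with its MD5 checksum (same config + seed
#' always reproduces identical checksums).
#'
#' @param cfg configuration list, passed through [validate_config()].
#' @param out_dir optional output directory.
#' @param refh_fit optionally, an already-trained `"refh"` (skips training).
#' @return list with `stats` (data frame: model, mse, err_mean, err_var),
#'   `models`, `cfg` and (if written) `manifest`.
#' @export
run_experiment <- function(cfg = list(), out_dir = NULL, refh_fit = NULL) {
  cfg <- validate_config(cfg)
  st <- lds_preset(cfg$preset)
  fit <- refh_fit %||% refh(st = st, n_hidden = cfg$n_hidden,
                            epochs = cfg$epochs, T = cfg$T,
                            n_traj = cfg$n_traj, eps0 = cfg$eps0,
                            seed = cfg$seed)
  test <- encode_dataset(st, cfg$T, cfg$n_traj,
                         seed = traj_seed(cfg$seed, 424242))
  obs <- lapply(test$traj, pseudo_obs_seq, code_prop = test$code_prop,
                code_efcp = test$code_efcp)
  truth <- lapply(test$traj, function(tr) tr$theta[, 1])
  L <- test$code_prop$L

  ests <- list(
    rEFH = estimator_refh(fit)(test),
    OPT = estimator_kf(kf_model(st))(test),
    PROP = estimator_naive(test$code_prop)(test)
  )
  models <- list(refh = fit, opt = kf_model(st))
  wrapL <- if (st$controlled) c(L, test$code_efcp$L) else L
  for (ord in cfg$em_orders) {
    em <- em_lds(obs, order = ord, wrapL = wrapL, n_restarts = cfg$K,
                 seed = traj_seed(cfg$seed, 31000 + ord),
                 val = list(obs = obs, truth = truth))
    nm <- paste0("EM", ord)
    ests[[nm]] <- lapply(obs, function(o) predict.lds_model(em, o))
    models[[nm]] <- em
  }
  if (st$controlled) {
    ob <- obs_fit(test$traj, wrapL = L)
    ests$OBS <- lapply(test$traj, function(tr)
      predict.lds_model(ob, pseudo_obs_seq(tr, test$code_prop)))
    ests$EfCp <- estimator_naive(test$code_efcp, "r_efcp")(test)
    models$obs <- ob
  }
  stats <- do.call(rbind, lapply(names(ests), function(nm) {
    truth_i <- if (nm == "EfCp") lapply(test$traj, `[[`, "u") else truth
    L_i <- if (nm == "EfCp") test$code_efcp$L else L
    es <- error_stats(ests[[nm]], truth_i, L_i, model = nm)
    data.frame(model = nm, mse = es$mse, err_mean = es$mean,
               err_var = es$var, n = es$n)
  }))

  out <- list(stats = stats, models = models, cfg = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(stats, file.path(out_dir, "error_stats.csv"),
                     row.names = FALSE)
    save_model(fit$params, file.path(out_dir, "refh_params.json"))
    preset_to_json(st, file.path(out_dir, "preset.json"))
    writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE),
               file.path(out_dir, "config.json"))
    files <- list.files(out_dir, full.names = TRUE)
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    out$manifest <- manifest
  }
  out
}
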