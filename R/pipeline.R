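#' Configuration of an end-to-end decoding run
#'
#' Bundles every knob of the pipeline into one serializable list. Writes to
#' and reads from JSON losslessly via [write_run_config()] /
#' [read_run_config()].
#'
#' @param seed master seed for simulation, splits and bootstraps.
#' @param n_neurons simulated population size.
#' @param trials_per_condition trials per (position x direction).
#' @param gamma ridge shrinkage.
#' @param lags target-lag grid in ms.
#' @param n_sets cross-validation sets.
#' @param n_boot PCA bootstrap replicates.
#' @param r2_threshold admission threshold for the weight analyses.
#' @param exclusion fixation-only training exclusion half-width in ms.
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1, n_neurons = 100, trials_per_condition = 20,
                       gamma = 30, lags = seq(-400, 400, by = 100),
                       n_sets = 50, n_boot = 200, r2_threshold = 0.75,
                       exclusion = 100) {
  structure(
    list(seed = seed, n_neurons = n_neurons,
         trials_per_condition = trials_per_condition, gamma = gamma,
         lags = lags, n_sets = n_sets, n_boot = n_boot,
         r2_threshold = r2_threshold, exclusion = exclusion),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Run the full decoding pipeline
#'
#' Simulate a session (or use one supplied), bin rates, summarize the
#' direction-specific population dynamics by bootstrap PCA, sweep the
#' target lags with cross-validated decoding and sigmoid parameterization,
#' summarize the pooling weights, and run the fixation-only decoder.
#' Tables are written as CSV and summaries as JSON under `out_dir`, with
#' the configuration embedded.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param session optional `spike_session` to analyze instead of
#'   simulating one.
#' @return (invisibly) a list with `session`, `pca`, `sweep`,
#'   `weight_summary`, `fixation_fit`, `zero_lag_fit`, and `files`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         session = NULL) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[%s] done (%.1f s elapsed)", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  if (is.null(session)) {
    session <- stage("simulate", {
      task <- task_config(trials_per_condition = config$trials_per_condition)
      pop <- sample_population(config$n_neurons, seed = config$seed)
      simulate_session(pop, task, seed = config$seed + 1)
    })
  }
  tensor <- stage("rates", bin_rates(session))
  pca <- stage("pca", {
    rm_all <- condition_average(tensor)
    D <- differential_timecourses(rm_all)
    bootstrap_pca(D, k = 3, n_boot = config$n_boot,
                  seed = config$seed + 2)
  })
  sweep <- stage("lag sweep", {
    lag_sweep(tensor, lags = config$lags, gamma = config$gamma,
              n_sets = config$n_sets, seed = config$seed + 3)
  })
  ws <- stage("weights", {
    pw <- tryCatch(pooling_weights(sweep, r2_threshold = config$r2_threshold),
                   error = function(e) NULL)
    if (is.null(pw)) {
      warning("no target lag passed the peri-saccadic R^2 threshold; ",
              "weight summaries skipped")
      list(pooling = NULL)
    } else {
      list(pooling = pw,
           histogram = weight_histogram(pw),
           modulation = if (ncol(pw) >= 2) weight_modulation(pw),
           consistency = if (ncol(pw) >= 2 && nrow(pw) >= 3)
             weight_consistency(pw))
    }
  })
  fix <- stage("fixation-only", {
    zero <- which(config$lags == 0)
    target0 <- make_target(0)
    dfix <- fixation_only_decoder(tensor, target0, gamma = config$gamma,
                                  exclusion = config$exclusion,
                                  n_sets = config$n_sets,
                                  seed = config$seed + 3,
                                  task = session$task)
    ffix <- fit_sigmoid_joint(dfix$X_hat$rightward$mean,
                              dfix$Y_hat$downward$mean, dfix$times)
    fzero <- if (length(zero) == 1) sweep$fits_raw[[zero]] else {
      d0 <- cross_validate(tensor, target0, gamma = config$gamma,
                           n_sets = config$n_sets, seed = config$seed + 3)
      fit_sigmoid_joint(d0$X_hat$rightward$mean, d0$Y_hat$downward$mean,
                        d0$times)
    }
    list(decoded = dfix, fit = ffix, zero_lag_fit = fzero)
  })

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wf <- function(obj, name, writer) {
      path <- file.path(out_dir, name)
      writer(obj, path)
      files <<- c(files, path)
    }
    wf(config, "config.json", write_run_config)
    wf(sweep$table, "lag_sweep.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    pca_tab <- data.frame(time = tensor$times, pca$components,
                          boot_se = pca$boot_se)
    names(pca_tab) <- c("time", paste0("pc", seq_len(pca$k)),
                        paste0("pc", seq_len(pca$k), "_se"))
    wf(pca_tab, "pca_components.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    decoded_tab <- do.call(rbind, lapply(seq_along(sweep$decoded), function(i) {
      d <- sweep$decoded[[i]]
      do.call(rbind, lapply(names(d$X_hat), function(dir) {
        rbind(
          data.frame(lag = sweep$lags[i], time = d$times, direction = dir,
                     channel = "X", mean = d$X_hat[[dir]]$mean,
                     sd = d$X_hat[[dir]]$sd),
          data.frame(lag = sweep$lags[i], time = d$times, direction = dir,
                     channel = "Y", mean = d$Y_hat[[dir]]$mean,
                     sd = d$Y_hat[[dir]]$sd)
        )
      }))
    }))
    wf(decoded_tab, "decoded_timecourses.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    if (!is.null(ws$pooling)) {
      wf(as.data.frame(ws$pooling), "pooling_weights.csv",
         function(o, p) utils::write.csv(o, p, row.names = FALSE))
    }
    summary <- list(
      seed = config$seed,
      variance_fraction_top3 = sum(pca$variance_fraction[1:3]),
      r2_by_lag = stats::setNames(as.list(sweep$table$r2_full),
                                  as.character(config$lags)),
      r2_peri_by_lag = stats::setNames(as.list(sweep$table$r2_peri),
                                       as.character(config$lags)),
      weight_modulation_mean = if (!is.null(ws$modulation))
        ws$modulation$mean,
      weight_consistency_mean = if (!is.null(ws$consistency))
        ws$consistency$mean,
      fixation_only_mu = fix$fit$mu,
      zero_lag_mu = fix$zero_lag_fit$mu
    )
    wf(summary, "summary.json",
       function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                           digits = NA))
  }

  invisible(list(session = session, tensor = tensor, pca = pca,
                 sweep = sweep, weight_summary = ws,
                 fixation_fit = fix$fit, zero_lag_fit = fix$zero_lag_fit,
                 files = files))
}
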