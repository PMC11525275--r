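#' Default pipeline configuration
#'
#' Returns the fully resolved default configuration for [run_pipeline()].
#' Users override entries with a named list (or a YAML file) containing a
#' subset of these keys; unknown keys are rejected.
#'
#' @return nested named list of pipeline settings.
#' @export
default_pipeline_config <- function() {
  list(
    out_dir = "wmh_pipeline_out",
    seed = 1L,
    k_threshold = 0.7,
    paths = list(phenotypes = NULL, connectomes = NULL, atlas = NULL),
    stages = list(simulate = TRUE, factors = TRUE, assoc = TRUE,
                  plsr = TRUE, resample = TRUE, graph = TRUE, mediate = TRUE),
    simulate = list(),                       # overrides passed to sim_config()
    plsr = list(kfolds = 5L, ncomp_max = 10L),
    resample = list(n_iter = 5000L, masks = c("SUB-SUB", "SUB-DMN", "SUB-FPN",
                                              "SUB-LN", "SUB-SMN", "SUB-VAN",
                                              "SUB-DAN", "SUB-VIS"),
                    ncomp_max = 5L, keep_distributions = FALSE),
    graph = list(gammas = c(1, 1.25, 1.5), n_runs = 100L, tau = 0.5),
    mediate = list(n_boot = 10000L)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  check_that(is.list(user), "config entry '%s' must be a list", path)
  unknown <- setdiff(names(user), names(defaults))
  check_that(length(unknown) == 0, "unknown config key(s)%s: %s",
             if (nzchar(path)) paste0(" under '", path, "'") else "",
             paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, if (nzchar(path)) "/" else "", nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

run_stage <- function(name, log_lines, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  list(value = value,
       log = c(log_lines, sprintf("%s: %.1fs", name,
                                  proc.time()[["elapsed"]] - t0)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages behind one seeded configuration:
#' simulate (optional) -> cognitive factor scores -> correlation tables ->
#' whole-brain PLSR with CV component selection and feature importance ->
#' subnetwork permutation-null resampling -> graph metrics and their
#' association tables -> mediation models. Every stage receives a child
#' seed derived deterministically from the master seed, so stages are
#' individually rerunnable. All declared artifacts (CSV/TSV/JSON), a
#' resolved configuration, a run log, and an md5 manifest are written under
#' `out_dir`.
#'
#' @param config named list overriding [default_pipeline_config()] entries,
#'   or a path to a YAML file with such a list.
#' @return invisible list with the in-memory results of each executed stage
#'   and `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_lines <- c(sprintf("wmhconn %s | R %s", as.character(utils::packageVersion("wmhconn")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("master seed: %d", cfg$seed))
  results <- list()

  k_tag <- if (abs(cfg$k_threshold - 0.5) < 1e-9) "k05" else "k07"
  wmh_col <- paste0("wmh_global_", k_tag)

  # --- inputs / simulation ---------------------------------------------
  if (isTRUE(cfg$stages$simulate)) {
    st <- run_stage("simulate", log_lines, {
      sc_args <- cfg$simulate
      sc_args$seed <- derive_seed(cfg$seed, "simulate")
      sim_cfg <- do.call(sim_config, sc_args)
      atlas <- make_atlas(seed = derive_seed(cfg$seed, "atlas"))
      ph <- simulate_phenotypes(sim_cfg)
      cs <- simulate_connectomes(ph, atlas, sim_cfg)
      write_atlas(atlas, file.path(out, "atlas.tsv"))
      write_phenotypes(ph, file.path(out, "phenotypes.csv"))
      write_connectome_dir(cs, file.path(out, "connectomes"))
      jsonlite::write_json(
        list(seed = sim_cfg$seed,
             loadings = solve_latent_loadings(sim_cfg),
             signal_edges = which(cs$signal_mask)),
        file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
      list(atlas = atlas, phenotypes = ph, connectomes = cs)
    })
    log_lines <- st$log; results[c("atlas", "phenotypes", "connectomes")] <- st$value
  } else {
    st <- run_stage("load", log_lines, {
      atlas <- read_atlas(cfg$paths$atlas)
      ph <- read_phenotypes(cfg$paths$phenotypes)
      cs <- read_connectome_dir(cfg$paths$connectomes, ids = ph$participant_id,
                                n_nodes = nrow(atlas))
      list(atlas = atlas, phenotypes = ph, connectomes = cs)
    })
    log_lines <- st$log; results[c("atlas", "phenotypes", "connectomes")] <- st$value
  }
  atlas <- results$atlas; ph <- results$phenotypes; cs <- results$connectomes
  check_that(wmh_col %in% names(ph), "phenotypes lack WMH column '%s'", wmh_col)

  # --- cognitive factors ------------------------------------------------
  if (isTRUE(cfg$stages$factors)) {
    st <- run_stage("factors", log_lines, {
      ff <- fluid_cognition(ph)
      ph$fluid <- ff$general
      ph <- cbind(ph, stats::setNames(as.data.frame(ff$domains),
                                      paste0("domain_", colnames(ff$domains))))
      write_phenotypes(ph, file.path(out, "factors.csv"))
      list(factors = ff, phenotypes = ph)
    })
    log_lines <- st$log
    results$factors <- st$value$factors
    ph <- st$value$phenotypes
    results$phenotypes <- ph
  }

  # --- correlation tables ----------------------------------------------
  if (isTRUE(cfg$stages$assoc)) {
    st <- run_stage("assoc", log_lines, {
      dat <- ph
      dat$log_wmh <- log_wmh(ph[[wmh_col]])
      pairs <- data.frame(
        x = c("age_years", "age_years", "fluid", "fluid"),
        y = c("fluid", "log_wmh", "log_wmh", "log_wmh"),
        covariates = c("", "", "", "age_years"),
        family = c("zero_order", "zero_order", "zero_order", "partial"),
        stringsAsFactors = FALSE)
      ct <- correlation_table(dat, pairs)
      utils::write.csv(ct, file.path(out, "correlations.csv"), row.names = FALSE)
      ct
    })
    log_lines <- st$log; results$correlations <- st$value
  }

  Y <- cbind(age = ph$age_years,
             fluid = if (!is.null(ph$fluid)) ph$fluid else ph$latent_g,
             wmh = log_wmh(ph[[wmh_col]]))
  X <- connectome_edges(cs)

  # --- whole-brain PLSR -------------------------------------------------
  if (isTRUE(cfg$stages$plsr)) {
    st <- run_stage("plsr", log_lines, {
      cv <- select_components_cv(X, Y, k = cfg$plsr$kfolds,
                                 ncomp_max = cfg$plsr$ncomp_max,
                                 seed = derive_seed(cfg$seed, "plsr"))
      # importance from standardized-outcome fits so no outcome's scale
      # dominates the coefficient magnitudes
      cv_std <- select_components_cv(X, Y, k = cfg$plsr$kfolds,
                                     ncomp_max = cfg$plsr$ncomp_max,
                                     seed = derive_seed(cfg$seed, "plsr"),
                                     standardize_y = TRUE)
      imp <- feature_importance(cv_std$fold_models, cs$edge_map,
                                ncomp = cv_std$ncomp_best)
      jsonlite::write_json(
        list(table = cv$table, baseline_mse = cv$baseline_mse,
             ncomp_best = cv$ncomp_best,
             r2_per_outcome = as.list(cv$r2_per_outcome)),
        file.path(out, "cv_result.json"), auto_unbox = TRUE, digits = NA)
      utils::write.csv(imp$edges, file.path(out, "edge_importance.csv"),
                       row.names = FALSE)
      utils::write.csv(imp$rois, file.path(out, "roi_importance.csv"),
                       row.names = FALSE)
      list(cv = cv, importance = imp)
    })
    log_lines <- st$log; results$plsr <- st$value
  }

  # --- subnetwork resampling -------------------------------------------
  if (isTRUE(cfg$stages$resample)) {
    st <- run_stage("resample", log_lines, {
      masks <- build_masks(atlas, cs$edge_map)
      use <- intersect(cfg$resample$masks, names(masks))
      rr <- lapply(use, function(nm) {
        resample_evaluate(X, Y, mask = masks[[nm]],
                          n_iter = cfg$resample$n_iter,
                          ncomp_max = cfg$resample$ncomp_max,
                          seed = derive_seed(cfg$seed, paste0("resample_", nm)),
                          mask_name = nm)
      })
      names(rr) <- use
      ks_fdr <- bh_fdr(vapply(rr, `[[`, numeric(1), "ks_p"))
      payload <- lapply(seq_along(rr), function(i) {
        r <- rr[[i]]
        base <- list(mask = r$mask_name, n_iter = r$n_iter,
                     ks_stat = r$ks_stat, ks_p = r$ks_p, ks_p_fdr = ks_fdr[i],
                     cohens_d = r$cohens_d, median = r$median_true,
                     pi_low = r$pi_low, pi_high = r$pi_high)
        if (isTRUE(cfg$resample$keep_distributions)) {
          base$true_perf <- r$true_perf; base$null_perf <- r$null_perf
        }
        base
      })
      jsonlite::write_json(payload, file.path(out, "resample.json"),
                           auto_unbox = TRUE, digits = NA)
      rr
    })
    log_lines <- st$log; results$resample <- st$value
  }

  # --- graph metrics ----------------------------------------------------
  if (isTRUE(cfg$stages$graph)) {
    st <- run_stage("graph", log_lines, {
      gm <- graph_metrics(cs, atlas, gammas = cfg$graph$gammas,
                          n_runs = cfg$graph$n_runs, tau = cfg$graph$tau,
                          seed = derive_seed(cfg$seed, "graph"))
      utils::write.csv(gm, file.path(out, "metrics.csv"), row.names = FALSE)
      ma <- metrics_regressions(gm, ph, wmh_col = wmh_col,
                                fluid_col = if (!is.null(ph$fluid)) "fluid" else "latent_g")
      utils::write.csv(ma$regressions, file.path(out, "metrics_regressions.csv"),
                       row.names = FALSE)
      utils::write.csv(ma$correlations, file.path(out, "metrics_correlations.csv"),
                       row.names = FALSE)
      list(metrics = gm, associations = ma)
    })
    log_lines <- st$log; results$graph <- st$value
  }

  # --- mediation --------------------------------------------------------
  if (isTRUE(cfg$stages$mediate)) {
    st <- run_stage("mediate", log_lines, {
      fluid <- if (!is.null(ph$fluid)) ph$fluid else ph$latent_g
      simple <- mediate(ph$age_years, log_wmh(ph[[wmh_col]]), fluid,
                        n_boot = cfg$mediate$n_boot,
                        seed = derive_seed(cfg$seed, "mediate_simple"))
      tract_cols <- grep("^tract_", names(ph), value = TRUE)
      parallel <- NULL
      if (length(tract_cols) >= 2) {
        Mlog <- sapply(ph[tract_cols], log_wmh)
        parallel <- mediate(ph$age_years, Mlog, fluid,
                            n_boot = cfg$mediate$n_boot,
                            seed = derive_seed(cfg$seed, "mediate_parallel"))
      }
      ser <- function(mfit) list(
        direct = mfit$direct, total = mfit$total,
        indirect = mfit$indirect, n = mfit$n, n_boot = mfit$n_boot)
      jsonlite::write_json(
        list(simple = ser(simple),
             parallel = if (is.null(parallel)) NULL else ser(parallel)),
        file.path(out, "mediation.json"), auto_unbox = TRUE, digits = NA)
      list(simple = simple, parallel = parallel)
    })
    log_lines <- st$log; results$mediation <- st$value
  }

  # --- provenance -------------------------------------------------------
  yaml::write_yaml(cfg, file.path(out, "config_resolved.yaml"))
  writeLines(log_lines, file.path(out, "run.log"))
  artifacts <- setdiff(list.files(out, recursive = TRUE),
                       c("manifest.json", "run.log"))
  manifest <- as.list(tools::md5sum(file.path(out, artifacts)))
  names(manifest) <- artifacts
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE)
  results$out_dir <- out
  invisible(results)
}
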