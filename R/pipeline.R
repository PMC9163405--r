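#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis. `preset` selects the
#' window length: `"main22"` (22 TR, the main analysis), `"val20"` or
#' `"val30"` (robustness analyses); all other defaults equal the
#' main-analysis settings. Unknown argument names are rejected up front.
#'
#' @param preset `"main22"`, `"val20"` or `"val30"`.
#' @param ... overrides for: `wspec`, `gcfg`, `k`, `k_range`, `grid`,
#'   `n_replicates`, `n_null`, `seed`, `covariate_columns`,
#'   `n_per_group`, `preprocess`, `residualize`, `synth`.
#' @return object of class `run_config`.
#' @export
run_config <- function(preset = c("main22", "val20", "val30"), ...) {
  preset <- match.arg(preset)
  W <- switch(preset, main22 = 22, val20 = 20, val30 = 30)
  cfg <- list(
    preset = preset,
    wspec = tapered_window_spec(window_length_tr = W),
    gcfg = glasso_config(),
    k = 4L,
    k_range = NULL,          # set to e.g. 2:10 to select k by elbow
    grid = sparsity_grid(),
    n_replicates = 100L,
    n_null = 0L,
    seed = 1L,
    covariate_columns = c("age", "sex", "education", "mean_fd"),
    n_per_group = c(HD = 50, NonD = 50, HC = 64),
    preprocess = FALSE,       # simulated series are already clean
    residualize = TRUE,
    synth = NULL              # synth_spec(); built lazily from seed
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_dynfc("run_config: unknown option(s): %s",
               paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Run the full pipeline on a synthetic (or supplied) cohort
#'
#' Stages: simulate (unless `timecourses`/`covariates` are supplied) ->
#' optional preprocessing -> windowed dynamic FC with graphical-LASSO
#' regularization -> covariate residualization -> k-means state
#' decomposition and temporal metrics -> graph-metric AUC variance ->
#' group statistics (Kruskal-Wallis omnibus + FDR post hocs on temporal
#' and graph-variance measures, partial correlations between temporal
#' metrics and cognitive scores within patients). Fully deterministic
#' given the config seed. When `out_dir` is given, all intermediates are
#' written as TSV/CSV/JSON along with a manifest of seeds and file
#' checksums.
#'
#' @param cfg a [run_config()].
#' @param timecourses optional list of [timecourse()] (else simulated).
#' @param covariates optional covariate data frame.
#' @param out_dir optional output directory.
#' @return list with `stacks`, `model`, `temporal`, `graph_variance`,
#'   `stats`, `covariates`, `truth` (when simulated), `config`.
#' @export
run_pipeline <- function(cfg = run_config(), timecourses = NULL,
                         covariates = NULL, out_dir = NULL) {
  if (nrow_cfg_invalid(cfg))
    stop_dynfc("run_pipeline: window length %d >= timepoints",
               cfg$wspec$window_length_tr)
  truth <- NULL
  if (is.null(timecourses)) {
    synth <- if (is.null(cfg$synth)) synth_spec(seed = cfg$seed) else cfg$synth
    cohort <- simulate_cohort(synth, cfg$n_per_group, seed = cfg$seed)
    timecourses <- cohort$timecourses
    covariates <- cohort$covariates
    truth <- cohort$truth
  }
  if (is.null(covariates))
    stop_dynfc("run_pipeline: covariates are required with supplied data")
  n_sub <- length(timecourses)

  if (cfg$preprocess)
    timecourses <- lapply(timecourses, preprocess_timecourse)

  seeds <- derive_seeds(cfg$seed, n_sub)
  stacks <- lapply(seq_len(n_sub), function(i)
    dynamic_fc(timecourses[[i]], cfg$wspec, cfg$gcfg, seed = seeds[i]))

  if (cfg$residualize)
    stacks <- residualize_covariates(stacks, covariates,
                                     cfg$covariate_columns)

  pooled <- do.call(rbind, lapply(stacks, `[[`, "edge_values"))
  k <- if (!is.null(cfg$k_range))
    elbow_select_k(pooled, cfg$k_range, seed = cfg$seed) else cfg$k
  model <- kmeans_l1(pooled, k, cfg$n_replicates, seed = cfg$seed)

  n_win <- vapply(stacks, `[[`, 0L, "n_windows")
  idx_end <- cumsum(n_win)
  idx_start <- idx_end - n_win + 1L
  temporal <- lapply(seq_len(n_sub), function(i)
    temporal_metrics(model$assignments[idx_start[i]:idx_end[i]], k))

  gvar <- t(vapply(seq_len(n_sub), function(i)
    dynamic_metric_variance(stacks[[i]], cfg$grid, n_null = cfg$n_null,
                            seed = seeds[i])$variance,
    numeric(if (cfg$n_null > 0) 7 else 4)))
  rownames(gvar) <- names(timecourses)

  stats_out <- pipeline_stats(temporal, gvar, covariates, k)

  result <- list(stacks = stacks, model = model, temporal = temporal,
                 graph_variance = gvar, stats = stats_out,
                 covariates = covariates, truth = truth, config = cfg)
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

nrow_cfg_invalid <- function(cfg) {
  n_tp <- if (is.null(cfg$synth)) 170 else cfg$synth$n_timepoints
  cfg$wspec$window_length_tr >= n_tp
}

# group stats on temporal metrics and graph-metric variances, plus
# dwell/transition vs cognition partial correlations within patients
pipeline_stats <- function(temporal, gvar, covariates, k) {
  grp <- factor(covariates$group)
  measures <- data.frame(
    n_transitions = vapply(temporal, `[[`, 0L, "n_transitions"))
  for (s in seq_len(k)) {
    measures[[paste0("frac_state", s)]] <-
      vapply(temporal, function(m) m$fractional_windows[s], 0)
    measures[[paste0("dwell_state", s)]] <-
      vapply(temporal, function(m) m$mean_dwell[s], 0)
  }
  measures <- cbind(measures, as.data.frame(gvar))
  omni <- lapply(names(measures), function(nm) {
    v <- measures[[nm]]
    if (length(unique(v)) == 1)
      return(data.frame(measure = nm, H = NA, p = NA))
    kw <- kruskal_wallis(v, grp)
    data.frame(measure = nm, H = kw$statistic, p = kw$p)
  })
  omni <- do.call(rbind, omni)
  bh <- fdr_bh(omni$p[is.finite(omni$p)])
  omni$q <- NA_real_
  omni$q[is.finite(omni$p)] <- bh$q

  posthoc <- lapply(omni$measure[which(omni$q < 0.05)], function(nm)
    cbind(measure = nm,
          posthoc_pairwise(measures[[nm]], grp, test = "rank")))
  posthoc <- if (length(posthoc)) do.call(rbind, posthoc) else NULL

  pat <- covariates$group != "HC"
  cogs <- intersect(c("TMT_A", "TMT_B", "MMSE", "MoCA", "SDMT"),
                    names(covariates))
  pc_cov <- covariates[pat, intersect(c("age", "sex", "education",
                                        "disease_duration", "mean_fd"),
                                      names(covariates)), drop = FALSE]
  if ("disease_duration" %in% names(pc_cov) &&
      any(is.na(pc_cov$disease_duration)))
    pc_cov$disease_duration <- NULL
  cors <- list()
  for (met in intersect(c("dwell_state3", "n_transitions"),
                        names(measures))) {
    for (cg in cogs) {
      pc <- tryCatch(
        partial_correlation(measures[[met]][pat],
                            covariates[[cg]][pat], pc_cov),
        error = function(e) NULL)  # too few patients for the covariate set
      if (is.null(pc)) next
      cors[[paste(met, cg, sep = "~")]] <-
        data.frame(metric = met, score = cg, r = pc$r, p = pc$p, n = pc$n)
    }
  }
  list(omnibus = omni, posthoc = posthoc,
       correlations = if (length(cors)) do.call(rbind, cors) else NULL,
       measures = measures)
}

# write all intermediates + manifest
write_run <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_covariates(result$covariates, file.path(out_dir, "covariates.csv"))
  stack_dir <- file.path(out_dir, "stacks")
  dir.create(stack_dir, showWarnings = FALSE)
  for (s in result$stacks)
    write_fc_stack(s, file.path(stack_dir, paste0(s$subject_id, ".tsv")))
  ids <- vapply(result$stacks, `[[`, "", "subject_id")
  write_state_model(result$model,
                    rep(ids, vapply(result$stacks, `[[`, 0L, "n_windows")),
                    file.path(out_dir, "states"))
  write_temporal_metrics(result$temporal, ids,
                         file.path(out_dir, "temporal_metrics.csv"))
  write.csv(cbind(subject = rownames(result$graph_variance),
                  as.data.frame(result$graph_variance)),
            file.path(out_dir, "graph_variance.csv"), row.names = FALSE)
  write.csv(result$stats$omnibus, file.path(out_dir, "stats_omnibus.csv"),
            row.names = FALSE)
  if (!is.null(result$stats$correlations))
    write.csv(result$stats$correlations,
              file.path(out_dir, "stats_correlations.csv"),
              row.names = FALSE)
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    preset = result$config$preset,
    seed = result$config$seed,
    k = result$model$k,
    objective = result$model$objective,
    r_version = as.character(getRversion()),
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
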