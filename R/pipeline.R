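#' Build and validate a pipeline configuration
#'
#' Collects input paths and analysis parameters for
#' [run_noise_pipeline()]. All referenced input files must exist at
#' validation time; a missing file fails here, before any computation.
#'
#' @param out_dir output directory (created if absent).
#' @param events path to an event TSV ([write_event_tsv()]); alternatively
#'   pass `truth` to stream a synthetic study without an event file.
#' @param network path to a network edge-list TSV (optional).
#' @param growth_rates path to a growth-rate TSV (optional).
#' @param features path to an external gene-feature TSV (optional).
#' @param truth a `noise_ground_truth` to summarize in streaming mode.
#' @param q,n_bins noise-floor envelope settings.
#' @param lambda ridge penalty or `"auto"`.
#' @param k_folds cross-validation folds for `lambda = "auto"`.
#' @param n_shuffles permutations for the FOV null.
#' @param background background threshold on mean log-fluorescence
#'   (`-Inf`: keep all).
#' @param seed master seed; all stage seeds derive from it.
#' @return validated config (class `noise_pipeline_config`).
#' @export
noise_pipeline_config <- function(out_dir, events = NULL, network = NULL,
                                  growth_rates = NULL, features = NULL,
                                  truth = NULL, q = 0.05, n_bins = 20L,
                                  lambda = "auto", k_folds = 10L,
                                  n_shuffles = 100L, background = -Inf,
                                  seed = 1L) {
  if (is.null(events) && is.null(truth)) {
    stopf("either an events path or a ground truth must be given")
  }
  for (p in c(events, network, growth_rates, features)) {
    if (!file.exists(p)) stopf("input file not found: %s", p)
  }
  if (!is.null(truth)) stopifnot(inherits(truth, "noise_ground_truth"))
  structure(
    list(out_dir = out_dir, events = events, network = network,
         growth_rates = growth_rates, features = features, truth = truth,
         q = q, n_bins = as.integer(n_bins), lambda = lambda,
         k_folds = as.integer(k_folds),
         n_shuffles = as.integer(n_shuffles), background = background,
         seed = as.integer(seed)),
    class = "noise_pipeline_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full noise pipeline
#'
#' Executes the stages in order — summarize, floor, noise, propagate,
#' stats, pca — writing each stage's TSV artifacts to `out_dir` before the
#' next stage starts, plus a machine-readable JSON run manifest recording
#' the package version, seed and parameters. Reruns with the same
#' configuration and seed produce bit-identical outputs.
#'
#' Stages depending on missing inputs are skipped: propagation and the
#' regulatory statistics require a network; the growth-rate regression
#' requires growth rates; the PCA uses external features when provided and
#' otherwise the measured features alone.
#'
#' @param config a `noise_pipeline_config`.
#' @return (invisibly) list of in-memory stage results, with
#'   `$out_dir` and `$files` listing the artifacts written.
#' @export
run_noise_pipeline <- function(config) {
  stopifnot(inherits(config, "noise_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  emit <- function(obj, name, writer = tsv_write) {
    writer(obj, out(name))
    files <<- c(files, name)
  }

  ## -- summarize ------------------------------------------------------
  summaries <- run_stage("summarize", {
    s <- if (!is.null(config$truth)) {
      summarize_study(config$truth)
    } else {
      summarize_events(read_event_tsv(config$events))
    }
    s <- summarize_replicates(s)
    filter_above_background(s, config$background)
  })
  emit(summaries, "summaries.tsv")

  ## -- floor + noise --------------------------------------------------
  nl <- run_stage("floor", {
    noise_level_matrix(summaries, q = config$q, n_bins = config$n_bins)
  })
  floor_tab <- data.frame(
    condition_id = names(nl$fits),
    a = vapply(nl$fits, function(f) f$a, numeric(1L)),
    b = vapply(nl$fits, function(f) f$b, numeric(1L)),
    n_promoters = vapply(nl$fits, function(f) f$n_points, numeric(1L)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  growth_fit <- NULL
  if (!is.null(config$growth_rates)) {
    growth <- read_growth_rate_tsv(config$growth_rates)
    rate <- growth$growth_rate[match(floor_tab$condition_id,
                                     growth$condition_id)]
    floor_tab$growth_rate <- rate
    growth_fit <- run_stage("floor", floor_vs_growth_rate(nl$fits, rate))
    emit(data.frame(growth_fit), "floor_vs_growth.tsv")
  }
  emit(floor_tab, "noise_floor.tsv")
  emit(nl$noise, "noise_matrix.tsv", write_noise_matrix_tsv)
  emit(nl$mean, "mean_matrix.tsv", write_noise_matrix_tsv)

  ## -- propagate ------------------------------------------------------
  estimates <- shuffle <- propagators <- NULL
  S <- NULL
  if (!is.null(config$network)) {
    run_stage("propagate", {
      S <- read_network_tsv(config$network, promoters = rownames(nl$noise))
      estimates <- infer_activities(
        nl$noise, S, lambda = config$lambda, k_folds = config$k_folds,
        seed = child_seed(config$seed, 1L), unannotated = "zero")
      shuffle <- randomized_fov(
        nl$noise, S, lambda = estimates$lambda,
        n_shuffles = config$n_shuffles,
        seed = child_seed(config$seed, 2L), unannotated = "zero")
      propagators <- condition_specific_propagators(estimates)
    })
    act <- data.frame(regulator = rownames(estimates$A), estimates$A,
                      check.names = FALSE, stringsAsFactors = FALSE)
    err <- data.frame(regulator = rownames(estimates$delta),
                      estimates$delta, check.names = FALSE,
                      stringsAsFactors = FALSE)
    emit(act, "activities.tsv")
    emit(err, "activity_errors.tsv")
    emit(data.frame(condition_id = names(estimates$fov),
                    fov = unname(estimates$fov),
                    shuffled_mean = unname(shuffle$mean),
                    shuffled_sd = unname(shuffle$sd),
                    shuffled_sem = unname(shuffle$sem)),
         "fov_report.tsv")
    emit(propagators$specific, "condition_specific_propagators.tsv")
    emit(average_activities(estimates)$table, "average_activities.tsv")
  }

  ## -- stats ----------------------------------------------------------
  plast <- run_stage("stats", {
    compute_plasticities(nl$mean, nl$noise, network = S)
  })
  emit(plast, "plasticities.tsv")
  if (!is.null(S)) {
    run_stage("stats", {
      emit(inputs_above_cutoff_curve(plast), "inputs_above_cutoff.tsv")
      emit(fraction_regulated_curve(plast), "fraction_regulated.tsv")
      emit(plasticity_by_input_group(plast)$tests,
           "plasticity_group_tests.tsv")
    })
  }

  ## -- pca ------------------------------------------------------------
  pca <- run_stage("pca", {
    feat <- if (!is.null(config$features)) {
      assemble_feature_table(plast, nl$mean,
                             read_feature_tsv(config$features))
    } else {
      measured <- c(if (!is.null(S)) "n_inputs", "expression_plasticity",
                    "mean_noise", "noise_plasticity")
      data.frame(gene_id = plast$promoter_id,
                 mean_expression = rowMeans(nl$mean)[plast$promoter_id],
                 plast[, measured, drop = FALSE],
                 stringsAsFactors = FALSE)
    }
    corr <- correlation_matrix(feat)
    p <- pca_of_correlation(corr, repair = TRUE)
    emit(data.frame(feature = rownames(corr$R), corr$R, check.names = FALSE),
         "feature_correlation.tsv")
    emit(data.frame(component = paste0("PC", seq_along(p$eigenvalues)),
                    eigenvalue = p$eigenvalues,
                    variance_fraction = p$variance_fraction),
         "pca_eigenvalues.tsv")
    emit(data.frame(feature = rownames(p$loadings), p$loadings,
                    check.names = FALSE),
         "pca_loadings.tsv")
    p
  })

  ## -- manifest -------------------------------------------------------
  manifest <- list(
    package = "noisenet",
    version = as.character(utils::packageVersion("noisenet")),
    seed = config$seed,
    parameters = list(q = config$q, n_bins = config$n_bins,
                      lambda = config$lambda, k_folds = config$k_folds,
                      n_shuffles = config$n_shuffles,
                      background = config$background),
    inputs = list(events = config$events, network = config$network,
                  growth_rates = config$growth_rates,
                  features = config$features,
                  synthetic = !is.null(config$truth)),
    outputs = files
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files <- c(files, "manifest.json")

  invisible(list(
    out_dir = config$out_dir, files = files, summaries = summaries,
    noise = nl, floor = floor_tab, growth_fit = growth_fit,
    estimates = estimates, shuffle = shuffle, propagators = propagators,
    plasticities = plast, pca = pca
  ))
}
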