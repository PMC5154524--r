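# Configuration handling and the simulate -> cluster -> evaluate pipeline.

#' Run configuration
#'
#' Assembles the configuration of a full benchmark run. Either a simulated
#' dataset (the default; see [sim_config()]) or an external MRC/MRCS stack
#' (`input_stack`) provides the images.
#'
#' @param algorithm one of `"ack"`, `"kmeans"`, `"eqk"`, `"spider"`.
#' @param k number of classes.
#' @param beta balance weight (ACK-means only).
#' @param sigma0 termination threshold.
#' @param max_iter iteration cap.
#' @param seed master seed; stage seeds are derived as documented in
#'   [run_pipeline()].
#' @param dissim `"sq_euclid"`, `"euclid"` or `"aligned"`.
#' @param rot_step,max_shift alignment grid parameters for
#'   `dissim = "aligned"`.
#' @param simulator list of [sim_config()] overrides (e.g. `n_centers`,
#'   `per_center`, `snr`).
#' @param input_stack optional path to an MRC/MRCS stack to cluster
#'   instead of simulating.
#' @param truth optional path to a ground-truth CSV (as written by the
#'   simulate stage) for evaluation of an external stack.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(algorithm = c("ack", "kmeans", "eqk", "spider"),
                       k = 20L, beta = 0.5, sigma0 = 0.01, max_iter = 100L,
                       seed = 1L, dissim = c("sq_euclid", "euclid", "aligned"),
                       rot_step = 10, max_shift = 2L, simulator = list(),
                       input_stack = NULL, truth = NULL) {
  algorithm <- match.arg(algorithm)
  dissim <- match.arg(dissim)
  structure(list(algorithm = algorithm, k = as.integer(k), beta = beta,
                 sigma0 = sigma0, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), dissim = dissim,
                 rot_step = rot_step, max_shift = as.integer(max_shift),
                 simulator = simulator, input_stack = input_stack,
                 truth = truth),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Accepts the keys of [run_config()]; the `simulator` key may be a nested
#' mapping of [sim_config()] fields.
#'
#' @param path YAML file path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

config_dissim_spec <- function(config) {
  dissim_spec(config$dissim,
              grid = alignment_grid(rotation_step = config$rot_step,
                                    max_shift = config$max_shift))
}

#' Write / read an assignment table
#'
#' CSV with columns `image_index` (1-based), `class_0based`,
#' `class_1based`.
#'
#' @param assignment 0-based label vector.
#' @param path CSV path.
#' @return `read_assignment_csv()` returns the 0-based label vector.
#' @export
write_assignment_csv <- function(assignment, path) {
  df <- data.frame(image_index = seq_along(assignment),
                   class_0based = as.integer(assignment),
                   class_1based = as.integer(assignment) + 1L)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignment_csv
#' @export
read_assignment_csv <- function(path) {
  df <- utils::read.csv(path)
  as.integer(df$class_0based)
}

write_truth_csv <- function(dataset, path) {
  df <- data.frame(image_index = seq_len(nrow(dataset$orientations)),
                   phi = dataset$orientations$phi,
                   theta = dataset$orientations$theta,
                   psi = dataset$orientations$psi,
                   center_index = dataset$orientations$center_index,
                   defocus_um = dataset$ctf$defocus_um,
                   snr = dataset$snr)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_truth_csv <- function(path) {
  utils::read.csv(path)
}

write_diagnostics_csv <- function(result, path) {
  df <- data.frame(iter = seq_len(result$n_iter),
                   sigma = result$sigma_history,
                   d_c = result$dc_history,
                   two_lambda = result$lambda_history,
                   J = result$objective_history)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the simulate -> cluster -> evaluate pipeline
#'
#' Executes the configured stages and writes all artifacts under
#' `out_dir`: the simulated stack (`stack.mrcs`) and ground truth
#' (`truth.csv`) when simulating; the assignment table
#' (`assignments.csv`), per-iteration diagnostics (`diagnostics.csv`) and
#' class averages (`class_averages.mrcs`) from clustering; the size curve
#' (`size_curve.csv`) and, when ground truth is available, the angular
#' histogram (`angular_histogram.csv`); and a provenance record
#' (`provenance.json` with the full configuration, derived stage seeds and
#' package version). Identical configuration and seed give identical
#' artifacts. Stage seeds: simulation `seed + 100`, clustering
#' `seed + 200`.
#'
#' @param config a [run_config()] (or path to a YAML file).
#' @param out_dir output directory (created if missing).
#' @return Invisible list with the clustering result, evaluation report
#'   and artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  truth <- NULL
  if (is.null(config$input_stack)) {
    dataset <- run_stage("simulate", {
      sc <- do.call(sim_config, c(config$simulator,
                                  list(seed = config$seed + 100L)))
      simulate_dataset(sc)
    })
    stack <- dataset$stack
    truth <- dataset$orientations
    paths$stack <- file.path(out_dir, "stack.mrcs")
    write_mrc_stack(stack, paths$stack,
                    pixel_size = dataset$ctf$pixel_size[1])
    paths$truth <- file.path(out_dir, "truth.csv")
    write_truth_csv(dataset, paths$truth)
  } else {
    stack <- run_stage("load", read_mrc_stack(config$input_stack))
    if (!is.null(config$truth)) truth <- read_truth_csv(config$truth)
  }

  result <- run_stage("cluster", {
    params <- ack_params(beta = config$beta, sigma0 = config$sigma0,
                         max_iter = config$max_iter,
                         seed = config$seed + 200L)
    fn <- switch(config$algorithm, ack = ack_means, kmeans = kmeans_baseline,
                 eqk = eqk_means, spider = spider_kmeans)
    fn(stack, config$k, params, config_dissim_spec(config))
  })
  paths$assignments <- file.path(out_dir, "assignments.csv")
  write_assignment_csv(result$labels, paths$assignments)
  paths$diagnostics <- file.path(out_dir, "diagnostics.csv")
  write_diagnostics_csv(result, paths$diagnostics)
  paths$class_averages <- file.path(out_dir, "class_averages.mrcs")
  write_mrc_stack(image_stack(result$centroids, result$image_side),
                  paths$class_averages)

  report <- run_stage("evaluate", {
    evaluate_clustering(result, orientations = truth)
  })
  paths$size_curve <- file.path(out_dir, "size_curve.csv")
  utils::write.csv(data.frame(rank = seq_along(report$size_curve),
                              size = report$size_curve),
                   paths$size_curve, row.names = FALSE)
  if (!is.null(report$angular_histogram)) {
    h <- report$angular_histogram
    paths$angular_histogram <- file.path(out_dir, "angular_histogram.csv")
    utils::write.csv(data.frame(bin_low = h$bin_edges[-length(h$bin_edges)],
                                bin_high = h$bin_edges[-1],
                                frequency = h$frequencies),
                     paths$angular_histogram, row.names = FALSE)
  }

  paths$provenance <- file.path(out_dir, "provenance.json")
  prov <- list(
    config = config[setdiff(names(config), "volume")],
    stage_seeds = list(simulate = config$seed + 100L,
                       cluster = config$seed + 200L),
    package = "ackmeans",
    version = as.character(utils::packageVersion("ackmeans")))
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(result = result, report = report, paths = paths))
}

run_stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}
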