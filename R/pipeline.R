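#' Serialise a dictionary fit as JSON
#'
#' Writes the configuration snapshot, eps diagnostics, calibrated threshold
#' and the dictionary entries. Supports are serialised as 0-based unit
#' indices (the behaviour unit of a neuro-behavioural dataset is index 0).
#'
#' @param fit an [isingdict()] fit.
#' @param file output path; \code{NULL} returns the JSON string.
#' @return the path (or JSON string), invisibly.
#' @export
write_dictionary_json <- function(fit, file = NULL) {
  d <- fit$dictionary
  obj <- list(
    config = list(k_max = fit$config$k_max,
                  absent_threshold = fit$config$absent_threshold,
                  n_max = fit$config$n_max,
                  n_false = fit$n_false, shuffles = fit$shuffles,
                  seed = fit$seed),
    data = list(M = fit$M, N = fit$N,
                behavior_index = if (is.null(fit$behavior_col)) NULL else
                  fit$behavior_col - 1L,
                flipped_columns = which(fit$flip_mask) - 1L),
    eps = list(eps1 = fit$trajectory$eps1, eps2 = fit$trajectory$eps2,
               eps_max = fit$trajectory$eps_max,
               converged = all(fit$trajectory$converged)),
    threshold = fit$threshold,
    entries = lapply(seq_len(nrow(d)), function(i) list(
      support = d$support[[i]] - 1L,
      order = d$order[i],
      n_mu = d$n_mu[i],
      null_mean = d$null_mean[i],
      magnetization = d$magnetization[i],
      direction = d$direction[i],
      codeword = d$codeword[i])))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(file)) return(invisible(as.character(json)))
  writeLines(json, file)
  invisible(file)
}

#' Write the dictionary as a flat delimited table
#'
#' @param fit an [isingdict()] fit.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_dictionary_table <- function(fit, file) {
  d <- fit$dictionary
  flat <- data.frame(
    support = vapply(d$support, function(s) paste(s - 1L, collapse = ";"),
                     character(1)),
    order = d$order, n_mu = d$n_mu, null_mean = d$null_mean,
    magnetization = d$magnetization, h = d$h,
    direction = d$direction, codeword = d$codeword)
  write.table(flat, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Assemble a pipeline run configuration
#'
#' All randomness downstream flows from the single \code{seed}.
#'
#' @param input path to a delimited binary matrix, or to a trial file
#'   (\code{input_type = "trials"}).
#' @param input_type \code{"matrix"} or \code{"trials"}.
#' @param seed root seed (default 1).
#' @param k_max,absent_threshold,n_max candidate settings.
#' @param n_false,shuffles calibration settings.
#' @param flip apply [flip_majority_columns()] first.
#' @param behavior_col behaviour unit (1-based); for trial input this is
#'   forced to 1.
#' @param feature,scheme,lo,hi,index,polarity,bin_width,window encoding
#'   settings for trial input (see [binarize_behavior()],
#'   [binarize_spikes()]).
#' @param validate also run [compare_predictors()] (trial input only).
#' @param lambda ridge penalty for validation.
#' @param header does a matrix input file carry a header row?
#' @return a list of class \code{"run_config"}.
#' @export
run_config <- function(input, input_type = c("matrix", "trials"), seed = 1L,
                       k_max = 5L, absent_threshold = 0.02, n_max = 500L,
                       n_false = 0.5, shuffles = 100L, flip = FALSE,
                       behavior_col = NULL, feature = NULL,
                       scheme = "median", lo = 0, hi = 20, index = 1L,
                       polarity = "above", bin_width = 2, window = 40,
                       validate = FALSE, lambda = 0.1, header = FALSE) {
  input_type <- match.arg(input_type)
  structure(list(input = input, input_type = input_type, seed = as.integer(seed),
                 k_max = k_max, absent_threshold = absent_threshold,
                 n_max = n_max, n_false = n_false, shuffles = shuffles,
                 flip = flip, behavior_col = behavior_col, feature = feature,
                 scheme = scheme, lo = lo, hi = hi, index = index,
                 polarity = polarity, bin_width = bin_width, window = window,
                 validate = validate, lambda = lambda, header = header),
            class = "run_config")
}

#' Read or write a run configuration as JSON
#'
#' Configurations round-trip losslessly.
#'
#' @param config a [run_config()].
#' @param file path.
#' @return [write_run_config()] returns \code{file}; [read_run_config()] a
#'   \code{"run_config"}.
#' @export
write_run_config <- function(config, file) {
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  obj <- jsonlite::fromJSON(file)
  do.call(run_config, obj[!vapply(obj, is.null, logical(1))])
}

#' Run the full pipeline and write artifacts
#'
#' Stages: read input (binarising trial data if needed), fit the dictionary
#' with shuffle calibration, optionally validate predictive power, and write
#' the dictionary (JSON + table), candidate statistics, fields/couplings,
#' magnetizations and a JSON run manifest into \code{output_dir}.
#'
#' @param config a [run_config()] or path to its JSON.
#' @param output_dir output directory (created if missing).
#' @return the [isingdict()] fit, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  if (config$input_type == "trials") {
    trials <- read_trials(config$input)
    feature <- config$feature
    if (is.null(feature)) feature <- names(trials$features)[1L]
    spikes <- binarize_spikes(trials, config$bin_width, config$window)
    bits <- binarize_behavior(trials$features[[feature]], config$scheme,
                              lo = config$lo, hi = config$hi,
                              index = config$index, polarity = config$polarity)
    data <- assemble_neurobehavioral(bits, spikes, feature = feature)
    behavior_col <- 1L
  } else {
    data <- read_binary_dataset(config$input, header = config$header)
    behavior_col <- config$behavior_col
    spikes <- NULL
  }

  fit <- isingdict(data, k_max = config$k_max,
                   absent_threshold = config$absent_threshold,
                   n_max = config$n_max, n_false = config$n_false,
                   shuffles = config$shuffles, flip = config$flip,
                   behavior_col = behavior_col)

  write_dictionary_json(fit, file.path(output_dir, "dictionary.json"))
  write_dictionary_table(fit, file.path(output_dir, "dictionary.tsv"))
  write_candidates(fit$candidates, file.path(output_dir, "candidates.tsv"))
  write_ising_system(fit$system, file.path(output_dir, "ising"))
  write.table(data.frame(
      support = vapply(fit$system$supports,
                       function(s) paste(s - 1L, collapse = ";"), character(1)),
      magnetization = fit$trajectory$m_final),
    file.path(output_dir, "magnetizations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  validation <- NULL
  if (isTRUE(config$validate) && config$input_type == "trials")
    validation <- compare_predictors(spikes, data[, 1L], fit,
                                     lambda = config$lambda,
                                     cv_seed = config$seed)
  if (!is.null(validation))
    write.table(validation, file.path(output_dir, "validation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "isingdict",
    version = as.character(utils::packageVersion("isingdict")),
    seed = config$seed,
    M = fit$M, N = fit$N,
    candidates_enumerated = nrow(fit$candidates),
    candidates_retained = length(fit$system$h),
    eps = list(eps1 = fit$trajectory$eps1, eps2 = fit$trajectory$eps2,
               eps_max = fit$trajectory$eps_max),
    threshold = fit$threshold,
    dictionary_size = nrow(fit$dictionary),
    codewords = sum(fit$dictionary$codeword),
    validated = !is.null(validation))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(output_dir, "manifest.json"))
  invisible(fit)
}
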