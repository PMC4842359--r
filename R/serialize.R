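# JSON persistence for projection models, networks and evaluation reports.
# Matrices are stored row-major with explicit dimensions; all files
# round-trip (read -> write -> read) to equality.

.mat_to_json <- function(M) {
  list(nrow = nrow(M), ncol = ncol(M), values = as.vector(t(M)))
}

.mat_from_json <- function(x) {
  matrix(unlist(x$values), nrow = x$nrow, ncol = x$ncol, byrow = TRUE)
}

#' Save / load a CKA projection model as JSON
#'
#' @param model a `"cka_projection"` from [fit_cka_projection()].
#' @param path file path.
#' @return `write_projection_json()` returns `path` invisibly;
#'   `read_projection_json()` returns the restored `"cka_projection"`.
#' @export
write_projection_json <- function(model, path) {
  obj <- list(
    type = "cka_projection",
    W = .mat_to_json(model$W),
    trace = list(iteration = model$trace$iteration, rho = model$trace$rho),
    rho = model$rho,
    relevance = as.vector(model$relevance),
    relevance_raw = as.vector(model$relevance_raw),
    config = unclass(model$config),
    seed = model$seed,
    center = model$center,
    scale = model$scale,
    feature_names = model$feature_names
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_projection_json
#' @export
read_projection_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "cka_projection")) {
    stop("not a projection model file: ", path)
  }
  structure(list(
    W = .mat_from_json(obj$W),
    trace = data.frame(iteration = as.integer(obj$trace$iteration),
                       rho = as.numeric(obj$trace$rho)),
    rho = obj$rho,
    relevance = as.numeric(obj$relevance),
    relevance_raw = as.numeric(obj$relevance_raw),
    config = structure(obj$config, class = "cka_optimizer_config"),
    seed = as.integer(obj$seed),
    center = if (is.null(obj$center)) NULL else as.numeric(obj$center),
    scale = if (is.null(obj$scale)) NULL else as.numeric(obj$scale),
    feature_names = obj$feature_names
  ), class = "cka_projection")
}

#' Save / load network parameters as JSON
#'
#' @param params an `"nn_params"` network.
#' @param path file path.
#' @return `write_network_json()` returns `path` invisibly;
#'   `read_network_json()` returns the restored `"nn_params"`.
#' @export
write_network_json <- function(params, path) {
  obj <- list(
    type = "nn_params",
    sizes = params$sizes,
    strategy = params$strategy,
    seed = params$seed,
    center = params$center,
    scale = params$scale,
    layers = lapply(params$layers, function(l) {
      list(W = .mat_to_json(l$W), b = as.vector(l$b))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "nn_params")) stop("not a network file: ", path)
  layers <- if (is.data.frame(obj$layers)) {
    lapply(seq_len(nrow(obj$layers)), function(i) {
      list(W = .mat_from_json(obj$layers$W[i, ]), b = unlist(obj$layers$b[i]))
    })
  } else {
    lapply(obj$layers, function(l) list(W = .mat_from_json(l$W), b = unlist(l$b)))
  }
  structure(list(layers = layers, sizes = as.integer(obj$sizes),
                 strategy = obj$strategy, seed = as.integer(obj$seed),
                 center = if (is.null(obj$center)) NULL else as.numeric(obj$center),
                 scale = if (is.null(obj$scale)) NULL else as.numeric(obj$scale)),
            class = "nn_params")
}

#' Save an evaluation report
#'
#' Writes the full per-class detail (confusion matrix, metrics and ROC
#' operating points) as JSON, and optionally the scalar summary as a
#' one-row CSV.
#'
#' @param report an `"eval_report"` from [evaluate_classifier()].
#' @param path JSON output path.
#' @param csv_path optional CSV output path for the scalar metrics.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, csv_path = NULL) {
  obj <- list(
    type = "eval_report",
    class_names = report$class_names,
    confusion = .mat_to_json(unname(report$confusion)),
    alpha = report$alpha,
    tau = as.vector(report$tau),
    beta = report$beta,
    beta_per_class = as.vector(report$beta_per_class),
    n_per_class = as.vector(report$n_per_class),
    roc = lapply(report$roc, function(r) {
      if (is.null(r)) NULL else list(fpr = r$fpr, tpr = r$tpr)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  if (!is.null(csv_path)) {
    row <- c(alpha = report$alpha,
             stats::setNames(report$tau, paste0("tau_", report$class_names)),
             beta = report$beta,
             stats::setNames(report$beta_per_class,
                             paste0("beta_", report$class_names)))
    utils::write.csv(as.data.frame(t(row)), csv_path, row.names = FALSE)
  }
  invisible(path)
}
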