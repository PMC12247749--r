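record_columns <- c(
  "pulse_index", "time_s", "phase", "pressure_mpa",
  paste0("h", 2:8), paste0("uh", 1:7), "h4_db", "broadband_db",
  "is_event", "prediction", "safety_action", "concentration", "instability"
)

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Save a sonication record
#'
#' Writes the per-pulse log as CSV (UTF-8, '.' decimal separator, one row
#' per pulse, full numeric precision) and a JSON manifest (same path with
#' \code{.json} appended) echoing protocol, subject, generator parameters,
#' controller label and seed -- sufficient to re-run bit-identically.
#'
#' @param record a \code{sonication_record}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
save_record <- function(record, path) {
  stopifnot(inherits(record, "sonication_record"))
  p <- record$pulses[, record_columns]
  out <- p
  for (cc in names(out)) {
    if (is.numeric(out[[cc]]) && !cc %in% c("pulse_index", "is_event",
                                            "prediction")) {
      out[[cc]] <- fmt_num(out[[cc]])
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  manifest <- list(
    package_version = as.character(utils::packageVersion("mbfus")),
    controller_label = record$controller_label,
    seed = record$seed,
    protocol = unclass(record$protocol),
    subject = unclass(record$subject),
    params = unclass(record$params)
  )
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a sonication record
#'
#' Reads a CSV written by \code{\link{save_record}} (and its JSON manifest if
#' present). Unknown extra columns are accepted with a warning and ignored;
#' a missing required column is an error naming it.
#'
#' @param path CSV path.
#' @return A \code{sonication_record}.
#' @export
load_record <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty record file: ", path, call. = FALSE)
  missing <- setdiff(record_columns, names(df))
  if (length(missing) > 0L) {
    stop("record file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), record_columns)
  if (length(extra) > 0L) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  df <- df[, record_columns]
  mpath <- paste0(path, ".json")
  protocol <- sonication_protocol()
  subject <- NULL
  params <- NULL
  label <- "unknown"
  seed <- NA_integer_
  if (file.exists(mpath)) {
    man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    protocol <- do.call(sonication_protocol, man$protocol[
      setdiff(names(man$protocol), "n_pulses")])
    subject <- do.call(subject_model, man$subject)
    params <- do.call(generator_params, man$params)
    label <- man$controller_label
    seed <- man$seed
  }
  structure(
    list(protocol = protocol, subject = subject, params = params,
         controller_label = label, seed = seed, pulses = df),
    class = "sonication_record"
  )
}

#' Save / load a trained predictor as portable structured text
#'
#' JSON with layer shapes, weights, the feature scaler, the decision
#' threshold and a training manifest; round-trips at full precision.
#'
#' @param model an \code{mlp_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(
    type = "mlp", input_dim = nrow(model$W1), hidden = model$hidden,
    W1 = model$W1, b1 = model$b1, w2 = model$w2, b2 = model$b2,
    center = model$center, scale = model$scale, threshold = model$threshold,
    feature_names = model$feature_names,
    manifest = list(stop_reason = model$stop_reason,
                    epochs_run = length(model$history),
                    final_sse = if (length(model$history)) tail(model$history, 1) else NA,
                    seed = model$config$seed)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "mlp")) stop("not an mlp model file", call. = FALSE)
  structure(
    list(W1 = matrix(unlist(obj$W1), obj$input_dim, obj$hidden),
         b1 = as.numeric(obj$b1), w2 = as.numeric(obj$w2),
         b2 = as.numeric(obj$b2), center = as.numeric(obj$center),
         scale = as.numeric(obj$scale), threshold = obj$threshold,
         feature_names = obj$feature_names, hidden = obj$hidden,
         history = numeric(0), stop_reason = obj$manifest$stop_reason,
         config = list(seed = obj$manifest$seed)),
    class = "mlp_model"
  )
}

config_defaults <- function() {
  list(
    protocol = list(), subject = list(), generator = list(),
    controllers = list(list(kind = "CL", target_db = 36)),
    predictor = list(feature_set = 12, train_runs = 40, epochs = 200,
                     pressure_range = c(0.12, 0.40), tumor_fraction = 0.3),
    output_dir = ".", seed = 1
  )
}

#' Load and validate an experiment configuration
#'
#' JSON with blocks \code{protocol}, \code{subject}, \code{generator},
#' \code{controllers} (a list of controller blocks), \code{predictor},
#' \code{output_dir} and \code{seed}. Defaults are filled from the package
#' constructors; unknown keys anywhere are rejected with the path to the
#' offending key.
#'
#' @param path JSON config path.
#' @return An \code{experiment_config}: validated blocks as package objects.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  defs <- config_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- defs
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  # predictor keys are merged (constructors fill the other blocks' defaults)
  cfg$predictor <- utils::modifyList(defs$predictor, as.list(cfg$predictor))

  check_block <- function(block, fun, where, drop = character(0)) {
    block <- block[setdiff(names(block), drop)]
    ok <- names(formals(fun))
    bad <- setdiff(names(block), ok)
    if (length(bad) > 0L) {
      stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    do.call(fun, block)
  }
  protocol <- check_block(cfg$protocol, sonication_protocol, "protocol")
  subject <- check_block(cfg$subject, subject_model, "subject")
  generator <- check_block(cfg$generator, generator_params, "generator")
  if (!is.null(names(cfg$controllers)) &&
      any(names(cfg$controllers) %in% names(formals(controller_config)))) {
    cfg$controllers <- list(cfg$controllers) # single unnamed block
  }
  controllers <- lapply(seq_along(cfg$controllers), function(i) {
    check_block(as.list(cfg$controllers[[i]]), controller_config,
                sprintf("controllers[%d]", i))
  })
  structure(
    list(protocol = protocol, subject = subject, generator = generator,
         controllers = controllers, predictor = cfg$predictor,
         output_dir = cfg$output_dir, seed = as.integer(cfg$seed)),
    class = "experiment_config"
  )
}

#' Save an experiment configuration skeleton
#'
#' @param config a list (raw blocks, as in the JSON schema) or an
#'   \code{experiment_config}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  if (inherits(config, "experiment_config")) {
    config <- list(
      protocol = unclass(config$protocol)[
        setdiff(names(config$protocol), "n_pulses")],
      subject = unclass(config$subject),
      generator = unclass(config$generator),
      controllers = lapply(config$controllers, function(x) {
        Filter(Negate(is.null), unclass(x))
      }),
      predictor = config$predictor,
      output_dir = config$output_dir,
      seed = config$seed
    )
  }
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
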