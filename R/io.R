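#' Read a wide-format abundance table
#'
#' The canonical interchange format is a wide CSV: one `time` column, one
#' column per species, optional `replicate` column.  Blank cells become
#' missing entries; species order is preserved.  A `--long` style table
#' (`time`, `species`, `value`, optional `replicate`) is accepted via
#' `long = TRUE`.
#'
#' @param path CSV file path.
#' @param long Is the file in long format?
#' @return An [abundance_data].
#' @export
read_dataset <- function(path, long = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) {
    stop(sprintf("'%s' has no `time` column", path), call. = FALSE)
  }
  if (long) {
    need <- c("time", "species", "value")
    if (!all(need %in% names(df))) {
      stop("long format needs columns time, species, value", call. = FALSE)
    }
    keys <- if ("replicate" %in% names(df)) c("time", "replicate") else "time"
    wide <- stats::reshape(df[c(keys, "species", "value")],
                           idvar = keys, timevar = "species",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    ord <- if ("replicate" %in% names(wide)) {
      order(wide$replicate, wide$time)
    } else {
      order(wide$time)
    }
    df <- wide[ord, ]
  }
  value_cols <- setdiff(names(df), c("time", "replicate"))
  for (cl in c("time", value_cols)) {
    if (!is.numeric(df[[cl]])) {
      stop(sprintf("column '%s' is not numeric", cl), call. = FALSE)
    }
  }
  key <- if ("replicate" %in% names(df)) paste(df$time, df$replicate) else df$time
  if (anyDuplicated(key)) {
    stop("duplicate (time, replicate) rows", call. = FALSE)
  }
  if ("replicate" %in% names(df)) {
    df <- df[order(df$replicate, df$time), ]
  } else {
    df <- df[order(df$time), ]
  }
  as_abundance_data(df)
}

#' Write an abundance table as wide CSV
#'
#' @param data An [abundance_data] (or coercible) or [trajectory].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  df <- as.data.frame(as_abundance_data(data))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## Parameters as a CSV matrix: rows = target (affected) species, columns =
## intercept then source (affecting) species.
params_to_matrix <- function(params) {
  if (inherits(params, "lv_params")) {
    m <- cbind(intercept = params$growth_rates, params$interactions)
  } else if (inherits(params, "mar_params")) {
    m <- cbind(intercept = params$intercepts, params$transition)
  } else {
    stop("unsupported parameter object", call. = FALSE)
  }
  rownames(m) <- params$species
  m
}

#' Assemble a run manifest
#'
#' A JSON-serializable record of everything needed to reproduce a run:
#' package version, scenario and method configuration, seeds, reference
#' choice and output paths.
#'
#' @param scenario Scenario configuration (name or list).
#' @param methods Method labels.
#' @param seeds Named or unnamed integer seeds.
#' @param reference Reference-series choice.
#' @param config Additional settings.
#' @param outputs Output file paths.
#' @return A list of class `"run_manifest"`.
#' @export
run_manifest <- function(scenario = NULL, methods = NULL, seeds = NULL,
                         reference = NULL, config = NULL, outputs = NULL) {
  structure(list(tool = "lvmar",
                 version = as.character(utils::packageVersion("lvmar")),
                 created = format(Sys.time(), tz = "UTC",
                                  "%Y-%m-%dT%H:%M:%SZ"),
                 scenario = scenario, methods = methods, seeds = seeds,
                 reference = reference, config = config, outputs = outputs),
            class = "run_manifest")
}

#' Write fit results or a comparison table to disk
#'
#' Parameters go out as CSV matrices (rows = target species, columns =
#' intercept + source species), predictions and comparison tables as CSV,
#' and the manifest as JSON.  Rereading reproduces the numbers to full
#' precision (values are written with all significant digits).
#'
#' @param x A [fit_result] or `"sse_table"`.
#' @param manifest A [run_manifest] (or `NULL` to skip).
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the files written.
#' @export
write_results <- function(x, manifest = NULL, out_dir, prefix = "result") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  fmt <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) sprintf("%.17g", col) else col)
    df
  }
  if (inherits(x, "fit_result")) {
    p <- file.path(out_dir, paste0(prefix, "_parameters.csv"))
    m <- params_to_matrix(x$params)
    utils::write.csv(fmt(data.frame(species = rownames(m), m,
                                    check.names = FALSE)),
                     p, row.names = FALSE)
    paths <- c(paths, p)
    if (!is.null(x$predicted)) {
      p2 <- file.path(out_dir, paste0(prefix, "_predicted.csv"))
      utils::write.csv(fmt(as.data.frame(x$predicted)), p2, row.names = FALSE)
      paths <- c(paths, p2)
    }
  } else if (inherits(x, "sse_table")) {
    p <- file.path(out_dir, paste0(prefix, "_sse_table.csv"))
    utils::write.csv(fmt(as.data.frame(x)), p, row.names = FALSE)
    paths <- c(paths, p)
  } else {
    stop("unsupported result object", call. = FALSE)
  }
  if (!is.null(manifest)) {
    pm <- file.path(out_dir, paste0(prefix, "_manifest.json"))
    manifest$outputs <- paths
    jsonlite::write_json(unclass(manifest), pm, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    paths <- c(paths, pm)
  }
  paths
}

#' Serialize a scenario spec to YAML
#'
#' @param spec A [scenario_spec].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(spec, path) {
  ## numbers are serialized as %.17g strings so the round trip is exact
  num <- function(x) sprintf("%.17g", as.numeric(x))
  rows <- function(m) apply(m, 1, num, simplify = FALSE)
  p <- spec$params
  pl <- if (spec$kind == "lv") {
    list(growth_rates = num(p$growth_rates),
         interactions = rows(p$interactions))
  } else {
    list(intercepts = num(p$intercepts),
         transition = rows(p$transition),
         process_covariance = rows(p$process_covariance))
  }
  obj <- list(kind = spec$kind, species = p$species, params = pl,
              x0 = num(spec$x0),
              grid = list(start_time = num(spec$grid$start_time),
                          step = num(spec$grid$step),
                          n_steps = spec$grid$n_steps),
              noise = list(shape = num(spec$noise$shape),
                           enabled = spec$noise$enabled),
              sampling = spec$sampling, seed = spec$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a scenario spec from YAML
#'
#' @param path YAML path written by [write_scenario()].
#' @return A [scenario_spec].
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  num <- function(x) as.numeric(unlist(x))
  rows <- function(l) do.call(rbind, lapply(l, num))
  params <- if (obj$kind == "lv") {
    lv_params(num(obj$params$growth_rates),
              rows(obj$params$interactions),
              species = unlist(obj$species))
  } else {
    mar_params(num(obj$params$intercepts),
               rows(obj$params$transition),
               rows(obj$params$process_covariance),
               species = unlist(obj$species))
  }
  scenario_spec(obj$kind, params, num(obj$x0),
                sim_grid(num(obj$grid$start_time), num(obj$grid$step),
                         obj$grid$n_steps),
                noise = noise_spec(num(obj$noise$shape), obj$noise$enabled),
                sampling = obj$sampling, seed = obj$seed)
}
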