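#' Abundance trajectory
#'
#' A dense model trajectory: a strictly increasing time vector and a matrix
#' of abundances with one column per species.  Trajectories are what the
#' simulators return and what predictions are expressed as; observed (and
#' possibly replicated or gappy) data are held in an [abundance_data]
#' object instead.
#'
#' @param times Numeric vector, strictly increasing.
#' @param values Numeric matrix, `length(times)` rows, one column per species.
#' @param species Character vector of species labels; defaults to the column
#'   names of `values`, or `X1 ... Xn`.
#' @return An object of class `"trajectory"` with fields `times`, `values`
#'   and `species`.
#' @seealso [abundance_data()], [as_abundance_data()]
#' @export
trajectory <- function(times, values, species = NULL) {
  values <- as.matrix(values)
  times <- as.numeric(times)
  if (length(times) != nrow(values)) {
    stop("`times` must have one entry per row of `values`", call. = FALSE)
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (is.null(species)) {
    species <- colnames(values)
    if (is.null(species)) species <- paste0("X", seq_len(ncol(values)))
  }
  if (length(species) != ncol(values)) {
    stop("`species` must have one label per column of `values`", call. = FALSE)
  }
  dimnames(values) <- list(NULL, species)
  structure(list(times = times, values = values, species = species),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points x %d species [%s], t in [%g, %g]\n",
              length(x$times), length(x$species),
              paste(x$species, collapse = ", "),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, x$values, check.names = FALSE)
}

#' Observed abundance data
#'
#' Observed (sampled) community time series: times, an abundance matrix with
#' possible missing entries, and an optional replicate label per row.  Within
#' a replicate, times must be strictly increasing; different replicates may
#' share times (that is the point of replication).
#'
#' @param times Numeric vector of observation times.
#' @param values Numeric matrix (rows = observations, columns = species);
#'   `NA` marks a missing entry.
#' @param species Character vector of species labels.
#' @param replicate Optional vector of replicate labels, one per row.
#' @return An object of class `"abundance_data"`.
#' @export
abundance_data <- function(times, values, species = NULL, replicate = NULL) {
  values <- as.matrix(values)
  times <- as.numeric(times)
  if (length(times) != nrow(values)) {
    stop("`times` must have one entry per row of `values`", call. = FALSE)
  }
  if (is.null(species)) {
    species <- colnames(values)
    if (is.null(species)) species <- paste0("X", seq_len(ncol(values)))
  }
  dimnames(values) <- list(NULL, species)
  if (!is.null(replicate)) {
    if (length(replicate) != length(times)) {
      stop("`replicate` must have one label per row", call. = FALSE)
    }
    replicate <- as.character(replicate)
    for (r in unique(replicate)) {
      tt <- times[replicate == r]
      if (length(tt) > 1 && any(diff(tt) <= 0)) {
        stop(sprintf("times within replicate '%s' must be strictly increasing", r),
             call. = FALSE)
      }
    }
  } else if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing (or supply `replicate`)",
         call. = FALSE)
  }
  n_obs <- colSums(!is.na(values))
  if (any(n_obs < 2)) {
    stop("every species needs at least 2 observed points", call. = FALSE)
  }
  structure(list(times = times, values = values, species = species,
                 replicate = replicate),
            class = "abundance_data")
}

#' @export
print.abundance_data <- function(x, ...) {
  rep_txt <- if (is.null(x$replicate)) "" else
    sprintf(", %d replicates", length(unique(x$replicate)))
  cat(sprintf("<abundance_data> %d rows x %d species%s, t in [%g, %g]\n",
              length(x$times), length(x$species), rep_txt,
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.abundance_data <- function(x, ...) {
  df <- data.frame(time = x$times, x$values, check.names = FALSE)
  if (!is.null(x$replicate)) df <- cbind(df[1], replicate = x$replicate, df[-1])
  df
}

#' Coerce to observed abundance data
#'
#' @param x A [trajectory] or a wide data frame with a `time` column.
#' @param ... Unused.
#' @return An [abundance_data] object.
#' @export
as_abundance_data <- function(x, ...) UseMethod("as_abundance_data")

#' @export
as_abundance_data.abundance_data <- function(x, ...) x

#' @export
as_abundance_data.trajectory <- function(x, ...) {
  abundance_data(x$times, x$values, species = x$species)
}

#' @export
as_abundance_data.data.frame <- function(x, ...) {
  if (!"time" %in% names(x)) stop("need a `time` column", call. = FALSE)
  rep_col <- if ("replicate" %in% names(x)) as.character(x$replicate) else NULL
  keep <- setdiff(names(x), c("time", "replicate"))
  abundance_data(x$time, as.matrix(x[keep]), species = keep,
                 replicate = rep_col)
}

n_species <- function(x) length(x$species)
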