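#' Read a BIDS-style events table
#'
#' Reads a tab-separated events file with columns `onset`, `duration`,
#' optional `trial_type` and optional `modulation` (defaulting to 1 when
#' absent). Rows are sorted by onset; one [event_spec()] is returned per
#' trial type.
#'
#' @param path path to the events.tsv file.
#' @return named list of `event_spec`, one per trial type.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("onset", "duration")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("events file is missing required column(s): ",
         paste(missing, collapse = ", "), "; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("events file contains no events (at least one trial is required)",
         call. = FALSE)
  for (col in c("onset", "duration")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop("non-numeric '", col, "' at row(s): ",
           paste(which(is.na(v)), collapse = ", "), call. = FALSE)
    df[[col]] <- v
  }
  if (is.null(df$trial_type)) df$trial_type <- "events"
  if (is.null(df$modulation)) df$modulation <- 1
  df$modulation <- as.numeric(df$modulation)
  df <- df[order(df$onset), , drop = FALSE]
  out <- lapply(split(df, df$trial_type), function(g)
    event_spec(g$onset, g$duration, g$modulation, label = g$trial_type[1]))
  out[unique(df$trial_type)]
}

#' Write an events table
#'
#' Writes one or more [event_spec()]s as a BIDS-style tab-separated file
#' with columns `onset`, `duration`, `trial_type`, `modulation`.
#'
#' @param events an `event_spec` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  if (inherits(events, "event_spec")) events <- list(events)
  df <- do.call(rbind, lapply(events, function(ev)
    data.frame(onset = ev$onsets, duration = ev$durations,
               trial_type = ev$label, modulation = ev$modulations)))
  df <- df[order(df$onset), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a multi-column time-series table
#'
#' Reads a tab-separated file with one column per region/voxel series (a
#' leading `time` column, if present, is dropped after a regularity check).
#'
#' @param path path to the TSV file.
#' @return named list of numeric vectors, plus attribute `dt` when a time
#'   column was present.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("series file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  dt <- NULL
  if ("time" %in% names(df)) {
    tv <- as.numeric(df$time)
    if (length(tv) > 1L) {
      steps <- diff(tv)
      if (max(abs(steps - steps[1])) > 1e-9)
        stop("'time' column is not on a regular grid", call. = FALSE)
      dt <- steps[1]
    }
    df$time <- NULL
  }
  out <- lapply(df, as.numeric)
  attr(out, "dt") <- dt
  out
}

#' Write a simulated dataset to disk
#'
#' Writes `events.tsv` (reward-delivery modulations under trial type
#' `feedback`, from which both candidate regressors can be rebuilt),
#' `series.tsv` (time plus one column per region) and `provenance.json`
#' (full configuration including seeds, sufficient for bit-identical
#' regeneration).
#'
#' @param ds a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- event_spec(ds$config$onsets, durations = 0,
                   modulations = ds$config$rewards, label = "feedback")
  write_events(ev, file.path(dir, "events.tsv"))
  n <- length(ds$series[[1]])
  tab <- data.frame(time = (seq_len(n) - 1) * ds$dt)
  for (nm in names(ds$series)) tab[[nm]] <- ds$series[[nm]]
  utils::write.table(tab, file.path(dir, "series.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sort_keys(ds$config),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# Recursively sort list keys so serialized JSON is stable across runs.
sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x))
    x <- lapply(x[order(names(x))], sort_keys)
  x
}
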