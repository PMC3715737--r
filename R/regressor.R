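#' Event specification
#'
#' A set of events for one condition / trial type: onsets (seconds from the
#' start of the series), durations (0 for impulse "stick" events, > 0 for
#' boxcars) and a per-event parametric modulation.
#'
#' @param onsets numeric, strictly increasing, seconds.
#' @param durations numeric, non-negative, seconds; recycled if scalar.
#' @param modulations numeric, one amplitude per event; recycled if scalar.
#' @param label condition name.
#' @return object of class `event_spec`.
#' @export
event_spec <- function(onsets, durations = 0, modulations = 1,
                       label = "events") {
  n <- length(onsets)
  if (n < 1L) stop("at least one event is required", call. = FALSE)
  if (length(durations) == 1L) durations <- rep(durations, n)
  if (length(modulations) == 1L) modulations <- rep(modulations, n)
  if (length(durations) != n || length(modulations) != n)
    stop("'onsets', 'durations' and 'modulations' must have equal length",
         call. = FALSE)
  if (any(diff(onsets) <= 0))
    stop("'onsets' must be strictly increasing", call. = FALSE)
  if (any(durations < 0))
    stop("'durations' must be non-negative", call. = FALSE)
  structure(list(onsets = as.numeric(onsets),
                 durations = as.numeric(durations),
                 modulations = as.numeric(modulations),
                 label = as.character(label)),
            class = "event_spec")
}

#' @export
print.event_spec <- function(x, ...) {
  cat("<event_spec> '", x$label, "': ", length(x$onsets), " events\n",
      sep = "")
  invisible(x)
}

# Population standard deviation (divide by n), the convention used
# throughout for standardization and noise scaling.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

new_regressor <- function(name, samples, dt, standardized = FALSE,
                          orthogonalized_against = character(0)) {
  structure(list(name = name, samples = as.numeric(samples), dt = dt,
                 standardized = standardized,
                 orthogonalized_against = orthogonalized_against),
            class = "regressor")
}

#' Build an HRF-convolved regressor from events
#'
#' Places each event's modulation on a fine internal time grid as a stick
#' (zero duration) or boxcar (positive duration) stimulus function,
#' convolves it with a hemodynamic response function, and decimates to the
#' output sampling interval `dt`. Convolution is carried out on the `hrf_dt`
#' grid (default 0.1 s) to avoid onset-quantization artifacts; onsets are
#' snapped to the nearest fine-grid sample.
#'
#' By default modulations are mean-centered across events before convolution
#' (`center_modulations = TRUE`), the standard treatment of parametric
#' modulators in fMRI design construction. With sparse events this makes the
#' correlation between two convolved regressors match the Pearson
#' correlation of their modulation vectors; without centering, the baseline
#' samples pull the time-series correlation toward the uncentered modulation
#' correlation instead. Set `center_modulations = FALSE` for a main-effect
#' regressor whose raw amplitude matters (e.g. a single unit impulse).
#'
#' @param events an [event_spec()].
#' @param total_duration series length in seconds.
#' @param dt output sampling interval, seconds (default 1).
#' @param hrf impulse response sampled at `hrf_dt`; defaults to
#'   [canonical_hrf()].
#' @param hrf_dt fine grid used for convolution, seconds (default 0.1).
#' @param center_modulations mean-center modulations before convolution.
#' @param name regressor name; defaults to the event label.
#' @return object of class `regressor` (not yet standardized).
#' @seealso [zscore()], [orthogonalize()]
#' @export
build_regressor <- function(events, total_duration, dt = 1, hrf = NULL,
                            hrf_dt = 0.1, center_modulations = TRUE,
                            name = events$label) {
  stopifnot(inherits(events, "event_spec"))
  if (total_duration <= 0) stop("'total_duration' must be positive",
                                call. = FALSE)
  step <- dt / hrf_dt
  if (abs(step - round(step)) > 1e-8)
    stop("'dt' must be an integer multiple of 'hrf_dt'", call. = FALSE)
  step <- as.integer(round(step))
  if (is.null(hrf)) hrf <- canonical_hrf(hrf_dt)
  if (any(events$onsets > total_duration))
    stop("event onset beyond 'total_duration'", call. = FALSE)

  n_fine <- as.integer(round(total_duration / hrf_dt))
  mods <- events$modulations
  if (center_modulations) mods <- mods - mean(mods)

  stim <- numeric(n_fine)
  for (i in seq_along(events$onsets)) {
    j <- as.integer(round(events$onsets[i] / hrf_dt)) + 1L
    if (j > n_fine) stop("event onset beyond 'total_duration'", call. = FALSE)
    if (events$durations[i] == 0) {
      stim[j] <- stim[j] + mods[i]
    } else {
      j2 <- min(n_fine, j + as.integer(round(events$durations[i] / hrf_dt)) - 1L)
      stim[j:j2] <- stim[j:j2] + mods[i]
    }
  }

  conv <- stats::convolve(c(stim, numeric(length(hrf))), rev(hrf),
                          type = "open")[seq_len(n_fine)]
  n_out <- as.integer(round(total_duration / dt))
  samples <- conv[1L + (seq_len(n_out) - 1L) * step]
  new_regressor(name, samples, dt)
}

#' z-standardize a regressor
#'
#' Centers to mean 0 and scales to standard deviation 1, using the
#' population convention (divide by n). Standardizing regressors before
#' fitting competing GLMs makes their parameter estimates comparable:
#' otherwise beta size reflects regressor scaling as well as explained
#' variance. Idempotent.
#'
#' @param x a `regressor` or plain numeric vector.
#' @return same type as `x`, standardized.
#' @export
zscore <- function(x) UseMethod("zscore")

#' @export
zscore.numeric <- function(x) {
  s <- sd_pop(x)
  if (s < 1e-12)
    stop("cannot z-score a constant (zero-variance) series", call. = FALSE)
  (x - mean(x)) / s
}

#' @export
zscore.regressor <- function(x) {
  x$samples <- zscore(x$samples)
  x$standardized <- TRUE
  x
}

#' Orthogonalize a regressor against others
#'
#' Replaces `target` by the residual of its least-squares projection onto
#' the span of `bases` plus an intercept, so that its parameter estimate in
#' a subsequent GLM measures only the variance it explains uniquely. The
#' intercept is always projected out, so orthogonality in the dot product is
#' equivalent to zero Pearson correlation with each base. The result is
#' deliberately not re-standardized: this preserves the identity that the
#' orthogonalized-last regressor's beta equals its beta in the
#' non-orthogonalized full model.
#'
#' @param target `regressor` to residualize.
#' @param bases a `regressor` or list of regressors to project out.
#' @return `regressor` with `orthogonalized_against` recording the base
#'   names in order; `standardized` is reset to `FALSE`.
#' @export
orthogonalize <- function(target, bases) {
  stopifnot(inherits(target, "regressor"))
  if (inherits(bases, "regressor")) bases <- list(bases)
  n <- length(target$samples)
  for (b in bases) {
    stopifnot(inherits(b, "regressor"))
    if (length(b$samples) != n || !isTRUE(all.equal(b$dt, target$dt)))
      stop("'target' and 'bases' must share the sampling grid", call. = FALSE)
  }
  X <- cbind(1, vapply(bases, function(b) b$samples, numeric(n)))
  res <- stats::lm.fit(X, target$samples)$residuals
  if (sd_pop(res) < 1e-12)
    stop("degenerate orthogonalization: '", target$name,
         "' lies in the span of the base regressors", call. = FALSE)
  out <- target
  out$samples <- res
  out$standardized <- FALSE
  out$orthogonalized_against <- c(target$orthogonalized_against,
                                  vapply(bases, `[[`, "", "name"))
  out
}

#' @export
print.regressor <- function(x, ...) {
  cat("<regressor> '", x$name, "': ", length(x$samples), " samples @ dt=",
      x$dt, "s", if (x$standardized) ", standardized" else "",
      if (length(x$orthogonalized_against))
        paste0(", orthogonal to ", paste(x$orthogonalized_against,
                                         collapse = ", ")) else "",
      "\n", sep = "")
  invisible(x)
}
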