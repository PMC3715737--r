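#' Rescorla-Wagner learning trace
#'
#' Iterates the Rescorla-Wagner update over a sequence of per-trial reward
#' receipts and returns the trial-by-trial predicted values and prediction
#' errors. On every trial the prediction error is the difference between the
#' delivered reward and the current predicted value,
#' \deqn{\delta_t = R_t - V_t,}
#' and the predicted value for the next trial is updated with learning rate
#' \eqn{\alpha}:
#' \deqn{V_{t+1} = V_t + \alpha \delta_t.}
#'
#' Values are computed exactly (no rounding is applied internally); display
#' rounding is left to the caller.
#'
#' When `trial_types` is supplied, each trial type maintains its own
#' predicted value, updated only on its own trials, so interleaved stimuli
#' learn independently. `alpha` may then be a named vector giving one
#' learning rate per trial type (unnamed scalar `alpha` is shared).
#'
#' @param rewards numeric vector of reward receipts, one per trial
#'   (1 = delivered, 0 = omitted in the classic example; arbitrary reals
#'   allowed).
#' @param alpha learning rate in \[0, 1\]; scalar, or a named vector keyed by
#'   trial type when `trial_types` is given.
#' @param v0 initial predicted value \eqn{V_1} (default 0).
#' @param trial_types optional character vector, one per trial, assigning
#'   each trial to a stimulus whose value is learned separately.
#'
#' @return An object of class `rw_trace`: a list with elements `rewards`,
#'   `alpha`, `v0`, `values` (\eqn{V_t}), `deltas` (\eqn{\delta_t}) and
#'   `n_trials`.
#'
#' @examples
#' tr <- rw_trace(c(1, 0, 0, 1, 1, 1, 0), alpha = 0.5)
#' round(tr$deltas, 2)
#' @export
rw_trace <- function(rewards, alpha = 0.5, v0 = 0, trial_types = NULL) {
  if (length(rewards) < 1L)
    stop("'rewards' must contain at least one trial", call. = FALSE)
  if (!is.numeric(rewards) || anyNA(rewards))
    stop("'rewards' must be numeric with no missing values", call. = FALSE)
  if (!is.numeric(alpha) || anyNA(alpha) || any(alpha < 0) || any(alpha > 1))
    stop("'alpha' must lie in [0, 1]", call. = FALSE)

  n <- length(rewards)
  values <- numeric(n)
  deltas <- numeric(n)

  if (is.null(trial_types)) {
    if (length(alpha) != 1L)
      stop("'alpha' must be a scalar unless 'trial_types' is given",
           call. = FALSE)
    v <- v0
    for (t in seq_len(n)) {
      values[t] <- v
      deltas[t] <- rewards[t] - v
      v <- v + alpha * deltas[t]
    }
  } else {
    if (length(trial_types) != n)
      stop("'trial_types' must have one entry per trial", call. = FALSE)
    types <- unique(trial_types)
    a <- resolve_alpha(alpha, types)
    v <- stats::setNames(rep(v0, length(types)), types)
    for (t in seq_len(n)) {
      tt <- trial_types[t]
      values[t] <- v[[tt]]
      deltas[t] <- rewards[t] - v[[tt]]
      v[[tt]] <- v[[tt]] + a[[tt]] * deltas[t]
    }
  }

  structure(
    list(rewards = as.numeric(rewards), alpha = alpha, v0 = v0,
         trial_types = trial_types, values = values, deltas = deltas,
         n_trials = n),
    class = "rw_trace"
  )
}

# Map a scalar or named alpha vector onto the set of trial types.
resolve_alpha <- function(alpha, types) {
  if (length(alpha) == 1L && is.null(names(alpha)))
    return(stats::setNames(rep(alpha, length(types)), types))
  missing <- setdiff(types, names(alpha))
  if (length(missing))
    stop("no learning rate supplied for trial type(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  alpha[types]
}

#' @export
print.rw_trace <- function(x, ...) {
  cat("Rescorla-Wagner trace:", x$n_trials, "trials, alpha =",
      paste(format(x$alpha), collapse = ", "), ", V1 =", x$v0, "\n")
  print(data.frame(trial = seq_len(x$n_trials), reward = x$rewards,
                   value = x$values, delta = x$deltas), row.names = FALSE)
  invisible(x)
}
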