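#' Design matrix
#'
#' An ordered set of regressors sharing one sampling grid, optionally with
#' an intercept column.
#'
#' @param regressors list of `regressor` objects.
#' @param include_intercept add an all-ones column (default TRUE).
#' @param ortho_order free-text record of any serial orthogonalization.
#' @return object of class `design_matrix`.
#' @export
design_matrix <- function(regressors, include_intercept = TRUE,
                          ortho_order = "") {
  stopifnot(length(regressors) >= 1L,
            all(vapply(regressors, inherits, TRUE, "regressor")))
  n <- length(regressors[[1]]$samples)
  dt <- regressors[[1]]$dt
  for (r in regressors)
    if (length(r$samples) != n || !isTRUE(all.equal(r$dt, dt)))
      stop("all regressors must share dt and n_samples", call. = FALSE)
  structure(list(regressors = regressors,
                 include_intercept = include_intercept,
                 n_samples = n, dt = dt, ortho_order = ortho_order),
            class = "design_matrix")
}

# Column name for a regressor inside a design matrix: orthogonalized
# regressors are suffixed so full GLM1/GLM2 columns are unambiguous.
regressor_colname <- function(r) {
  if (length(r$orthogonalized_against))
    paste0(r$name, ".orth") else r$name
}

#' @export
as.matrix.design_matrix <- function(x, ...) {
  M <- vapply(x$regressors, `[[`, numeric(x$n_samples), "samples")
  if (is.null(dim(M))) M <- matrix(M, ncol = length(x$regressors))
  colnames(M) <- vapply(x$regressors, regressor_colname, "")
  if (x$include_intercept)
    M <- cbind(`(Intercept)` = rep(1, x$n_samples), M)
  M
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", x$n_samples, " samples x ",
      length(x$regressors) + x$include_intercept, " columns: ",
      paste(colnames(as.matrix(x)), collapse = ", "), "\n", sep = "")
  if (nzchar(x$ortho_order)) cat("  orthogonalization: ", x$ortho_order,
                                 "\n", sep = "")
  invisible(x)
}

#' The four GLM designs of a two-model comparison
#'
#' Given two standardized candidate regressors A and B, constructs the four
#' designs the comparison needs: two full GLMs containing both regressors
#' with reversed serial orthogonalization, and two reduced GLMs containing
#' only one candidate each. Each design includes an intercept.
#'
#' * `full1`: \[A, B orthogonalized to A\] — B's beta is its unique
#'   contribution, A's beta absorbs the shared variance.
#' * `full2`: \[B, A orthogonalized to B\] — roles reversed.
#' * `reduced_A`: \[A\]; `reduced_B`: \[B\].
#'
#' The two full designs span the same fitted-value space (orthogonalization
#' is a change of basis), so their hat matrices coincide.
#'
#' @param regA,regB standardized `regressor` objects on the same grid.
#' @return named list of four `design_matrix` objects.
#' @export
build_designs <- function(regA, regB) {
  stopifnot(inherits(regA, "regressor"), inherits(regB, "regressor"))
  if (!regA$standardized || !regB$standardized)
    stop("both regressors must be z-standardized (see zscore())",
         call. = FALSE)
  if (length(regA$samples) != length(regB$samples) ||
      !isTRUE(all.equal(regA$dt, regB$dt)))
    stop("'regA' and 'regB' must share the sampling grid", call. = FALSE)
  list(
    full1 = design_matrix(list(regA, orthogonalize(regB, regA)),
                          ortho_order = paste(regB$name, "orthogonalized to",
                                              regA$name)),
    full2 = design_matrix(list(regB, orthogonalize(regA, regB)),
                          ortho_order = paste(regA$name, "orthogonalized to",
                                              regB$name)),
    reduced_A = design_matrix(list(regA)),
    reduced_B = design_matrix(list(regB))
  )
}
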