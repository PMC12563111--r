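# small shared helpers

#' Population standard deviation
#'
#' Standard deviation with the 1/n (population) normalisation, used by the
#' Grassberger-Procaccia distance cutoff and the scatter (SP) feature.
#'
#' @param x numeric vector.
#' @return A single number, `sqrt(mean((x - mean(x))^2))`.
#' @export
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Euclidean norm of each row of a 2-column matrix
.row_norms <- function(xy) sqrt(rowSums(xy^2))

# stop with a consistent prefix
.fail <- function(...) stop(sprintf(...), call. = FALSE)

# check a numeric matrix for NaN/NA
.check_finite <- function(m, what = "data") {
  if (anyNA(m) || any(!is.finite(m)))
    .fail("%s contains NA/NaN/Inf values", what)
  invisible(m)
}
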