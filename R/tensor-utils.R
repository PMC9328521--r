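#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm sd predict
#' @importFrom utils head read.csv write.csv
NULL

# Validate an order-3 array (subjects x features x timepoints).
assert_tensor3 <- function(A, arg = "A") {
  if (!is.array(A) || length(dim(A)) != 3L) {
    abort(sprintf("`%s` must be a 3-dimensional array (subjects x features x timepoints).", arg),
          class = "tcam_shape_error")
  }
  if (any(dim(A) < 1L)) {
    abort(sprintf("`%s` has a zero-length dimension.", arg), class = "tcam_shape_error")
  }
  if (!all(is.finite(A))) {
    abort(sprintf("`%s` contains non-finite values.", arg), class = "tcam_value_error")
  }
  invisible(A)
}

#' Frobenius norm of a tensor or matrix
#'
#' Square root of the sum of squared entries, the norm under which all
#' reconstruction and truncation error guarantees of the tsvdm hold.
#'
#' @param A A numeric array of any order.
#' @return A non-negative scalar.
#' @examples
#' frobenius_norm(array(c(3, 4), dim = c(1, 1, 2)))  # 5
#' @export
frobenius_norm <- function(A) {
  sqrt(sum(as.numeric(A)^2))
}

# Mode-1 unfolding: m x (p*n) matrix, horizontal slice i becomes row i.
unfold_mode1 <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(1L, 2L, 3L)), nrow = d[1L], ncol = d[2L] * d[3L])
}

# Relative Frobenius difference, guarding the zero denominator.
rel_fro_error <- function(A, B) {
  den <- frobenius_norm(A)
  if (den == 0) frobenius_norm(B) else frobenius_norm(A - B) / den
}
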