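#' Construct the domain-mixing matrix M
#'
#' The star-M algebra is parameterized by an invertible n x n matrix M that
#' is applied along the time axis (mode 3) of the data tensor, carrying it
#' into the "hat" domain where the tubal SVD reduces to independent
#' matrix SVDs of the frontal faces. Two orthonormal families are provided:
#' the orthonormal DCT-II, which concentrates smooth temporal variation in
#' the leading faces, and a Haar-distributed random orthogonal matrix.
#' Orthonormality makes the mode-3 product an exact isometry, so
#' hat-domain and original-domain Frobenius errors coincide.
#'
#' @param n Side length; must equal the number of timepoints of the tensors
#'   the transform will be applied to.
#' @param kind One of `"dct2"` (default), `"haar_random"`, or `"custom"`.
#' @param seed Integer seed, required for (and only used by)
#'   `"haar_random"`; stored on the object for reproducibility.
#' @param matrix For `kind = "custom"`, the invertible n x n matrix itself.
#' @return An object of class `m_transform`: a list with elements `matrix`,
#'   `kind`, `n`, and `seed`.
#' @examples
#' M <- m_transform(4)
#' max(abs(crossprod(M$matrix) - diag(4)))  # orthonormal
#' @export
m_transform <- function(n, kind = c("dct2", "haar_random", "custom"),
                        seed = NULL, matrix = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer.", class = "tcam_invalid_size")
  }
  n <- as.integer(n)
  mat <- switch(kind,
    dct2 = dct2_matrix(n),
    haar_random = {
      if (is.null(seed)) {
        abort("`seed` is required for kind = \"haar_random\".",
              class = "tcam_invalid_argument")
      }
      haar_orthogonal(n, seed)
    },
    custom = {
      if (is.null(matrix)) {
        abort("`matrix` is required for kind = \"custom\".",
              class = "tcam_invalid_argument")
      }
      matrix <- base::as.matrix(matrix)
      if (!all(dim(matrix) == c(n, n))) {
        abort("custom `matrix` must be n x n.", class = "tcam_shape_error")
      }
      if (abs(det(matrix)) < .Machine$double.eps * n) {
        abort("custom `matrix` is numerically singular.",
              class = "tcam_invalid_argument")
      }
      matrix
    }
  )
  structure(
    list(matrix = mat, kind = kind, n = n,
         seed = if (kind == "haar_random") as.integer(seed) else NULL),
    class = "m_transform"
  )
}

# Orthonormal DCT-II: row k (0-based) has entries
# c_k * cos(pi * (2j + 1) * k / (2n)), with c_0 = sqrt(1/n), c_k = sqrt(2/n).
dct2_matrix <- function(n) {
  k <- seq_len(n) - 1L
  j <- seq_len(n) - 1L
  mat <- sqrt(2 / n) * cos(outer(k, 2 * j + 1) * pi / (2 * n))
  mat[1L, ] <- sqrt(1 / n)
  mat
}

# Haar-distributed orthogonal matrix: QR of a Gaussian matrix with the R
# diagonal sign fix (otherwise the distribution is not uniform on O(n)).
haar_orthogonal <- function(n, seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  G <- matrix(rnorm(n * n), n, n)
  qr_ <- qr(G)
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  sweep(Q, 2L, d, `*`)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(value) {
  if (is.null(value)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", value, envir = globalenv())
  }
}

#' @export
print.m_transform <- function(x, ...) {
  cat(sprintf("<m_transform> kind=%s n=%d%s\n", x$kind, x$n,
              if (!is.null(x$seed)) sprintf(" seed=%d", x$seed) else ""))
  invisible(x)
}

m_inverse <- function(M) {
  if (M$kind %in% c("dct2", "haar_random")) t(M$matrix) else solve(M$matrix)
}

#' Write / read an M-transform as plain text
#'
#' The matrix is stored as a whitespace-delimited text file with a JSON
#' sidecar (`<path>.json`) recording `kind`, `n`, and `seed`.
#'
#' @param M An `m_transform`.
#' @param path File path for the matrix; the sidecar is `<path>.json`.
#' @return `write_m_transform()` returns `path` invisibly;
#'   `read_m_transform()` returns the reconstructed `m_transform`.
#' @export
write_m_transform <- function(M, path) {
  stopifnot(inherits(M, "m_transform"))
  utils::write.table(format(M$matrix, digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(kind = M$kind, n = M$n)
  if (!is.null(M$seed)) meta$seed <- M$seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_m_transform
#' @export
read_m_transform <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mat <- base::as.matrix(utils::read.table(path))
  dimnames(mat) <- NULL
  if (meta$kind == "haar_random") {
    # reconstruct from the seed so reading is bitwise-faithful
    M <- m_transform(meta$n, "haar_random", seed = meta$seed)
  } else if (meta$kind == "dct2") {
    M <- m_transform(meta$n, "dct2")
  } else {
    M <- m_transform(meta$n, "custom", matrix = mat)
  }
  if (max(abs(M$matrix - mat)) > 1e-8) {
    warn("stored matrix disagrees with its metadata reconstruction; using the stored values")
    M$matrix <- mat
  }
  M
}

#' Mode-3 product: apply M along the time axis
#'
#' Applies the mixing matrix to every tube fiber `A[i, j, ]`, carrying the
#' tensor into the hat domain; `mode3_inverse()` applies the inverse and
#' carries it back. For orthonormal M the product preserves the Frobenius
#' norm exactly.
#'
#' @param A An m x p x n array.
#' @param M An `m_transform` with side length n.
#' @return An array of the same shape.
#' @export
mode3_product <- function(A, M) {
  assert_tensor3(A)
  stopifnot(inherits(M, "m_transform"))
  d <- dim(A)
  if (M$n != d[3L]) {
    abort(sprintf("M is %d x %d but the tensor has %d timepoints.", M$n, M$n, d[3L]),
          class = "tcam_shape_error")
  }
  apply_mode3(A, M$matrix)
}

#' @rdname mode3_product
#' @export
mode3_inverse <- function(A, M) {
  assert_tensor3(A)
  stopifnot(inherits(M, "m_transform"))
  d <- dim(A)
  if (M$n != d[3L]) {
    abort(sprintf("M is %d x %d but the tensor has %d timepoints.", M$n, M$n, d[3L]),
          class = "tcam_shape_error")
  }
  apply_mode3(A, m_inverse(M))
}

# Core mode-3 contraction: unfold tubes to rows, right-multiply by t(mat).
apply_mode3 <- function(A, mat) {
  d <- dim(A)
  out <- matrix(A, nrow = d[1L] * d[2L], ncol = d[3L]) %*% t(mat)
  dim(out) <- d
  dimnames(out) <- dimnames(A)
  out
}
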