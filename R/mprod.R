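#' Face-wise product of two tensors
#'
#' Multiplies corresponding frontal slices: `C[, , i] = A[, , i] %*% B[, , i]`.
#' The star-M product is a face-wise product carried out in the hat domain.
#'
#' @param A An m x p x n array.
#' @param B A p x r x n array.
#' @return An m x r x n array.
#' @export
facewise_product <- function(A, B) {
  assert_tensor3(A); assert_tensor3(B, "B")
  da <- dim(A); db <- dim(B)
  if (da[2L] != db[1L] || da[3L] != db[3L]) {
    abort(sprintf("cannot face-multiply %dx%dx%d by %dx%dx%d.",
                  da[1L], da[2L], da[3L], db[1L], db[2L], db[3L]),
          class = "tcam_shape_error")
  }
  out <- array(0, dim = c(da[1L], db[2L], da[3L]))
  for (i in seq_len(da[3L])) {
    out[, , i] <- A[, , i, drop = FALSE][, , 1L] %*% B[, , i, drop = FALSE][, , 1L]
  }
  out
}

#' The star-M tensor-tensor product
#'
#' Both operands are carried into the hat domain by the mode-3 product with
#' M, multiplied face-wise, and carried back with the inverse transform.
#'
#' @param A An m x p x n array.
#' @param B A p x r x n array.
#' @param M An `m_transform` with side length n.
#' @return An m x r x n array.
#' @export
m_product <- function(A, B, M) {
  mode3_inverse(facewise_product(mode3_product(A, M), mode3_product(B, M)), M)
}

#' Tensor transpose
#'
#' Transposes every frontal slice (and, for the star-M algebra over real
#' orthogonal M, this is the algebra's adjoint: `(A *M B)^T = B^T *M A^T`).
#'
#' @param A An m x p x n array.
#' @return A p x m x n array.
#' @export
m_transpose <- function(A) {
  assert_tensor3(A)
  aperm(A, c(2L, 1L, 3L))
}

#' Identity tensor of the star-M algebra
#'
#' The neutral element: every hat-domain face is the m x m identity, so
#' `m_product(identity_tensor(m, n, M), A, M)` returns `A`.
#'
#' @param m Slice side length.
#' @param n Number of faces (timepoints).
#' @param M An `m_transform` with side length n.
#' @return An m x m x n array.
#' @export
identity_tensor <- function(m, n, M) {
  stopifnot(m >= 1, n >= 1)
  I_hat <- array(0, dim = c(m, m, n))
  for (i in seq_len(n)) I_hat[, , i] <- diag(m)
  mode3_inverse(I_hat, M)
}

#' Test star-M orthogonality
#'
#' A tensor Q is star-M orthogonal (in the economy sense) when every
#' hat-domain face has orthonormal columns.
#'
#' @param Q An m x k x n array.
#' @param M An `m_transform`.
#' @param tol Absolute tolerance on `t(face) %*% face - I`.
#' @return `TRUE` or `FALSE`.
#' @export
is_m_orthogonal <- function(Q, M, tol = 1e-8) {
  Q_hat <- mode3_product(Q, M)
  k <- dim(Q_hat)[2L]
  for (i in seq_len(dim(Q_hat)[3L])) {
    face <- Q_hat[, , i, drop = FALSE][, , 1L]
    if (max(abs(crossprod(face) - diag(k))) > tol) return(FALSE)
  }
  TRUE
}

#' Tubal singular value decomposition (tsvdm)
#'
#' Factorizes `A = U *M S *M t(V)` with star-M-orthogonal `U`, `V` and
#' f-diagonal `S`, by taking the economy SVD of each hat-domain face and
#' carrying the factors back with the inverse transform. The economy size is
#' `k = min(m, p)`; the trailing zero singular values of a full decomposition
#' carry no information and are never materialized.
#'
#' Sign convention: within each hat-domain face, the entry of largest
#' magnitude of every right-singular-vector column is made positive (ties
#' broken by lowest feature index), with the matching left column flipped
#' accordingly. This makes the factorization deterministic across runs.
#'
#' @param A An m x p x n array with finite entries.
#' @param M An `m_transform` with side length n.
#' @return An object of class `tsvdm`: list with `U` (m x k x n),
#'   `V` (p x k x n), `s_hat` (k x n matrix of hat-domain singular values,
#'   columns non-negative and non-increasing), and `M`.
#' @examples
#' A <- array(rnorm(3 * 4 * 2), dim = c(3, 4, 2))
#' f <- tsvdm(A, m_transform(2))
#' frobenius_norm(tsvdm_reconstruct(f) - A)  # ~1e-15
#' @export
tsvdm <- function(A, M) {
  assert_tensor3(A)
  A_hat <- mode3_product(A, M)
  d <- dim(A)
  m <- d[1L]; p <- d[2L]; n <- d[3L]
  k <- min(m, p)
  U_hat <- array(0, dim = c(m, k, n))
  V_hat <- array(0, dim = c(p, k, n))
  s_hat <- matrix(0, nrow = k, ncol = n)
  for (i in seq_len(n)) {
    sv <- svd(A_hat[, , i, drop = FALSE][, , 1L], nu = k, nv = k)
    u <- sv$u; v <- sv$v
    for (col in seq_len(k)) {
      pivot <- which.max(abs(v[, col]))    # first maximum = lowest index on ties
      if (v[pivot, col] < 0) {
        v[, col] <- -v[, col]
        u[, col] <- -u[, col]
      }
    }
    U_hat[, , i] <- u
    V_hat[, , i] <- v
    s_hat[, i] <- sv$d[seq_len(k)]
  }
  structure(
    list(U = mode3_inverse(U_hat, M),
         V = mode3_inverse(V_hat, M),
         s_hat = s_hat,
         M = M),
    class = "tsvdm"
  )
}

#' @export
print.tsvdm <- function(x, ...) {
  d <- dim(x$U); p <- dim(x$V)[1L]
  cat(sprintf("<tsvdm> %d x %d x %d tensor, k = %d; M kind = %s\n",
              d[1L], p, d[3L], d[2L], x$M$kind))
  invisible(x)
}

#' Materialize the f-diagonal tensor S
#'
#' The factorization stores only the k x n matrix of hat-domain diagonals;
#' this expands it to the full k x k x n f-diagonal tensor (original domain).
#'
#' @param factors A `tsvdm` object.
#' @return A k x k x n array.
#' @export
tsvdm_s_tensor <- function(factors) {
  k <- nrow(factors$s_hat); n <- ncol(factors$s_hat)
  S_hat <- array(0, dim = c(k, k, n))
  for (i in seq_len(n)) S_hat[, , i] <- diag(factors$s_hat[, i], nrow = k)
  mode3_inverse(S_hat, factors$M)
}

#' Reconstruct a tensor from its tsvdm factors
#'
#' Computes `U *M S *M t(V)`, optionally with hat-domain diagonals zeroed by
#' an explicit-rank keep mask.
#'
#' @param factors A `tsvdm` object.
#' @param keep Optional logical k x n matrix; diagonals where `keep` is
#'   `FALSE` are zeroed before reconstruction.
#' @return The reconstructed m x p x n array.
#' @export
tsvdm_reconstruct <- function(factors, keep = NULL) {
  U_hat <- mode3_product(factors$U, factors$M)
  V_hat <- mode3_product(factors$V, factors$M)
  s <- factors$s_hat
  if (!is.null(keep)) {
    stopifnot(all(dim(keep) == dim(s)))
    s <- s * keep
  }
  m <- dim(U_hat)[1L]; p <- dim(V_hat)[1L]; n <- ncol(s)
  out_hat <- array(0, dim = c(m, p, n))
  for (i in seq_len(n)) {
    u <- U_hat[, , i, drop = FALSE][, , 1L]
    v <- V_hat[, , i, drop = FALSE][, , 1L]
    out_hat[, , i] <- u %*% (s[, i] * t(v))
  }
  mode3_inverse(out_hat, factors$M)
}

#' Explicit rank-q truncation of a tsvdm
#'
#' Keeps only the q globally largest hat-domain singular values across all
#' faces — the ordering given by the ranking vector — and zeroes the rest.
#' For orthonormal M the truncation error obeys
#' `||A - A_q||_F^2 = sum of the dropped squared singular values`, and among
#' all keep-sets of q diagonals this choice minimizes the error.
#'
#' @param factors A `tsvdm` object.
#' @param q Number of diagonals to keep, between 0 and k * n.
#' @param ranking Optional ranking-vector tibble from [ranking_vector()];
#'   computed from `factors$s_hat` when omitted.
#' @return A `tsvdm` object whose `s_hat` has all but q entries zeroed.
#' @export
truncate_explicit_rank <- function(factors, q, ranking = NULL) {
  kn <- length(factors$s_hat)
  if (!is.numeric(q) || length(q) != 1L || q != round(q) || q < 0 || q > kn) {
    abort(sprintf("`q` must be an integer in [0, %d].", kn),
          class = "tcam_invalid_argument")
  }
  if (is.null(ranking)) ranking <- ranking_vector(factors$s_hat)
  keep <- matrix(FALSE, nrow = nrow(factors$s_hat), ncol = ncol(factors$s_hat))
  if (q > 0) {
    kept <- ranking[seq_len(q), ]
    keep[cbind(kept$diag_index, kept$face_index)] <- TRUE
  }
  factors$s_hat <- factors$s_hat * keep
  factors
}
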