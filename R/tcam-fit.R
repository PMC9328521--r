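#' Ranking vector: global ordering of hat-domain singular values
#'
#' Orders all (diagonal index, face index) pairs of the hat-domain
#' f-diagonal by descending singular value. Ties are broken by ascending
#' face index, then ascending diagonal index (stable and documented, so two
#' fits of the same tensor agree bitwise). The ranking defines the order of
#' the tcam factors and of explicit-rank truncation.
#'
#' @param s_hat A k x n matrix of non-negative hat-domain singular values.
#' @return A tibble with columns `factor` (h = 1..k*n), `diag_index`,
#'   `face_index`, and `sigma`, with `sigma` non-increasing.
#' @export
ranking_vector <- function(s_hat) {
  s_hat <- base::as.matrix(s_hat)
  if (any(s_hat < 0)) {
    abort("singular values must be non-negative.", class = "tcam_value_error")
  }
  k <- nrow(s_hat); n <- ncol(s_hat)
  grid <- tibble(
    diag_index = rep(seq_len(k), times = n),
    face_index = rep(seq_len(n), each = k),
    sigma = as.vector(s_hat)
  )
  ord <- order(-grid$sigma, grid$face_index, grid$diag_index)
  out <- grid[ord, ]
  out$factor <- seq_len(k * n)
  out[, c("factor", "diag_index", "face_index", "sigma")]
}

#' Mean sample of a tensor
#'
#' The entrywise mean over the subject axis: a 1 x p x n tensor whose single
#' horizontal slice is the average trajectory of the cohort.
#'
#' @param A An m x p x n array.
#' @return A 1 x p x n array.
#' @export
mean_sample <- function(A) {
  assert_tensor3(A)
  d <- dim(A)
  array(colMeans(matrix(A, nrow = d[1L])), dim = c(1L, d[2L], d[3L]))
}

#' Center a tensor to mean-deviation form (MDF)
#'
#' Subtracts the mean sample from every horizontal slice, after which the
#' mean sample of the result is exactly zero. tcam always centers its input;
#' this helper exposes the operation (it is idempotent).
#'
#' @param A An m x p x n array.
#' @return A list with `centered` (m x p x n) and `mean_sample` (1 x p x n).
#' @export
center_mdf <- function(A) {
  abar <- mean_sample(A)
  d <- dim(A)
  centered <- A - array(rep(abar, each = d[1L]) , dim = d)
  dimnames(centered) <- dimnames(A)
  list(centered = centered, mean_sample = abar)
}

#' Fit a tensor component analysis (tcam)
#'
#' Centers the subjects x features x timepoints tensor to mean-deviation
#' form, computes its tubal SVD under the star-M product, and orders the
#' hat-domain singular values into a global ranking that defines the tcam
#' factors. Each subject's full trajectory becomes a single point in the
#' reduced space; the explained-variance fraction of factor h is
#' `sigma_h^2 / sum_j sigma_j^2`.
#'
#' @param x A numeric m x p x n array, or a `tensor_dataset` from
#'   [assemble_tensor()] / the normalization front-ends.
#' @param M An `m_transform`; defaults to the orthonormal DCT-II of size n.
#' @param q Number of components to retain; default all `k * n` with
#'   `k = min(m, p)`. Truncation never changes the leading factors (nesting).
#' @return An object of class `tcam`: list with `mean_sample`, `ranking`
#'   (tibble), `V` (p x k x n right factor tensor), `M`, `scores`
#'   (m x k*n matrix, training scores), `explained_variance`
#'   (length k*n, non-increasing, sums to 1), `q`, and the axis labels.
#' @examples
#' A <- array(rnorm(6 * 10 * 4), dim = c(6, 10, 4))
#' fit <- tcam(A)
#' head(fit$explained_variance)
#' @export
tcam <- function(x, M = NULL, q = NULL) {
  ds <- NULL
  if (inherits(x, "tensor_dataset")) {
    ds <- x
    A <- ds$tensor
  } else {
    A <- x
  }
  assert_tensor3(A, "x")
  d <- dim(A)
  if (d[1L] < 2L) {
    abort("tcam needs at least 2 subjects.", class = "tcam_invalid_input")
  }
  if (is.null(M)) M <- m_transform(d[3L], "dct2")
  stopifnot(inherits(M, "m_transform"))
  if (M$n != d[3L]) {
    abort(sprintf("M side (%d) must equal the number of timepoints (%d).", M$n, d[3L]),
          class = "tcam_shape_error")
  }

  ctr <- center_mdf(A)
  if (frobenius_norm(ctr$centered) == 0) {
    abort("all horizontal slices are identical: total variance is zero.",
          class = "tcam_degenerate_input")
  }
  factors <- tsvdm(ctr$centered, M)
  ranking <- ranking_vector(factors$s_hat)
  kn <- nrow(ranking)
  if (is.null(q)) q <- kn
  if (!is.numeric(q) || length(q) != 1L || q != round(q) || q < 1 || q > kn) {
    abort(sprintf("`q` must be an integer in [1, %d].", kn),
          class = "tcam_invalid_argument")
  }

  # Training scores via U-hat * sigma; must (and does, tested) agree with
  # the definitional path used by predict().
  U_hat <- mode3_product(factors$U, M)
  Z <- matrix(0, nrow = d[1L], ncol = kn)
  for (h in seq_len(kn)) {
    Z[, h] <- U_hat[, ranking$diag_index[h], ranking$face_index[h]] * ranking$sigma[h]
  }

  ev <- ranking$sigma^2 / sum(ranking$sigma^2)

  subject_labels <- dimnames(A)[[1L]] %||% paste0("S", seq_len(d[1L]))
  feature_labels <- dimnames(A)[[2L]] %||% paste0("f", seq_len(d[2L]))
  timepoint_labels <- dimnames(A)[[3L]] %||% paste0("t", seq_len(d[3L]))
  rownames(Z) <- subject_labels
  colnames(Z) <- paste0("F", seq_len(kn))

  structure(
    list(mean_sample = ctr$mean_sample,
         ranking = ranking,
         V = factors$V,
         M = M,
         scores = Z,
         explained_variance = ev,
         q = as.integer(q),
         subject_labels = subject_labels,
         feature_labels = feature_labels,
         timepoint_labels = timepoint_labels,
         normalization_log = if (!is.null(ds)) ds$normalization_log else list()),
    class = "tcam"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tcam <- function(x, ...) {
  p <- dim(x$V)[1L]; n <- dim(x$V)[3L]
  cat(sprintf("tcam fit: %d subjects x %d features x %d timepoints\n",
              nrow(x$scores), p, n))
  cat(sprintf("  M: %s(%d); components retained: %d of %d\n",
              x$M$kind, x$M$n, x$q, length(x$explained_variance)))
  cat(sprintf("  explained variance (first %d): %s\n",
              min(5L, x$q),
              paste(sprintf("%.3f", head(x$explained_variance, 5L)), collapse = ", ")))
  invisible(x)
}

#' Truncate a fitted tcam to q components
#'
#' The tcam factors are fixed by the data and M; truncation just narrows the
#' retained block, so scores and loadings for factors 1..q are bitwise equal
#' to the leading block of any larger-q model from the same fit.
#'
#' @param model A fitted `tcam`.
#' @param q New number of retained components.
#' @return The model with `q` updated.
#' @export
truncate_model <- function(model, q) {
  kn <- length(model$explained_variance)
  if (!is.numeric(q) || length(q) != 1L || q != round(q) || q < 1 || q > kn) {
    abort(sprintf("`q` must be an integer in [1, %d].", kn),
          class = "tcam_invalid_argument")
  }
  model$q <- as.integer(q)
  model
}

#' Smallest q reaching a cumulative explained-variance threshold
#'
#' @param model A fitted `tcam`.
#' @param threshold Fraction in (0, 1].
#' @return The smallest integer q with cumulative explained variance >=
#'   `threshold`.
#' @export
choose_q_by_variance <- function(model, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].", class = "tcam_invalid_argument")
  }
  cum <- cumsum(model$explained_variance)
  # tolerate roundoff at the top of the cumulative sum
  which(cum >= threshold - 1e-12)[1L]
}
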