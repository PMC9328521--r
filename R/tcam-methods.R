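#' Subject scores of a fitted tcam
#'
#' One row per subject, one column per retained factor; row i is the image
#' of subject i's whole trajectory in the reduced space. Scores are returned
#' as a tibble so they pipe directly into plotting and downstream testing.
#'
#' @param model A fitted `tcam`.
#' @param q Number of factors; defaults to the model's retained `q`.
#' @return A tibble with columns `subject`, `F1`, ..., `Fq`.
#' @export
tcam_scores <- function(model, q = model$q) {
  stopifnot(inherits(model, "tcam"))
  q <- check_q(model, q)
  Z <- model$scores[, seq_len(q), drop = FALSE]
  dplyr::bind_cols(tibble(subject = model$subject_labels), as_tibble(Z))
}

check_q <- function(model, q) {
  kn <- length(model$explained_variance)
  if (!is.numeric(q) || length(q) != 1L || q != round(q) || q < 1 || q > kn) {
    abort(sprintf("`q` must be an integer in [1, %d].", kn),
          class = "tcam_invalid_argument")
  }
  as.integer(q)
}

#' Loadings of a fitted tcam
#'
#' Row h of the loadings matrix is the hat-domain right singular vector
#' selected by the h-th entry of the ranking vector: the per-feature
#' contribution (magnitude and direction) to factor h. Rows have unit
#' Euclidean norm, and rows drawn from the same hat face are mutually
#' orthogonal.
#'
#' @param model A fitted `tcam`.
#' @param q Number of factors; defaults to the model's retained `q`.
#' @param matrix If `TRUE` return the raw q x p matrix instead of a tibble.
#' @return A tibble with columns `factor`, `feature`, `loading` (or a q x p
#'   matrix with feature labels as column names).
#' @export
tcam_loadings <- function(model, q = model$q, matrix = FALSE) {
  stopifnot(inherits(model, "tcam"))
  q <- check_q(model, q)
  V_hat <- mode3_product(model$V, model$M)
  p <- dim(V_hat)[1L]
  L <- base::matrix(0, nrow = q, ncol = p,
                    dimnames = list(paste0("F", seq_len(q)), model$feature_labels))
  for (h in seq_len(q)) {
    L[h, ] <- V_hat[, model$ranking$diag_index[h], model$ranking$face_index[h]]
  }
  if (matrix) return(L)
  tibble(
    factor = rep(seq_len(q), times = p),
    feature = rep(model$feature_labels, each = q),
    loading = as.vector(L)
  ) |> dplyr::arrange(.data$factor, .data$feature)
}

#' Project new trajectories into a fitted tcam space
#'
#' Out-of-sample extension: each new subject's p x n trajectory is centered
#' with the training mean sample, multiplied by the fitted right factor
#' tensor under the star-M product, carried to the hat domain, and read out
#' at the ranked (diagonal, face) positions. For a training slice this
#' reproduces the fitted score row to numerical precision.
#'
#' @param object A fitted `tcam`.
#' @param newdata An m' x p x n array (or 1 x p x n for one subject, or a
#'   `tensor_dataset`), with the model's features and timepoints. When the
#'   array carries dimnames, features and timepoints are aligned by label.
#' @param q Number of factors; defaults to the model's retained `q`.
#' @param ... Unused.
#' @return A tibble with columns `subject`, `F1`, ..., `Fq`.
#' @export
predict.tcam <- function(object, newdata, q = object$q, ...) {
  q <- check_q(object, q)
  if (inherits(newdata, "tensor_dataset")) newdata <- newdata$tensor
  if (is.matrix(newdata)) newdata <- array(newdata, dim = c(1L, dim(newdata)))
  assert_tensor3(newdata, "newdata")
  newdata <- align_to_model(object, newdata)
  d <- dim(newdata)
  p <- dim(object$V)[1L]; n <- dim(object$V)[3L]
  if (d[2L] != p || d[3L] != n) {
    abort(sprintf("newdata is %d x %d x %d but the model expects p = %d, n = %d.",
                  d[1L], d[2L], d[3L], p, n),
          class = "tcam_shape_error")
  }
  X <- newdata - array(rep(object$mean_sample, each = d[1L]), dim = d)
  # ((X - Abar) *M V) x3 M  ==  X-hat face-multiplied by V-hat
  X_hat <- mode3_product(X, object$M)
  V_hat <- mode3_product(object$V, object$M)
  ZV <- facewise_product(X_hat, V_hat)
  Z <- matrix(0, nrow = d[1L], ncol = q)
  for (h in seq_len(q)) {
    Z[, h] <- ZV[, object$ranking$diag_index[h], object$ranking$face_index[h]]
  }
  colnames(Z) <- paste0("F", seq_len(q))
  subj <- dimnames(newdata)[[1L]] %||% paste0("new", seq_len(d[1L]))
  dplyr::bind_cols(tibble(subject = subj), as_tibble(Z))
}

# Label-based alignment of newdata to the model's feature/timepoint order;
# positional when the array carries no dimnames.
align_to_model <- function(model, A) {
  dn <- dimnames(A)
  if (!is.null(dn) && !is.null(dn[[2L]])) {
    missing <- setdiff(model$feature_labels, dn[[2L]])
    extra <- setdiff(dn[[2L]], model$feature_labels)
    if (length(missing) || length(extra)) {
      abort(paste0("feature mismatch with the model.",
                   if (length(missing)) paste0(" Missing: ",
                     paste(head(missing, 10L), collapse = ", "), "."),
                   if (length(extra)) paste0(" Extra: ",
                     paste(head(extra, 10L), collapse = ", "), ".")),
            class = "tcam_shape_error")
    }
    A <- A[, model$feature_labels, , drop = FALSE]
  }
  dn <- dimnames(A)
  if (!is.null(dn) && !is.null(dn[[3L]])) {
    if (!setequal(dn[[3L]], model$timepoint_labels)) {
      abort("timepoint labels do not match the model.", class = "tcam_shape_error")
    }
    A <- A[, , model$timepoint_labels, drop = FALSE]
  }
  A
}

#' Tidy a tcam fit (broom-style)
#'
#' @param x A fitted `tcam`.
#' @param matrix Which quantity to return: `"scores"` (default),
#'   `"loadings"`, or `"eigenvalues"` (singular values and explained
#'   variance per factor).
#' @param ... Unused.
#' @return A tibble in long form.
#' @export
tidy.tcam <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = tcam_scores(x) |>
      tidyr::pivot_longer(-"subject", names_to = "factor",
                          names_prefix = "F", names_transform = as.integer,
                          values_to = "score"),
    loadings = tcam_loadings(x),
    eigenvalues = scree_table(x) |>
      dplyr::mutate(sigma = x$ranking$sigma[.data$factor], .after = "factor")
  )
}

#' One-row summary of a tcam fit (broom-style)
#'
#' @param x A fitted `tcam`.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, retained q, and the cumulative
#'   explained variance of the retained factors.
#' @export
glance.tcam <- function(x, ...) {
  tibble(
    n_subjects = nrow(x$scores),
    n_features = dim(x$V)[1L],
    n_timepoints = dim(x$V)[3L],
    n_components = length(x$explained_variance),
    q = x$q,
    var_explained_q = sum(x$explained_variance[seq_len(x$q)]),
    m_kind = x$M$kind
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
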