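#' Top-loading features of a factor
#'
#' The loadings matrix supports a simple pruning strategy: keep only the
#' fraction of features contributing most (by absolute loading) to a factor
#' of interest. Contributions are reported signed — a large positive loading
#' pushes that factor's scores upwards — and ranked by magnitude, with ties
#' broken by feature label for determinism.
#'
#' @param model A fitted `tcam`.
#' @param factor Factor index (1-based, within the retained `q`).
#' @param frac Fraction of features to keep, in (0, 1]; `ceiling(frac * p)`
#'   features are returned. No default: analyses in the field use different
#'   cutoffs (e.g. 2.5% or 5%) and the choice is substantive.
#' @return A tibble with columns `rank`, `feature`, `contribution`, ordered
#'   by descending `abs(contribution)`.
#' @export
top_loadings_features <- function(model, factor, frac) {
  stopifnot(inherits(model, "tcam"))
  kn <- length(model$explained_variance)
  if (!is.numeric(factor) || length(factor) != 1L || factor != round(factor) ||
      factor < 1 || factor > kn) {
    abort(sprintf("`factor` must be an integer in [1, %d].", kn),
          class = "tcam_invalid_argument")
  }
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac > 1) {
    abort("`frac` must lie in (0, 1].", class = "tcam_invalid_argument")
  }
  L <- tcam_loadings(model, q = max(model$q, factor), matrix = TRUE)
  contrib <- L[factor, ]
  rank_features(contrib, ceiling(frac * length(contrib)))
}

rank_features <- function(contrib, n_keep = length(contrib)) {
  ord <- order(-abs(contrib), names(contrib))
  kept <- ord[seq_len(n_keep)]
  tibble(
    rank = seq_len(n_keep),
    feature = names(contrib)[kept],
    contribution = unname(contrib[kept])
  )
}

#' Project loadings onto a direction in score space
#'
#' Given a direction w in the reduced space (for instance the normal to a
#' classifier's decision boundary), ranks features by the projected
#' contribution `sum_h w_h * loading[h, j]` — which features push subjects
#' along that direction.
#'
#' @param model A fitted `tcam`.
#' @param direction Numeric vector of length `q`.
#' @return A tibble with columns `rank`, `feature`, `contribution`.
#' @export
project_loadings_direction <- function(model, direction) {
  stopifnot(inherits(model, "tcam"))
  if (!is.numeric(direction) || length(direction) != model$q) {
    abort(sprintf("`direction` must be a numeric vector of length q = %d.", model$q),
          class = "tcam_shape_error")
  }
  L <- tcam_loadings(model, matrix = TRUE)
  contrib <- drop(crossprod(L, direction))
  names(contrib) <- colnames(L)
  rank_features(contrib)
}

#' Pairwise distances between subject trajectories in score space
#'
#' Euclidean distances between score rows. At full rank (all k*n factors,
#' orthonormal M) these equal the Frobenius distances between the centered
#' trajectories themselves, so the reduced-space configuration is faithful.
#'
#' @param scores A numeric matrix of scores (subjects x factors), a tibble
#'   from [tcam_scores()], or a fitted `tcam`.
#' @return A symmetric m x m matrix with zero diagonal.
#' @export
pairwise_trajectory_distances <- function(scores) {
  if (inherits(scores, "tcam")) scores <- tcam_scores(scores)
  if (is.data.frame(scores)) {
    labels <- if ("subject" %in% names(scores)) scores$subject else NULL
    scores <- base::as.matrix(scores[vapply(scores, is.numeric, logical(1))])
    rownames(scores) <- labels
  }
  D <- base::as.matrix(stats::dist(scores))
  dimnames(D) <- list(rownames(scores), rownames(scores))
  D
}

#' Scree table of a fitted tcam
#'
#' Explained-variance fraction and cumulative fraction per factor, the data
#' behind a scree plot and behind variance-threshold choices of q.
#'
#' @param model A fitted `tcam`.
#' @return A tibble with columns `factor`, `variance_fraction`,
#'   `cumulative_fraction` (final entry 1 up to roundoff).
#' @export
scree_table <- function(model) {
  stopifnot(inherits(model, "tcam"))
  ev <- model$explained_variance
  tibble(
    factor = seq_along(ev),
    variance_fraction = ev,
    cumulative_fraction = cumsum(ev)
  )
}

#' Export a feature ranking to CSV
#'
#' @param ranking A tibble from [top_loadings_features()] or
#'   [project_loadings_direction()].
#' @param path Output file path.
#' @param label Value for the `direction` column (e.g. "F1" or "decision").
#' @return `path`, invisibly.
#' @export
write_feature_ranking <- function(ranking, path, label = "F1") {
  out <- dplyr::mutate(ranking, direction = label, .before = 1L)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
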