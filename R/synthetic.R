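#' Specification for the synthetic longitudinal cohort
#'
#' Describes a fully sampled cohort with group-specific temporal signal,
#' subject-level static offsets, and noise — the two variance regimes that
#' dominate real longitudinal omics data: large static inter-individual
#' differences, and smaller temporal intra-individual variation carrying the
#' biology of interest. Defaults describe a modest two-arm study: 2 groups
#' of 10 subjects, 50 features of which 3 carry a group-specific temporal
#' effect of amplitude 3, subject offsets of SD 1 per (subject, feature),
#' and additive Gaussian noise of SD 0.5.
#'
#' @param groups Number of groups.
#' @param subjects_per_group Subjects in each group.
#' @param p Number of features.
#' @param n Number of timepoints.
#' @param signal_features Number of features carrying the group effect.
#' @param effect_profile A groups x n matrix of per-timepoint effect sizes;
#'   by default group g follows `amplitude * (g - 1) * ramp(t)`, a ramp from
#'   0 at the first timepoint to the full amplitude at the last, so the
#'   baseline timepoint is group-neutral.
#' @param amplitude Peak effect size used by the default profile.
#' @param baseline_level Mean level added to every feature.
#' @param subject_offset_sd SD of the static per-(subject, feature) offset.
#' @param noise_sd SD of the additive Gaussian noise.
#' @param mode `"continuous"` (Gaussian, proteomics-like) or `"counts"`
#'   (log-normal-Poisson chain, microbiome-like, for rclr testing).
#' @param seed Integer seed; all randomness flows from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(groups = 2, subjects_per_group = 10, p = 50, n = 8,
                           signal_features = 3, effect_profile = NULL,
                           amplitude = 3, baseline_level = 0,
                           subject_offset_sd = 1, noise_sd = 0.5,
                           mode = c("continuous", "counts"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(groups >= 1, subjects_per_group >= 1, p >= 1, n >= 1,
            signal_features >= 0, signal_features <= p,
            subject_offset_sd >= 0, noise_sd >= 0)
  if (is.null(effect_profile)) {
    ramp <- if (n == 1L) 1 else (seq_len(n) - 1) / (n - 1)
    effect_profile <- outer(seq_len(groups) - 1, ramp) * amplitude
  }
  effect_profile <- base::as.matrix(effect_profile)
  stopifnot(nrow(effect_profile) == groups, ncol(effect_profile) == n)
  structure(
    list(groups = as.integer(groups),
         subjects_per_group = as.integer(subjects_per_group),
         p = as.integer(p), n = as.integer(n),
         signal_features = as.integer(signal_features),
         effect_profile = effect_profile,
         baseline_level = baseline_level,
         subject_offset_sd = subject_offset_sd,
         noise_sd = noise_sd,
         mode = mode,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic longitudinal cohort
#'
#' Entry (i, j, t) is
#' `baseline_level + offset[i, j] + effect_profile[group(i), t] * 1[j in signal set] + noise`,
#' with the signal set being the first `signal_features` features. In
#' `"counts"` mode this quantity parameterizes the log-mean of a
#' log-normal-Poisson draw instead, giving sparse non-negative counts
#' suitable for rclr. All randomness derives from the spec's single seed.
#'
#' @param spec A `synthetic_spec`.
#' @return A list with `dataset` (a `tensor_dataset`) and `groups` (a tibble
#'   with columns `subject`, `group`).
#' @export
generate_longitudinal_tensor <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)

  m <- spec$groups * spec$subjects_per_group
  p <- spec$p; n <- spec$n
  group_of <- rep(seq_len(spec$groups), each = spec$subjects_per_group)
  subjects <- sprintf("S%02d", seq_len(m))
  features <- sprintf("f%03d", seq_len(p))
  times <- sprintf("t%02d", seq_len(n))

  offset <- matrix(rnorm(m * p, sd = spec$subject_offset_sd), m, p)
  signal <- seq_len(spec$signal_features)
  A <- array(spec$baseline_level, dim = c(m, p, n),
             dimnames = list(subjects, features, times))
  for (t in seq_len(n)) {
    slab <- matrix(A[, , t], m, p) + offset
    if (length(signal)) {
      slab[, signal] <- slab[, signal] + spec$effect_profile[group_of, t]
    }
    A[, , t] <- slab
  }
  if (spec$noise_sd > 0) {
    A <- A + array(rnorm(m * p * n, sd = spec$noise_sd), dim = dim(A),
                   dimnames = dimnames(A))
  }
  if (spec$mode == "counts") {
    # log-normal-Poisson chain: the latent Gaussian field becomes a log-mean
    lambda <- exp(A)
    A[] <- stats::rpois(length(A), lambda = as.vector(lambda))
  }

  ds <- new_tensor_dataset(A,
                           missing = matrix(FALSE, m, n,
                                            dimnames = list(subjects, times)),
                           log = list())
  list(dataset = ds,
       groups = tibble(subject = subjects, group = paste0("G", group_of)))
}

#' Construct a tensor of known explicit rank
#'
#' Builds star-M-orthogonal factors with exactly `q` nonzero hat-domain
#' diagonals and returns their product, so the tsvdm of the result recovers
#' exactly `q` nonzero singular values and its explicit rank-q truncation is
#' lossless.
#'
#' @param m,p,n Tensor dimensions.
#' @param q Target explicit rank, between 0 and `min(m, p) * n`.
#' @param M An `m_transform` with side length n.
#' @param seed Integer seed for the random orthonormal factors.
#' @return An m x p x n array.
#' @export
planted_rank_tensor <- function(m, p, n, q, M, seed = 1) {
  k <- min(m, p)
  if (!is.numeric(q) || q != round(q) || q < 0 || q > k * n) {
    abort(sprintf("`q` must be an integer in [0, %d].", k * n),
          class = "tcam_invalid_argument")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))

  U_hat <- array(0, dim = c(m, k, n))
  V_hat <- array(0, dim = c(p, k, n))
  for (i in seq_len(n)) {
    U_hat[, , i] <- qr.Q(qr(matrix(rnorm(m * k), m, k)))
    V_hat[, , i] <- qr.Q(qr(matrix(rnorm(p * k), p, k)))
  }
  # spread the q kept diagonals across faces round-robin with distinct,
  # well-separated magnitudes
  s_hat <- matrix(0, k, n)
  if (q > 0) {
    slots <- cbind(diag = rep(seq_len(k), times = n), face = rep(seq_len(n), each = k))
    slots <- slots[order(slots[, "diag"], slots[, "face"]), , drop = FALSE]
    pick <- slots[seq_len(q), , drop = FALSE]
    s_hat[pick] <- seq(from = q, to = 1)
  }
  out_hat <- array(0, dim = c(m, p, n))
  for (i in seq_len(n)) {
    out_hat[, , i] <- U_hat[, , i] %*% (s_hat[, i] * t(V_hat[, , i]))
  }
  mode3_inverse(out_hat, M)
}
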