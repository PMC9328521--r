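#' Assemble a long-format feature table into a tensor dataset
#'
#' Builds the order-3 tensor (subjects x features x timepoints) from tidy
#' long records with columns `subject`, `time`, `feature`, `value`. A
#' (subject, timepoint) sample is *present* when it has at least one record;
#' features absent from a present sample are filled with `fill` (0 for count
#' data — absence of a taxon is a zero, not a missing value). Whole missing
#' samples are an error in `"strict"` mode and are marked for
#' [impute_missing()] in `"impute"` mode. Subjects and features are sorted
#' lexicographically so the assembly is deterministic.
#'
#' @param data A data frame with columns `subject`, `time`, `feature`,
#'   `value` (extra columns are ignored).
#' @param timepoint_order Character vector giving the time axis order;
#'   defaults to the sorted unique `time` values. Must cover every timepoint
#'   present in the data.
#' @param mode `"strict"` (complete grid required) or `"impute"` (missing
#'   whole samples allowed, recorded in the missing mask).
#' @param fill Value for features absent from a present sample (default 0).
#' @return An object of class `tensor_dataset`: list with `tensor` (a named
#'   m x p x n array), `subject_labels`, `feature_labels`,
#'   `timepoint_labels`, `missing` (m x n logical matrix of whole missing
#'   samples), and `normalization_log`.
#' @export
assemble_tensor <- function(data, timepoint_order = NULL,
                            mode = c("strict", "impute"), fill = 0) {
  mode <- match.arg(mode)
  req <- c("subject", "time", "feature", "value")
  if (!all(req %in% names(data))) {
    abort(paste0("`data` must have columns: ", paste(req, collapse = ", "), "."),
          class = "tcam_invalid_input")
  }
  if (nrow(data) == 0L) {
    abort("`data` has no records.", class = "tcam_invalid_input")
  }
  data <- dplyr::mutate(data, dplyr::across(c("subject", "time", "feature"), as.character))
  dup <- data |>
    dplyr::count(.data$subject, .data$time, .data$feature) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0("duplicate (subject, time, feature) keys, e.g. (",
                 dup$subject[1L], ", ", dup$time[1L], ", ", dup$feature[1L], ")."),
          class = "tcam_duplicate_key")
  }
  subjects <- sort(unique(data$subject))
  features <- sort(unique(data$feature))
  times_present <- unique(data$time)
  if (is.null(timepoint_order)) {
    timepoint_order <- sort(times_present)
  } else {
    timepoint_order <- as.character(timepoint_order)
    uncovered <- setdiff(times_present, timepoint_order)
    if (length(uncovered)) {
      abort(paste0("`timepoint_order` does not cover timepoint(s): ",
                   paste(uncovered, collapse = ", "), "."),
            class = "tcam_invalid_argument")
    }
  }

  m <- length(subjects); p <- length(features); n <- length(timepoint_order)
  A <- array(fill, dim = c(m, p, n),
             dimnames = list(subjects, features, timepoint_order))
  A[cbind(data$subject, data$feature, data$time)] <- data$value

  present <- matrix(FALSE, m, n, dimnames = list(subjects, timepoint_order))
  seen <- unique(data[, c("subject", "time")])
  present[cbind(seen$subject, seen$time)] <- TRUE
  missing <- !present
  if (any(missing)) {
    offenders <- which(missing, arr.ind = TRUE)
    labels <- paste0("(", subjects[offenders[, 1L]], ", ",
                     timepoint_order[offenders[, 2L]], ")")
    if (mode == "strict") {
      abort(paste0("missing sample(s): ", paste(labels, collapse = ", "),
                   "; use mode = \"impute\" or complete the grid."),
            class = "tcam_missing_sample")
    }
    A[cbind(rep(offenders[, 1L], each = p),
            rep(seq_len(p), times = nrow(offenders)),
            rep(offenders[, 2L], each = p))] <- NA_real_
  }

  new_tensor_dataset(A, missing = missing, log = list())
}

new_tensor_dataset <- function(A, missing, log) {
  structure(
    list(tensor = A,
         subject_labels = dimnames(A)[[1L]],
         feature_labels = dimnames(A)[[2L]],
         timepoint_labels = dimnames(A)[[3L]],
         missing = missing,
         normalization_log = log),
    class = "tensor_dataset"
  )
}

#' @export
print.tensor_dataset <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<tensor_dataset> %d subjects x %d features x %d timepoints\n",
              d[1L], d[2L], d[3L]))
  if (any(x$missing)) cat(sprintf("  missing samples: %d\n", sum(x$missing)))
  if (length(x$normalization_log)) {
    cat("  transforms:", paste(vapply(x$normalization_log, `[[`, "", "op"),
                               collapse = " -> "), "\n")
  }
  invisible(x)
}

log_step <- function(ds, op, params = list()) {
  ds$normalization_log <- c(ds$normalization_log, list(list(op = op, params = params)))
  ds
}

#' Impute whole missing samples
#'
#' Naive schemes for filling whole (subject, timepoint) samples marked
#' missing at assembly: `"zeros"` fills 0; `"locf"` carries the last
#' observed timepoint forward (and the first observed backward at the
#' start); `"linear"` interpolates each (subject, feature) tube between
#' observed timepoints (constant extrapolation at the ends).
#'
#' @param ds A `tensor_dataset`.
#' @param method One of `"zeros"`, `"locf"`, `"linear"`.
#' @return The dataset with no missing samples and the imputation logged.
#' @export
impute_missing <- function(ds, method = c("zeros", "locf", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "tensor_dataset"))
  A <- ds$tensor
  d <- dim(A)
  for (i in seq_len(d[1L])) {
    miss <- ds$missing[i, ]
    if (!any(miss)) next
    if (all(miss)) {
      abort(sprintf("subject %s has no observed timepoints; cannot impute.",
                    ds$subject_labels[i]),
            class = "tcam_unimputable")
    }
    obs <- which(!miss)
    for (j in seq_len(d[2L])) {
      tube <- A[i, j, ]
      A[i, j, ] <- switch(method,
        zeros = {
          tube[miss] <- 0; tube
        },
        locf = {
          idx <- findInterval(seq_len(d[3L]), obs)
          idx[idx == 0L] <- 1L          # backward fill before the first observation
          tube[obs[idx]]
        },
        linear = stats::approx(obs, tube[obs], xout = seq_len(d[3L]),
                               method = "linear", rule = 2)$y
      )
    }
  }
  ds$tensor <- A
  ds$missing[] <- FALSE
  log_step(ds, "impute_missing", list(method = method))
}

check_baseline <- function(ds, baseline) {
  baseline <- as.character(baseline)
  absent <- setdiff(baseline, ds$timepoint_labels)
  if (length(absent)) {
    abort(paste0("baseline timepoint(s) not in the dataset: ",
                 paste(absent, collapse = ", "), "."),
          class = "tcam_invalid_argument")
  }
  if (any(ds$missing[, baseline, drop = FALSE])) {
    abort("some subjects are missing their baseline sample(s); impute first.",
          class = "tcam_missing_sample")
  }
  if (any(ds$missing)) {
    abort("dataset still has missing samples; impute before normalizing.",
          class = "tcam_missing_sample")
  }
  baseline
}

# Per-subject, per-feature baseline value: mean over the baseline timepoints.
baseline_slice <- function(A, baseline) {
  B <- A[, , baseline, drop = FALSE]
  apply(B, c(1L, 2L), mean)
}

#' Deviation-from-baseline (DFB) normalization
#'
#' Per subject and feature, subtracts that subject's own baseline value
#' (the mean over the baseline timepoints when several are given) from every
#' timepoint. Each trajectory is thereby re-expressed as deviation from the
#' subject's personal baseline, removing static inter-individual offsets —
#' the dominant source of variance in most longitudinal omics cohorts.
#' Baseline slices become (exactly, for a single baseline timepoint) zero
#' and are retained in the tensor so n stays consistent across subjects.
#'
#' @param ds A `tensor_dataset` with no missing samples.
#' @param baseline Character vector of baseline timepoint label(s).
#' @return The normalized dataset, with the step logged.
#' @export
normalize_dfb <- function(ds, baseline) {
  stopifnot(inherits(ds, "tensor_dataset"))
  baseline <- check_baseline(ds, baseline)
  base_val <- baseline_slice(ds$tensor, baseline)
  ds$tensor <- ds$tensor - array(rep(base_val, dim(ds$tensor)[3L]), dim = dim(ds$tensor),
                                 dimnames = dimnames(ds$tensor))
  log_step(ds, "normalize_dfb", list(baseline = baseline))
}

#' Log-fold-baseline (LFB) normalization
#'
#' Per subject and feature, each value becomes
#' `log_base((x_t + pseudocount) / (x_baseline + pseudocount))`, the log
#' fold change relative to the subject's own baseline (mean over baseline
#' timepoints when several). The symmetric pseudocount keeps zeros finite;
#' with base 2 the output reads as doublings/halvings relative to baseline.
#'
#' @param ds A `tensor_dataset` of non-negative values, no missing samples.
#' @param baseline Character vector of baseline timepoint label(s).
#' @param pseudocount Positive value added inside the ratio (default 1,
#'   suited to counts).
#' @param log_base Logarithm base (default 2).
#' @return The normalized dataset, with the step logged.
#' @export
normalize_lfb <- function(ds, baseline, pseudocount = 1, log_base = 2) {
  stopifnot(inherits(ds, "tensor_dataset"))
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("`pseudocount` must be positive.", class = "tcam_invalid_argument")
  }
  if (any(ds$tensor < 0, na.rm = TRUE)) {
    abort("LFB requires non-negative values.", class = "tcam_value_error")
  }
  baseline <- check_baseline(ds, baseline)
  base_val <- baseline_slice(ds$tensor, baseline)
  denom <- array(rep(base_val + pseudocount, dim(ds$tensor)[3L]),
                 dim = dim(ds$tensor), dimnames = dimnames(ds$tensor))
  ds$tensor <- log((ds$tensor + pseudocount) / denom, base = log_base)
  log_step(ds, "normalize_lfb",
           list(baseline = baseline, pseudocount = pseudocount, log_base = log_base))
}

#' Robust centered log-ratio (rclr) normalization
#'
#' Compositional normalization applied per sample (one subject x timepoint
#' feature vector): each nonzero entry becomes its natural log minus the
#' mean natural log over that sample's nonzero entries; zeros are excluded
#' from the geometric mean and remain 0 (the matched-mask convention),
#' avoiding the distortion a pseudocount imposes on sparse compositions.
#'
#' @param ds A `tensor_dataset` of non-negative values, no missing samples.
#' @return The normalized dataset, with the step logged.
#' @export
normalize_rclr <- function(ds) {
  stopifnot(inherits(ds, "tensor_dataset"))
  if (any(ds$missing)) {
    abort("dataset still has missing samples; impute before normalizing.",
          class = "tcam_missing_sample")
  }
  A <- ds$tensor
  if (any(A < 0)) {
    abort("rclr requires non-negative values.", class = "tcam_value_error")
  }
  d <- dim(A)
  for (i in seq_len(d[1L])) {
    for (t in seq_len(d[3L])) {
      x <- A[i, , t]
      nz <- x > 0
      if (!any(nz)) {
        abort(sprintf("sample (%s, %s) is all-zero; rclr is undefined.",
                      ds$subject_labels[i], ds$timepoint_labels[t]),
              class = "tcam_value_error")
      }
      lx <- log(x[nz])
      x[nz] <- lx - mean(lx)
      x[!nz] <- 0
      A[i, , t] <- x
    }
  }
  ds$tensor <- A
  log_step(ds, "normalize_rclr")
}

#' Filter features by prevalence and mean value
#'
#' Keeps features whose fraction of nonzero (subject, timepoint) samples is
#' at least `min_prevalence` and whose overall mean value is at least
#' `min_mean_value`. Label order is preserved.
#'
#' @param ds A `tensor_dataset`.
#' @param min_prevalence Fraction in \[0, 1\].
#' @param min_mean_value Minimum mean over all entries.
#' @return The filtered dataset, with the decision logged.
#' @export
filter_features <- function(ds, min_prevalence = 0, min_mean_value = -Inf) {
  stopifnot(inherits(ds, "tensor_dataset"))
  A <- ds$tensor
  prev <- apply(A != 0 & !is.na(A), 2L, mean)
  mu <- apply(A, 2L, mean, na.rm = TRUE)
  keep <- prev >= min_prevalence & mu >= min_mean_value
  if (!any(keep)) {
    abort("no features pass the filter.", class = "tcam_empty_result")
  }
  ds$tensor <- A[, keep, , drop = FALSE]
  ds$feature_labels <- ds$feature_labels[keep]
  log_step(ds, "filter_features",
           list(min_prevalence = min_prevalence, min_mean_value = min_mean_value))
}

#' Replay a normalization log on raw data
#'
#' The normalization log fully determines the transform chain: applying it
#' to the same raw dataset reproduces the processed dataset exactly.
#'
#' @param ds A raw `tensor_dataset` (e.g. fresh from [assemble_tensor()]).
#' @param log A `normalization_log` from a processed dataset.
#' @return The re-processed dataset.
#' @export
replay_normalization <- function(ds, log) {
  for (step in log) {
    ds <- switch(step$op,
      impute_missing = impute_missing(ds, method = step$params$method),
      normalize_dfb = normalize_dfb(ds, baseline = step$params$baseline),
      normalize_lfb = normalize_lfb(ds, baseline = step$params$baseline,
                                    pseudocount = step$params$pseudocount,
                                    log_base = step$params$log_base),
      normalize_rclr = normalize_rclr(ds),
      filter_features = filter_features(ds,
                                        min_prevalence = step$params$min_prevalence,
                                        min_mean_value = step$params$min_mean_value),
      abort(sprintf("unknown log step `%s`.", step$op), class = "tcam_invalid_argument")
    )
  }
  ds
}

#' Convert a tensor dataset back to a long tibble
#'
#' @param ds A `tensor_dataset`.
#' @return A tibble with columns `subject`, `time`, `feature`, `value`
#'   (missing samples as `NA`).
#' @export
as_long_tibble <- function(ds) {
  stopifnot(inherits(ds, "tensor_dataset"))
  d <- dim(ds$tensor)
  tibble(
    subject = rep(ds$subject_labels, times = d[2L] * d[3L]),
    feature = rep(rep(ds$feature_labels, each = d[1L]), times = d[3L]),
    time = rep(ds$timepoint_labels, each = d[1L] * d[2L]),
    value = as.vector(ds$tensor)
  )[, c("subject", "time", "feature", "value")]
}

#' Read / write the tidy long CSV format
#'
#' The long CSV has header `subject,time,feature,value`; it is the
#' interchange format between the synthetic generator, the preprocessing
#' front-end, and the command-line interface.
#'
#' @param path CSV file path.
#' @return `read_long_csv()` returns a tibble; `write_long_csv()` returns
#'   `path` invisibly.
#' @export
read_long_csv <- function(path) {
  as_tibble(read.csv(path, colClasses = c(subject = "character",
                                          time = "character",
                                          feature = "character",
                                          value = "numeric")))
}

#' @rdname read_long_csv
#' @param x A data frame with columns `subject`, `time`, `feature`, `value`,
#'   or a `tensor_dataset`.
#' @export
write_long_csv <- function(x, path) {
  if (inherits(x, "tensor_dataset")) x <- as_long_tibble(x)
  write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a BIOM table into long format
#'
#' Thin adapter over the biomformat package for microbiome feature tables:
#' observations become features, samples are split into subject and
#' timepoint by a separator in the sample identifier
#' (`<subject><sep><time>`).
#'
#' @param path A BIOM file.
#' @param sep Separator between subject and timepoint in sample ids.
#' @return A tibble with columns `subject`, `time`, `feature`, `value`.
#' @export
read_biom_long <- function(path, sep = "_") {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("the biomformat package is required to read BIOM files.",
          class = "tcam_invalid_argument")
  }
  b <- biomformat::read_biom(path)
  mat <- base::as.matrix(biomformat::biom_data(b))  # observations x samples
  parts <- strsplit(colnames(mat), sep, fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    abort(paste0("sample id(s) not of the form <subject>", sep, "<time>: ",
                 paste(colnames(mat)[bad], collapse = ", ")),
          class = "tcam_invalid_input")
  }
  tibble(
    subject = rep(vapply(parts, `[[`, "", 1L), each = nrow(mat)),
    time = rep(vapply(parts, function(z) paste(z[-1L], collapse = sep), ""),
               each = nrow(mat)),
    feature = rep(rownames(mat), times = ncol(mat)),
    value = as.vector(mat)
  )
}
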