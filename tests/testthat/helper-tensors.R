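# Shared fixtures, generated in code.

rand_tensor <- function(m, p, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(m * p * n), dim = c(m, p, n))
}

# Random MDF tensor (centered over subjects).
rand_mdf_tensor <- function(m, p, n, seed = NULL) {
  center_mdf(rand_tensor(m, p, n, seed))$centered
}

# Small fully sampled long table: values encode their own key for checks.
toy_long_table <- function() {
  grid <- expand.grid(subject = c("A", "B"), time = c("t01", "t02"),
                      feature = c("f1", "f2"), stringsAsFactors = FALSE)
  grid$value <- seq_len(nrow(grid))
  tibble::as_tibble(grid)
}

# Dataset wrapper around a plain array, for normalization tests.
as_toy_dataset <- function(A) {
  d <- dim(A)
  dimnames(A) <- list(sprintf("S%02d", seq_len(d[1])),
                      sprintf("f%02d", seq_len(d[2])),
                      sprintf("t%02d", seq_len(d[3])))
  ds <- assemble_tensor(tcam::as_long_tibble(
    structure(list(tensor = A,
                   subject_labels = dimnames(A)[[1]],
                   feature_labels = dimnames(A)[[2]],
                   timepoint_labels = dimnames(A)[[3]],
                   missing = matrix(FALSE, d[1], d[3]),
                   normalization_log = list()),
              class = "tensor_dataset")))
  ds
}
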