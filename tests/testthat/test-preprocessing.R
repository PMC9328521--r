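test_that("assembly places values by key and sorts axes deterministically", {
  tbl <- toy_long_table()
  ds <- assemble_tensor(tbl)
  expect_equal(dim(ds$tensor), c(2L, 2L, 2L))
  for (r in seq_len(nrow(tbl))) {
    expect_equal(ds$tensor[tbl$subject[r], tbl$feature[r], tbl$time[r]],
                 tbl$value[r])
  }
  # shuffling rows changes nothing
  ds2 <- assemble_tensor(tbl[sample(nrow(tbl)), ])
  expect_identical(ds2$tensor, ds$tensor)
})

test_that("assembly flags duplicates, missing samples, and absent features", {
  tbl <- toy_long_table()
  expect_error(assemble_tensor(rbind(tbl, tbl[1, ])), class = "tcam_duplicate_key")

  dropped <- dplyr::filter(tbl, !(subject == "B" & time == "t02"))
  expect_error(assemble_tensor(dropped, mode = "strict"),
               class = "tcam_missing_sample", regexp = "\\(B, t02\\)")
  ds <- assemble_tensor(dropped, mode = "impute")
  expect_true(ds$missing["B", "t02"])
  expect_true(all(is.na(ds$tensor["B", , "t02"])))

  # feature absent from a present sample is 0, not missing
  partial <- dplyr::filter(tbl, !(subject == "A" & time == "t01" & feature == "f2"))
  ds3 <- assemble_tensor(partial)
  expect_equal(ds3$tensor["A", "f2", "t01"], 0)

  expect_error(assemble_tensor(tbl, timepoint_order = "t01"),
               class = "tcam_invalid_argument")
})

test_that("imputation fills whole missing samples by the requested scheme", {
  tbl <- tibble::tibble(
    subject = rep("A", 2), time = c("t01", "t3"),
    feature = rep("f1", 2), value = c(1, 3)
  )
  ds <- assemble_tensor(tbl, timepoint_order = c("t01", "t02", "t3"), mode = "impute")
  expect_equal(as.vector(impute_missing(ds, "linear")$tensor["A", "f1", ]),
               c(1, 2, 3))
  expect_equal(as.vector(impute_missing(ds, "zeros")$tensor["A", "f1", ]),
               c(1, 0, 3))
  expect_equal(as.vector(impute_missing(ds, "locf")$tensor["A", "f1", ]),
               c(1, 1, 3))

  # backward fill at the start
  tbl2 <- dplyr::mutate(tbl, time = c("t02", "t3"), value = c(5, 5))
  ds2 <- assemble_tensor(tbl2, timepoint_order = c("t01", "t02", "t3"), mode = "impute")
  expect_equal(as.vector(impute_missing(ds2, "locf")$tensor["A", "f1", ]),
               c(5, 5, 5))

  # no missing entries: identity apart from the log entry
  full <- assemble_tensor(toy_long_table())
  expect_identical(impute_missing(full, "linear")$tensor, full$tensor)

  # a subject with no observed samples cannot be imputed
  tbl3 <- dplyr::bind_rows(
    tibble::tibble(subject = "A", time = c("t01", "t02"), feature = "f1", value = 1),
    tibble::tibble(subject = "B", time = "t01", feature = "f2", value = 2)
  )
  ds3 <- assemble_tensor(tbl3, mode = "impute")
  ds3$missing["B", ] <- TRUE
  ds3$tensor["B", , ] <- NA_real_
  expect_error(impute_missing(ds3, "zeros"), class = "tcam_unimputable")
})

test_that("DFB zeroes baseline slices and subtracts per-subject references", {
  A <- array(0, dim = c(2, 2, 2))
  A[1, 1, ] <- c(2, 5); A[1, 2, ] <- c(4, 4); A[2, 1, ] <- c(1, 7); A[2, 2, ] <- c(3, 3)
  ds <- as_toy_dataset(A)
  out <- normalize_dfb(ds, baseline = "t01")
  expect_equal(unname(out$tensor[, , "t01"]), matrix(0, 2, 2))        # baseline -> 0
  expect_equal(unname(out$tensor[1, 1, "t02"]), 3)                    # (2,5) -> (0,3)
  expect_equal(unname(out$tensor[1, 2, "t02"]), 0)                    # constant tube -> 0

  # multiple baseline timepoints aggregate by the mean
  B <- array(rnorm(2 * 3 * 4), dim = c(2, 3, 4))
  dsb <- as_toy_dataset(B)
  outb <- normalize_dfb(dsb, baseline = c("t01", "t02"))
  ref <- (B[, , 1] + B[, , 2]) / 2
  expect_equal(unname(outb$tensor[, , 3]), B[, , 3] - ref, tolerance = 1e-12)

  expect_error(normalize_dfb(ds, baseline = "t09"), class = "tcam_invalid_argument")
})

test_that("LFB computes symmetric-pseudocount log fold changes from baseline", {
  A <- array(0, dim = c(2, 2, 2))
  A[1, 1, ] <- c(1, 3)   # log2((3+1)/(1+1)) = 1
  A[1, 2, ] <- c(2, 2)   # equal to baseline -> 0
  A[2, 1, ] <- c(0, 0)   # 0 vs 0 -> 0
  A[2, 2, ] <- c(4, 1)
  ds <- as_toy_dataset(A)
  out <- normalize_lfb(ds, baseline = "t01", pseudocount = 1, log_base = 2)
  expect_equal(unname(out$tensor[1, 1, "t02"]), 1)
  expect_equal(unname(out$tensor[1, 2, "t02"]), 0)
  expect_equal(unname(out$tensor[2, 1, "t02"]), 0)
  expect_equal(unname(out$tensor[, , "t01"]), matrix(0, 2, 2))

  neg <- as_toy_dataset(array(-1, dim = c(2, 2, 2)))
  expect_error(normalize_lfb(neg, baseline = "t01"), class = "tcam_value_error")
})

test_that("rclr centers nonzero entries by their log mean and masks zeros", {
  A <- array(1, dim = c(2, 4, 2))
  A[1, , 1] <- c(1, 2, 4, 1)
  A[1, , 2] <- c(3, 3, 3, 3)
  A[2, , 1] <- c(1, 1, 1, 0)
  A[2, , 2] <- c(2, 0, 0, 8)
  ds <- as_toy_dataset(A)
  out <- normalize_rclr(ds)
  gm <- exp(mean(log(c(1, 2, 4, 1))))
  expect_equal(unname(out$tensor[1, , 1]), log(c(1, 2, 4, 1) / gm), tolerance = 1e-12)
  expect_equal(unname(out$tensor[1, , 2]), rep(0, 4))           # constant sample
  expect_equal(unname(out$tensor[2, , 1]), rep(0, 4))           # zeros masked
  expect_equal(unname(out$tensor[2, , 2]), c(-1, 0, 0, 1) * log(2), tolerance = 1e-12)

  # nonzero support sums to 0 on random sparse compositions
  set.seed(1)
  counts <- array(rpois(5 * 10 * 3, lambda = 2), dim = c(5, 10, 3))
  counts[1, , 1] <- pmax(counts[1, , 1], 1)  # guard the all-zero sample case
  dsr <- as_toy_dataset(counts)
  outr <- normalize_rclr(dsr)
  for (i in 1:5) for (t in 1:3) {
    nz <- counts[i, , t] > 0
    expect_lt(abs(sum(outr$tensor[i, nz, t])), 1e-12)
  }

  allzero <- as_toy_dataset(array(0, dim = c(2, 3, 2)))
  expect_error(normalize_rclr(allzero), class = "tcam_value_error")
})

test_that("baseline normalizations are per-subject local and order-invariant", {
  set.seed(2)
  A <- array(abs(rnorm(4 * 5 * 3)), dim = c(4, 5, 3))
  ds <- as_toy_dataset(A)
  out <- normalize_dfb(ds, baseline = "t01")

  # permute subjects, normalize, permute back: identical result
  perm <- c(3, 1, 4, 2)
  dsp <- ds
  dsp$tensor <- ds$tensor[perm, , ]
  dsp$subject_labels <- ds$subject_labels[perm]
  dimnames(dsp$tensor)[[1]] <- dsp$subject_labels
  outp <- normalize_dfb(dsp, baseline = "t01")
  expect_equal(outp$tensor[order(perm), , ], out$tensor, tolerance = 1e-14)

  # changing one subject's values leaves the others untouched
  ds2 <- ds
  ds2$tensor[1, , ] <- ds2$tensor[1, , ] * 2
  out2 <- normalize_lfb(ds2, baseline = "t01")
  ref <- normalize_lfb(ds, baseline = "t01")
  expect_equal(out2$tensor[-1, , ], ref$tensor[-1, , ], tolerance = 1e-14)
})

test_that("feature filtering applies prevalence and mean rules in order", {
  A <- array(1, dim = c(2, 4, 2))
  A[, 2, ] <- 0                       # zero everywhere: fails prevalence
  A[1, 3, ] <- 0                      # prevalence 0.5
  A[, 4, ] <- 0.01                    # low mean
  ds <- as_toy_dataset(A)
  out <- filter_features(ds, min_prevalence = 0.6, min_mean_value = 0.5)
  expect_equal(out$feature_labels, "f01")

  ident <- filter_features(ds, min_prevalence = 0, min_mean_value = -Inf)
  expect_identical(ident$tensor, ds$tensor)

  expect_error(filter_features(ds, min_prevalence = 2), class = "tcam_empty_result")
})

test_that("the normalization log replays to a bitwise-identical dataset", {
  set.seed(3)
  counts <- array(rpois(4 * 8 * 3, lambda = 5), dim = c(4, 8, 3))
  raw <- as_toy_dataset(counts)
  processed <- raw |>
    filter_features(min_prevalence = 0.2) |>
    normalize_lfb(baseline = "t01", pseudocount = 0.5, log_base = 2)
  replayed <- replay_normalization(raw, processed$normalization_log)
  expect_identical(replayed$tensor, processed$tensor)
  expect_identical(replayed$normalization_log, processed$normalization_log)
})

test_that("long CSV and long tibble round-trip the dataset", {
  set.seed(4)
  A <- array(rnorm(3 * 4 * 2), dim = c(3, 4, 2))
  ds <- as_toy_dataset(A)
  path <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(ds, path)
  back <- assemble_tensor(read_long_csv(path))
  expect_equal(back$tensor, ds$tensor, tolerance = 1e-12)
})

test_that("BIOM tables read into the long format", {
  skip_if_not_installed("biomformat")
  # tiny BIOM (JSON flavor) written on the fly
  mat <- matrix(c(1, 0, 3, 2, 5, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("taxA", "taxB"),
                                c("S1_t1", "S1_t2", "S2_t1")))
  b <- biomformat::make_biom(mat)
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, path)
  tbl <- read_biom_long(path)
  expect_setequal(names(tbl), c("subject", "time", "feature", "value"))
  expect_equal(dplyr::filter(tbl, subject == "S1", time == "t1",
                             feature == "taxA")$value, 1)
  expect_equal(nrow(tbl), 6)
})
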