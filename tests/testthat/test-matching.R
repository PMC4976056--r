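cmatrix <- function(v, lids = NULL, rids = NULL) {
  if (is.null(lids)) lids <- paste0("L", seq_len(nrow(v)))
  if (is.null(rids)) rids <- paste0("R", seq_len(ncol(v)))
  dimnames(v) <- list(lids, rids)
  comparison_matrix(v)
}

test_that("a single-cell matrix declares its trivial pair", {
  rep <- mutual_match(cmatrix(matrix(0.5, 1, 1)))
  expect_equal(nrow(rep$declared_pairs), 1L)
  expect_equal(rep$declared_pairs$value, 0.5)
  expect_equal(nrow(rep$declared_singletons), 0L)
})

test_that("non-mutual best candidates are rejected (A->B, B->C scenario)", {
  # L1's best is R1, but R1's best is L2 (and vice versa: L2 <-> R1 mutual)
  v <- rbind(c(0.5, 2.0),
             c(0.3, 1.8))
  rep <- mutual_match(cmatrix(v))
  expect_equal(rep$declared_pairs$left_id, "L2")
  expect_equal(rep$declared_pairs$right_id, "R1")
  expect_true("L1" %in% rep$declared_singletons$id)
  expect_true("R2" %in% rep$declared_singletons$id)
  # evidence for the disagreement is retained in the top-k lists
  expect_equal(rep$top_candidates$candidate[
    rep$top_candidates$id == "L1" & rep$top_candidates$rank == 1], "R1")
})

test_that("planted diagonal-dominant matrices are recovered exactly", {
  for (s in 1:20) {
    v <- osteopair:::with_seed(s, {
      n <- 5
      m <- matrix(stats::runif(n * n, 3, 8), n, n)
      diag(m) <- stats::runif(n, 0.4, 0.9)
      m
    })
    cm <- cmatrix(v)
    rep <- mutual_match(cm)
    # brute-force oracle: mutual row/column minima
    oracle <- which(outer(seq_len(5), seq_len(5), Vectorize(function(i, j)
      which.min(v[i, ]) == j && which.min(v[, j]) == i)), arr.ind = TRUE)
    expect_equal(nrow(rep$declared_pairs), nrow(oracle))
    expect_setequal(paste(rep$declared_pairs$left_id,
                          rep$declared_pairs$right_id),
                    paste0("L", oracle[, 1], " R", oracle[, 2]))
    expect_equal(nrow(rep$declared_singletons), 0L)
  }
})

test_that("matching is invariant to row and column order", {
  v <- osteopair:::with_seed(9, matrix(stats::runif(20, 1, 5), 4, 5))
  v[cbind(1:4, c(2, 4, 1, 5))] <- c(0.5, 0.6, 0.7, 0.8)
  dimnames(v) <- list(paste0("L", 1:4), paste0("R", 1:5))
  rep1 <- mutual_match(comparison_matrix(v))
  rep2 <- mutual_match(comparison_matrix(
    v[c(3, 1, 4, 2), c(5, 3, 1, 2, 4)]))
  key <- function(r) sort(paste(r$declared_pairs$left_id,
                                r$declared_pairs$right_id))
  expect_identical(key(rep1), key(rep2))
})

test_that("exact value ties declare no pair and warn", {
  v <- rbind(c(0.5, 0.5), c(2, 3))
  expect_warning(rep <- mutual_match(cmatrix(v)), "tie")
  expect_false("L1" %in% rep$declared_pairs$left_id)
})

test_that("failed cells act as absent candidates", {
  v <- rbind(c(NA, 0.4), c(0.3, NA))
  rep <- mutual_match(cmatrix(v))
  expect_setequal(paste(rep$declared_pairs$left_id,
                        rep$declared_pairs$right_id),
                  c("L1 R2", "L2 R1"))
  expect_error(mutual_match(cmatrix(matrix(NA_real_, 2, 2))), "empty")
})

test_that("topk agreement accepts within-list mutual candidates", {
  # L1's best (R2) is claimed by L2 with a lower value; under top-k
  # agreement L1 still pairs with R1 (mutual top-3), under mutual-best it
  # stays single
  v <- rbind(c(0.6, 0.5), c(3, 0.4))
  rep_best <- mutual_match(cmatrix(v), agreement = "best")
  rep_topk <- mutual_match(cmatrix(v), agreement = "topk")
  expect_false("R1" %in% rep_best$declared_pairs$right_id)
  expect_setequal(paste(rep_topk$declared_pairs$left_id,
                        rep_topk$declared_pairs$right_id),
                  c("L1 R1", "L2 R2"))
})

test_that("match reports round-trip through JSON", {
  v <- rbind(c(0.5, 2), c(3, 0.7))
  rep <- mutual_match(cmatrix(v))
  f <- withr::local_tempfile(fileext = ".json")
  write_match_report(rep, f)
  back <- read_match_report(f)
  expect_equal(back$declared_pairs$left_id, rep$declared_pairs$left_id)
  expect_equal(back$declared_pairs$value, rep$declared_pairs$value)
  expect_true(file.exists(sub("\\.json$", ".tsv", f)))
})

test_that("threshold analysis reproduces hand-computed cutoffs", {
  v <- diag(c(1, 1, 1))
  v[v == 0] <- 5
  truth <- data.frame(left_id = paste0("L", 1:3),
                      right_id = paste0("R", 1:3),
                      stringsAsFactors = FALSE)
  ta <- threshold_analysis(cmatrix(v), truth)
  expect_equal(ta$mean, 1)
  expect_equal(ta$sd, 0)
  expect_equal(ta$cutoff, 1)

  v2 <- matrix(5, 3, 3)
  v2[cbind(1:3, 1:3)] <- c(0.4, 0.6, 0.8)
  ta2 <- threshold_analysis(cmatrix(v2), truth)
  expect_equal(ta2$mean, 0.6)
  expect_equal(ta2$sd, 0.2)
  expect_equal(ta2$cutoff, 1.0)
  expect_equal(ta2$n_true_values_captured, 3L)
  expect_equal(ta2$n_false_values_below_cutoff, 0L)
})

test_that("threshold analysis distinguishes separated from overlapping matrices", {
  truth <- data.frame(left_id = paste0("L", 1:5),
                      right_id = paste0("R", 1:5),
                      stringsAsFactors = FALSE)
  sep <- osteopair:::with_seed(11, {
    m <- matrix(stats::runif(25, 4, 9), 5, 5)
    diag(m) <- stats::runif(5, 0.4, 0.8)
    m
  })
  expect_equal(threshold_analysis(cmatrix(sep),
                                  truth)$n_false_values_below_cutoff, 0L)

  overlapping <- osteopair:::with_seed(12, {
    m <- matrix(stats::runif(25, 0.5, 2), 5, 5)
    diag(m) <- stats::runif(5, 0.4, 1.5)
    m
  })
  expect_gt(threshold_analysis(cmatrix(overlapping),
                               truth)$n_false_values_below_cutoff, 0L)
})

test_that("threshold analysis needs at least two true pairs", {
  truth <- data.frame(left_id = "L1", right_id = "R1",
                      stringsAsFactors = FALSE)
  expect_error(threshold_analysis(cmatrix(matrix(c(1, 2, 3, 4), 2, 2)),
                                  truth), "at least 2")
})
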