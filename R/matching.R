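# Pair declaration from a comparison matrix (mutual-agreement rule) and the
# mean + 2 SD threshold analysis.

#' Declare pairs by the mutual-agreement rule
#'
#' For each bone the `k` lowest-value candidates are recorded; a pair (L, R)
#' is declared iff R is L's single lowest-value candidate AND L is R's single
#' lowest-value candidate (mutual best).  Non-best agreement is rejected —
#' the situation where left A points to right B but right B points to left C
#' produces no declared pair for any of the three.  All bones not in a
#' declared pair are declared singletons.  The top-k candidate lists are kept
#' in the report for analyst review.  Exact ties for the lowest value are
#' treated conservatively: no pair is declared and a warning is raised.
#'
#' With `agreement = "topk"` the looser reading is available: a pair is
#' declared when each bone appears in the other's top-k list and the pair is
#' the lowest-valued such mutual candidate for both (still one pair per
#' bone).
#'
#' @param cm a [comparison_matrix()] (or a plain named numeric matrix).
#'   Failed (`NA`) cells are treated as absent candidates.
#' @param k number of candidates kept per bone (default 3).
#' @param agreement `"best"` (default) or `"topk"`.
#' @return An object of class `match_report`: `declared_pairs` (data frame
#'   `left_id`, `right_id`, `value`), `declared_singletons` (data frame `id`,
#'   `side`) and `top_candidates` (data frame `id`, `side`, `rank`,
#'   `candidate`, `value`).
#' @export
mutual_match <- function(cm, k = 3L, agreement = NULL) {
  v <- if (inherits(cm, "comparison_matrix")) cm$values else as.matrix(cm)
  if (is.null(agreement))
    agreement <- if (inherits(cm, "comparison_matrix") &&
                     !is.null(cm$settings)) cm$settings$agreement else "best"
  agreement <- match.arg(agreement, c("best", "topk"))
  if (length(v) == 0L || all(is.na(v)))
    stop("empty comparison matrix: nothing to match")
  lids <- rownames(v)
  rids <- colnames(v)

  top_of <- function(vals, ids, k) {
    ok <- which(!is.na(vals))
    ok <- ok[order(vals[ok])]
    utils::head(data.frame(candidate = ids[ok], value = vals[ok],
                           stringsAsFactors = FALSE), k)
  }
  row_top <- lapply(seq_along(lids), function(i) top_of(v[i, ], rids, k))
  col_top <- lapply(seq_along(rids), function(j) top_of(v[, j], lids, k))

  # single lowest candidate per bone, NULL when tied or empty
  best_of <- function(vals) {
    ok <- which(!is.na(vals))
    if (length(ok) == 0L) return(NULL)
    mn <- min(vals[ok])
    hit <- ok[vals[ok] <= mn]
    if (length(hit) > 1L) return(structure(hit, tied = TRUE))
    hit
  }

  pairs <- list()
  tied_warned <- FALSE
  if (agreement == "best") {
    for (i in seq_along(lids)) {
      bi <- best_of(v[i, ])
      if (is.null(bi)) next
      if (isTRUE(attr(bi, "tied"))) { tied_warned <- TRUE; next }
      j <- bi
      bj <- best_of(v[, j])
      if (is.null(bj)) next
      if (isTRUE(attr(bj, "tied"))) { tied_warned <- TRUE; next }
      if (bj == i)
        pairs[[length(pairs) + 1L]] <-
          data.frame(left_id = lids[i], right_id = rids[j],
                     value = v[i, j], stringsAsFactors = FALSE)
    }
  } else {
    # topk agreement: mutual presence in each other's top-k lists, assigned
    # greedily by ascending value so each bone joins at most one pair
    cand <- list()
    for (i in seq_along(lids)) {
      ti <- row_top[[i]]
      for (r in seq_len(nrow(ti))) {
        j <- match(ti$candidate[r], rids)
        if (lids[i] %in% col_top[[j]]$candidate)
          cand[[length(cand) + 1L]] <-
            data.frame(left_id = lids[i], right_id = rids[j],
                       value = v[i, j], stringsAsFactors = FALSE)
      }
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand$value), , drop = FALSE]
      used_l <- character(0); used_r <- character(0)
      for (r in seq_len(nrow(cand))) {
        if (cand$left_id[r] %in% used_l || cand$right_id[r] %in% used_r)
          next
        pairs[[length(pairs) + 1L]] <- cand[r, , drop = FALSE]
        used_l <- c(used_l, cand$left_id[r])
        used_r <- c(used_r, cand$right_id[r])
      }
    }
  }
  if (tied_warned)
    warning("exact tie for lowest mesh-to-mesh value: no pair declared ",
            "for the tied bones")
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(left_id = character(0), right_id = character(0),
               value = numeric(0), stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(pairs$left_id), !anyDuplicated(pairs$right_id))

  single_l <- setdiff(lids, pairs$left_id)
  single_r <- setdiff(rids, pairs$right_id)
  singles <- data.frame(id = c(single_l, single_r),
                        side = c(rep("left", length(single_l)),
                                 rep("right", length(single_r))),
                        stringsAsFactors = FALSE)
  top <- rbind(
    do.call(rbind, lapply(seq_along(lids), function(i) {
      ti <- row_top[[i]]
      if (nrow(ti) == 0L) return(NULL)
      data.frame(id = lids[i], side = "left", rank = seq_len(nrow(ti)),
                 candidate = ti$candidate, value = ti$value,
                 stringsAsFactors = FALSE)
    })),
    do.call(rbind, lapply(seq_along(rids), function(j) {
      tj <- col_top[[j]]
      if (nrow(tj) == 0L) return(NULL)
      data.frame(id = rids[j], side = "right", rank = seq_len(nrow(tj)),
                 candidate = tj$candidate, value = tj$value,
                 stringsAsFactors = FALSE)
    })))
  rownames(pairs) <- rownames(singles) <- rownames(top) <- NULL
  structure(list(declared_pairs = pairs, declared_singletons = singles,
                 top_candidates = top, k = as.integer(k),
                 agreement = agreement),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("match_report (%s agreement): %d pair(s), %d singleton(s)\n",
              x$agreement, nrow(x$declared_pairs),
              nrow(x$declared_singletons)))
  if (nrow(x$declared_pairs)) {
    df <- x$declared_pairs
    df$value <- sprintf("%.4f", df$value)
    print(df, row.names = FALSE)
  }
  if (nrow(x$declared_singletons)) {
    cat("singletons:",
        paste(sprintf("%s (%s)", x$declared_singletons$id,
                      x$declared_singletons$side), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a match report
#'
#' JSON carries the declared pairs, singletons and top-k evidence; a TSV
#' sibling (same path with `.tsv`) lists pairs with their values for quick
#' reading.
#'
#' @param report a `match_report`.
#' @param path output `.json` path.
#' @export
write_match_report <- function(report, path) {
  jsonlite::write_json(list(agreement = report$agreement, k = report$k,
                            declared_pairs = report$declared_pairs,
                            declared_singletons = report$declared_singletons,
                            top_candidates = report$top_candidates),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tsv <- sub("\\.json$", ".tsv", path)
  if (tsv != path)
    utils::write.table(report$declared_pairs, tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_match_report
#' @export
read_match_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  empty_pairs <- data.frame(left_id = character(0),
                            right_id = character(0), value = numeric(0),
                            stringsAsFactors = FALSE)
  empty_single <- data.frame(id = character(0), side = character(0),
                             stringsAsFactors = FALSE)
  structure(list(
    declared_pairs = if (length(raw$declared_pairs))
      as.data.frame(raw$declared_pairs) else empty_pairs,
    declared_singletons = if (length(raw$declared_singletons))
      as.data.frame(raw$declared_singletons) else empty_single,
    top_candidates = if (length(raw$top_candidates))
      as.data.frame(raw$top_candidates) else NULL,
    k = raw$k %||% 3L, agreement = raw$agreement %||% "best"),
    class = "match_report")
}

#' Read / write a truth table of known pairs
#'
#' CSV with columns `left_id,right_id`; an empty `right_id` marks a left
#' singleton and an empty `left_id` a right singleton.
#'
#' @param path CSV path.
#' @return A data frame with character columns `left_id` and `right_id`
#'   (`NA` for the missing side of a singleton).
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("left_id", "right_id") %in% names(df)))
    stop("truth CSV must have columns left_id,right_id")
  df$left_id[!nzchar(df$left_id)] <- NA_character_
  df$right_id[!nzchar(df$right_id)] <- NA_character_
  df
}

#' @rdname read_truth
#' @param truth a truth data frame.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$left_id[is.na(out$left_id)] <- ""
  out$right_id[is.na(out$right_id)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean + 2 SD threshold analysis
#'
#' Computes the mean and sample standard deviation (n - 1 denominator) of
#' the true-pair mesh-to-mesh values, the cutoff `mean + 2 sd`, how many
#' true-pair values the cutoff captures, and how many non-pair cells also
#' fall below it — the diagnostic of whether a single global cutoff could
#' replace the matrix rule.
#'
#' @param cm a [comparison_matrix()].
#' @param truth truth data frame (see [read_truth()]).
#' @return An object of class `threshold_analysis` with fields `mean`, `sd`,
#'   `cutoff` (all mm), `true_values`, `n_true_values_captured` and
#'   `n_false_values_below_cutoff`.
#' @export
threshold_analysis <- function(cm, truth) {
  v <- if (inherits(cm, "comparison_matrix")) cm$values else as.matrix(cm)
  pairs <- truth[!is.na(truth$left_id) & !is.na(truth$right_id), ,
                 drop = FALSE]
  pairs <- pairs[pairs$left_id %in% rownames(v) &
                   pairs$right_id %in% colnames(v), , drop = FALSE]
  tv <- mapply(function(l, r) v[l, r], pairs$left_id, pairs$right_id)
  tv <- tv[!is.na(tv)]
  if (length(tv) < 2L)
    stop("threshold analysis needs at least 2 true-pair values ",
         "(standard deviation undefined)")
  is_true <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  for (r in seq_len(nrow(pairs)))
    is_true[pairs$left_id[r], pairs$right_id[r]] <- TRUE
  nonpair <- v[!is_true & !is.na(v)]
  m <- mean(tv)
  s <- stats::sd(tv)
  cutoff <- m + 2 * s
  structure(list(mean = m, sd = s, cutoff = cutoff,
                 true_values = as.numeric(tv),
                 n_true_values_captured = sum(tv <= cutoff),
                 n_false_values_below_cutoff = sum(nonpair <= cutoff)),
            class = "threshold_analysis")
}

#' @export
print.threshold_analysis <- function(x, ...) {
  cat(sprintf("threshold_analysis: true-pair mean %.3f mm, SD %.3f mm\n",
              x$mean, x$sd))
  cat(sprintf("  cutoff (mean + 2 SD): %.3f mm\n", x$cutoff))
  cat(sprintf("  true-pair values captured: %d of %d\n",
              x$n_true_values_captured, length(x$true_values)))
  cat(sprintf("  non-pair values below cutoff: %d\n",
              x$n_false_values_below_cutoff))
  invisible(x)
}
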