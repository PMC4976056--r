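# Scoring a match report against known truth: per-bone confusion counts,
# sensitivity and specificity.

#' Confusion counts and sensitivity/specificity
#'
#' The counting unit is the individual bone, not the pair: a bone in a
#' correctly declared pair is a true positive; a true-singleton bone declared
#' singleton is a true negative; a bone placed in a wrong pair is a false
#' positive (it asserts a false match, even if it does have a true partner
#' elsewhere); a truly-paired bone declared singleton — including one whose
#' partner was taken by a wrong pair — is a false negative.  Sensitivity is
#' TP/(TP+FN), specificity TN/(TN+FP); display rounds to whole percent,
#' full precision is retained in the object.
#'
#' @param tp,fn,fp,tn per-bone confusion counts.
#' @return An object of class `pair_score`.
#' @export
confusion_stats <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn),
                 sensitivity = sens, specificity = spec),
            class = "pair_score")
}

fmt_pct <- function(p) if (is.na(p)) "n/a" else sprintf("%.0f %%", 100 * p)

#' @export
print.pair_score <- function(x, ...) {
  cat(format_confusion_markdown(x), sep = "\n")
  invisible(x)
}

#' Markdown confusion table
#'
#' @param x a `pair_score`.
#' @return Character vector of Markdown lines.
#' @export
format_confusion_markdown <- function(x) {
  c("|                 |       |",
    "|-----------------|-------|",
    sprintf("| True positives  | %d |", x$tp),
    sprintf("| False negatives | %d |", x$fn),
    sprintf("| False positives | %d |", x$fp),
    sprintf("| True negatives  | %d |", x$tn),
    sprintf("| Sensitivity     | %s |", fmt_pct(x$sensitivity)),
    sprintf("| Specificity     | %s |", fmt_pct(x$specificity)))
}

#' Score a match report against known truth
#'
#' Applies the per-bone counting of [confusion_stats()] to the declared
#' pairs and singletons of a report.  Every id appearing in the report must
#' be covered by the truth table; bones in the truth table absent from the
#' report are not scored.
#'
#' @param report a `match_report` (see [mutual_match()]).
#' @param truth truth data frame with columns `left_id`, `right_id` (`NA`
#'   marks the missing side of a singleton); see [read_truth()].
#' @return A `pair_score` with an extra `per_bone` data frame
#'   (`id`, `side`, `outcome`).
#' @export
score_matches <- function(report, truth) {
  tl <- truth$left_id
  tr <- truth$right_id
  true_lefts <- tl[!is.na(tl)]
  true_rights <- tr[!is.na(tr)]
  if (anyDuplicated(true_lefts) || anyDuplicated(true_rights))
    stop("truth table assigns an id to more than one pair")
  partner_of_left <- stats::setNames(tr, tl)[true_lefts]
  partner_of_right <- stats::setNames(tl, tr)[true_rights]

  pl <- report$declared_pairs$left_id
  pr <- report$declared_pairs$right_id
  report_ids <- rbind(
    data.frame(id = c(pl, pr),
               side = c(rep("left", length(pl)), rep("right", length(pr))),
               stringsAsFactors = FALSE),
    report$declared_singletons)
  missing <- c(setdiff(report_ids$id[report_ids$side == "left"],
                       true_lefts),
               setdiff(report_ids$id[report_ids$side == "right"],
                       true_rights))
  if (length(missing))
    stop("id(s) in report missing from truth: ",
         paste(missing, collapse = ", "))

  outcomes <- list()
  note <- function(id, side, outcome)
    outcomes[[length(outcomes) + 1L]] <<-
      data.frame(id = id, side = side, outcome = outcome,
                 stringsAsFactors = FALSE)

  for (r in seq_len(nrow(report$declared_pairs))) {
    l <- report$declared_pairs$left_id[r]
    rr <- report$declared_pairs$right_id[r]
    correct <- !is.na(partner_of_left[l]) && partner_of_left[l] == rr
    note(l, "left", if (correct) "TP" else "FP")
    note(rr, "right", if (correct) "TP" else "FP")
  }
  for (r in seq_len(nrow(report$declared_singletons))) {
    id <- report$declared_singletons$id[r]
    side <- report$declared_singletons$side[r]
    has_partner <- if (side == "left") !is.na(partner_of_left[id])
                   else !is.na(partner_of_right[id])
    note(id, side, if (has_partner) "FN" else "TN")
  }
  per_bone <- do.call(rbind, outcomes)
  n <- table(factor(per_bone$outcome, levels = c("TP", "FN", "FP", "TN")))
  out <- confusion_stats(n[["TP"]], n[["FN"]], n[["FP"]], n[["TN"]])
  out$per_bone <- per_bone
  out
}

#' Write a score as JSON
#'
#' Counts plus full-precision sensitivity and specificity fractions.
#'
#' @param score a `pair_score`.
#' @param path output `.json` path.
#' @export
write_score <- function(score, path) {
  jsonlite::write_json(list(tp = score$tp, fn = score$fn, fp = score$fp,
                            tn = score$tn,
                            sensitivity = score$sensitivity,
                            specificity = score$specificity),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
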