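reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2)
  if (ov <= 0) return(0)
  min(ov / (e1 - s1), ov / (e2 - s2))
}

#' Score element predictions against synthetic ground truth
#'
#' Predictions and truth records match when they lie on the same
#' contig, have at least 50% reciprocal interval overlap, and agree in
#' class (the truth's `expected_class`).  Per-class precision, recall
#' and F1 are reported together with boundary-error statistics for the
#' matched pairs; truth records with `expected_class = NA` (decoys a
#' correct pipeline must ignore) only contribute false positives when
#' something is predicted on them.
#'
#' @param predictions element table from [annotate_retrozymes()].
#' @param truth truth table from [build_genome()].
#' @param min_overlap reciprocal-overlap threshold (default 0.5).
#' @return list with `metrics` (per-class data frame), `matches`
#'   (matched pairs with boundary errors) and `boundary_median`.
#' @export
evaluate_predictions <- function(predictions, truth, min_overlap = 0.5) {
  if (nrow(predictions) > 0 &&
      !all(predictions$contig %in% unique(truth$contig))) {
    stop("prediction contig(s) absent from truth: ",
         paste(setdiff(unique(predictions$contig), unique(truth$contig)),
               collapse = ", "))
  }
  classes <- sort(unique(c(predictions$class,
                           truth$expected_class[!is.na(truth$expected_class)])))
  matches <- list()
  metrics <- list()
  matched_pred <- rep(FALSE, nrow(predictions))
  for (cls in classes) {
    p_idx <- which(predictions$class == cls)
    t_idx <- which(!is.na(truth$expected_class) &
                     truth$expected_class == cls)
    used_t <- logical(length(t_idx))
    tp <- 0L
    for (pi in p_idx) {
      best <- 0; best_t <- NA_integer_
      for (k in seq_along(t_idx)) {
        ti <- t_idx[k]
        if (used_t[k] || truth$contig[ti] != predictions$contig[pi]) next
        ro <- reciprocal_overlap(predictions$start[pi], predictions$end[pi],
                                 truth$start[ti], truth$end[ti])
        if (ro >= min_overlap && ro > best) { best <- ro; best_t <- k }
      }
      if (!is.na(best_t)) {
        used_t[best_t] <- TRUE
        matched_pred[pi] <- TRUE
        tp <- tp + 1L
        ti <- t_idx[best_t]
        matches[[length(matches) + 1L]] <- data.frame(
          class = cls, pred_id = predictions$id[pi],
          truth_id = truth$id[ti],
          start_error = abs(predictions$start[pi] - truth$start[ti]),
          end_error = abs(predictions$end[pi] - truth$end[ti]),
          stringsAsFactors = FALSE)
      }
    }
    fp <- length(p_idx) - tp
    fn <- length(t_idx) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else NA_real_
    metrics[[length(metrics) + 1L]] <- data.frame(
      class = cls, n_truth = length(t_idx), n_pred = length(p_idx),
      tp = tp, fp = fp, fn = fn,
      precision = prec, recall = rec, f1 = f1, stringsAsFactors = FALSE)
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(class = character(0), pred_id = character(0),
               truth_id = character(0), start_error = integer(0),
               end_error = integer(0))
  bmed <- if (nrow(matches)) {
    median(pmax(matches$start_error, matches$end_error))
  } else NA_real_
  list(metrics = do.call(rbind, metrics), matches = matches,
       boundary_median = bmed)
}

#' Write an evaluation to TSV
#'
#' @param eval result of [evaluate_predictions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(eval, path) {
  write.table(eval$metrics, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
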