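#' One-against-all labels
#'
#' Labels the target disease positive and everything else — healthy
#' controls, every other disease, and the unconfirmed "Other" pool —
#' negative. Training against the union forces each panel to reject the
#' signatures of all other conditions, making it specific to its target.
#'
#' @param samples data.frame of sample records with a \code{group}
#'   column (or a \linkS4class{BloodExpressionSet}).
#' @param target_disease the group treated as positive.
#' @return logical vector, TRUE for target-disease samples.
#' @export
oneAgainstAll <- function(samples, target_disease) {
  if (is(samples, "BloodExpressionSet")) samples <- sampleInfo(samples)
  groups <- as.character(samples$group)
  if (!target_disease %in% groups)
    stop(sprintf("target disease '%s' not present among groups",
                 target_disease))
  y <- groups == target_disease
  if (all(y))
    stop("no negative samples: cohort contains only the target group")
  message(sprintf("one-against-all '%s': %d positive, %d negative",
                  target_disease, sum(y), sum(!y)))
  y
}

# Confusion-matrix metrics at the fixed score threshold 0, as percentages.
.thresholdMetrics <- function(scores, y, groups) {
  pos <- scores > 0
  ctrl <- !y & groups == "Control"
  others <- !y & groups != "Control"
  list(
    sensitivity = 100 * mean(pos[y]),
    control_specificity = if (any(ctrl)) 100 * mean(!pos[ctrl]) else NA_real_,
    others_specificity = if (any(others)) 100 * mean(!pos[others])
                         else NA_real_,
    auroc = 100 * auroc(scores[y], scores[!y])
  )
}

#' Iterated stratified k-fold cross-validation of the full pipeline
#'
#' Per iteration, the cohort is split into k stratified folds (class
#' ratio preserved); for each fold the ENTIRE pipeline — probe filtering,
#' replication balancing, pair screening, suppressor detection,
#' Monte-Carlo panel search, logistic fit — is re-run on the training
#' fold only, and the held-out fold is scored. Out-of-fold scores are
#' pooled across folds and iterations, and the metric set is computed on
#' the pool: sensitivity and specificities at the fixed threshold 0
#' (control specificity over healthy controls only, others-specificity
#' over other-disease samples only) and threshold-free AUROC. Pooling is
#' stabler than averaging per-iteration metrics when positive groups are
#' small. A fold that by chance lacks a class is resampled (and counted
#' in \code{n_resampled}), never silently dropped.
#'
#' @param es a \linkS4class{BloodExpressionSet} whose colData carries
#'   \code{group}.
#' @param target_disease positive class for [oneAgainstAll()].
#' @param config a [pipelineConfig()].
#' @param k number of folds (default 2).
#' @param iterations number of random re-splits.
#' @param seed integer; fixes folds and all in-fold randomness.
#' @return a CVReport: one-row data.frame (disease, sensitivity,
#'   control_specificity, others_specificity, auroc, n_iterations,
#'   fold_scheme), with the pooled per-sample score table in
#'   \code{attr(, "scores")} (sample_id, iteration, fold, score) and the
#'   resample count in \code{attr(, "n_resampled")}.
#' @export
crossValidate <- function(es, target_disease, config = pipelineConfig(),
                          k = 2L, iterations = 10L, seed = 1L) {
  info <- sampleInfo(es)
  y <- suppressMessages(oneAgainstAll(info, target_disease))
  if (sum(y) < 2 || sum(!y) < 2)
    stop("need at least 2 positive and 2 negative samples")
  set.seed(as.integer(seed))
  score_rows <- vector("list", iterations * k)
  n_resampled <- 0L
  row_i <- 0L
  for (it in seq_len(iterations)) {
    repeat {
      folds <- .stratifiedFolds(y, k)
      ok <- all(vapply(seq_len(k), function(f)
        sum(y[folds == f]) > 0 && sum(!y[folds == f]) > 0, logical(1)))
      if (ok) break
      n_resampled <- n_resampled + 1L
      message("fold without both classes; resampling split")
    }
    fold_seed <- sample.int(.Machine$integer.max, 1)
    for (f in seq_len(k)) {
      test <- folds == f
      cfg <- config
      cfg$search$seed <- (fold_seed + f) %% .Machine$integer.max
      fit <- trainPipeline(es[, !test], labels = y[!test], config = cfg,
                           seed = cfg$search$seed)
      s <- panelScore(fit$panel, es[, test])
      row_i <- row_i + 1L
      score_rows[[row_i]] <- data.frame(
        sample_id = info$sample_id[test], iteration = it, fold = f,
        score = unname(s), positive = y[test],
        group = info$group[test], stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, score_rows[seq_len(row_i)])
  m <- .thresholdMetrics(scores$score, scores$positive, scores$group)
  report <- data.frame(disease = target_disease,
                       sensitivity = m$sensitivity,
                       control_specificity = m$control_specificity,
                       others_specificity = m$others_specificity,
                       auroc = m$auroc,
                       n_iterations = iterations,
                       fold_scheme = sprintf("stratified %d-fold", k),
                       stringsAsFactors = FALSE)
  attr(report, "scores") <- scores
  attr(report, "n_resampled") <- n_resampled
  report
}

.stratifiedFolds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Write a CV report (plus per-sample scores) as CSV
#' @param report data.frame from [crossValidate()] (rows may be bound
#'   across diseases).
#' @param path output path for the report table.
#' @param scores_path optional path for the pooled out-of-fold score
#'   table.
#' @export
writeCVReport <- function(report, path, scores_path = NULL) {
  write.csv(report, path, row.names = FALSE, quote = FALSE)
  if (!is.null(scores_path) && !is.null(attr(report, "scores")))
    write.csv(attr(report, "scores"), scores_path, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
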