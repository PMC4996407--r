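#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen case value exceeds a randomly
#' chosen control value, ties counted one half:
#' \code{(#\{case_i > control_j\} + 0.5 #\{ties\}) / (n_case n_control)}.
#' Computed by midrank arithmetic, equivalent to exhaustive pair counting.
#'
#' @param case_values,control_values non-empty numeric vectors.
#' @return AUROC in [0, 1]; \code{auroc(a, b) == 1 - auroc(b, a)}.
#' @examples
#' auroc(c(3, 4, 5), c(1, 2))      # 1
#' auroc(c(2, 3, 5), c(1, 3, 4))   # 5.5/9
#' @export
auroc <- function(case_values, control_values) {
  n1 <- length(case_values)
  n0 <- length(control_values)
  if (!n1 || !n0) stop("both case and control groups must be non-empty")
  r <- rank(c(case_values, control_values), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Vectorized screening AUROC: one value per row of a feature matrix.
.aurocRows <- function(m, is_case) {
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  apply(m, 1, function(v) {
    r <- rank(v, ties.method = "average")
    (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
}

#' Pair-feature values on the log2 scale
#'
#' Ratio pairs are \code{log2(a) - log2(b)}; sum pairs are
#' \code{log2(a + b)}. A pair flagged \code{oriented} has its feature
#' negated (for a ratio this is exactly swapping numerator and
#' denominator), so that the recorded screening AUROC is always >= 0.5.
#' Log-ratio features are self-normalizing: any per-sample multiplicative
#' rescaling applied to both probes cancels exactly.
#'
#' @param sig signal matrix (probes x samples) with positive entries, or a
#'   \linkS4class{BloodExpressionSet}.
#' @param pairs data.frame with probe_a, probe_b, mode and (optionally)
#'   oriented columns.
#' @return numeric matrix, one row per pair, one column per sample.
#' @export
pairFeatureValues <- function(sig, pairs) {
  if (is(sig, "BloodExpressionSet")) sig <- signals(sig)
  if (any(sig <= 0))
    stop("non-positive signals cannot be log2-transformed; ",
         "run the probe filter (minimum signal 100) first")
  if (!nrow(pairs))
    return(matrix(0, 0, ncol(sig), dimnames = list(NULL, colnames(sig))))
  l2 <- log2(sig)
  a <- l2[pairs$probe_a, , drop = FALSE]
  b <- l2[pairs$probe_b, , drop = FALSE]
  f <- ifelse(matrix(pairs$mode == "ratio", nrow(pairs), ncol(sig)),
              a - b,
              log2(2^a + 2^b))
  if (!is.null(pairs$oriented)) f <- f * ifelse(pairs$oriented, -1, 1)
  dimnames(f) <- list(pairLabels(pairs), colnames(sig))
  f
}

#' Screen all probe pairs as ratio / sum features
#'
#' Enumerates every unordered pair of retained probes, computes the pair
#' feature on the log2 scale for each requested mode, and scores it by
#' screening AUROC for case vs control. Pairs are oriented (feature
#' negated, i.e. ratio flipped) so the recorded AUROC is >= 0.5. A pair is
#' classified \code{significant} when its AUROC reaches
#' \code{sig_threshold} (default 0.7). Sum pairs must additionally beat
#' the better of their two single-probe AUROCs by at least
#' \code{sum_margin} — the complementary-noise requirement: summing is
#' only useful when the pair's noise partially cancels.
#'
#' @param es \linkS4class{BloodExpressionSet} restricted (or about to be
#'   restricted via \code{probes}) to the filtered probe universe.
#' @param labels logical or factor/character vector per sample; TRUE (or
#'   \code{positive}) marks cases.
#' @param modes subset of c("ratio", "sum").
#' @param probes optional character vector restricting the probe universe.
#' @param sig_threshold screening AUROC needed to call a pair significant.
#' @param sum_margin minimum AUROC gain of a sum pair over its best
#'   single probe.
#' @param positive when \code{labels} is not logical, the level treated as
#'   case.
#' @return data.frame of PairFeature records: probe_a, probe_b, mode,
#'   oriented, auroc, klass (significant | neither; see
#'   [findSuppressors()] for the suppressor class).
#' @export
evaluatePairs <- function(es, labels, modes = c("ratio", "sum"),
                          probes = NULL, sig_threshold = 0.7,
                          sum_margin = 0.05, positive = NULL) {
  modes <- match.arg(modes, several.ok = TRUE)
  sig <- if (is(es, "BloodExpressionSet")) signals(es) else as.matrix(es)
  if (!is.null(probes)) sig <- sig[rownames(sig) %in% probes, , drop = FALSE]
  if (nrow(sig) < 2)
    stop("pair screening needs at least 2 retained probes")
  is_case <- .asCaseLogical(labels, positive)
  if (!any(is_case) || all(is_case))
    stop("both label groups must be non-empty")
  if (any(sig <= 0))
    stop("non-positive signals cannot be log2-transformed; ",
         "run the probe filter (minimum signal 100) first")
  l2 <- log2(sig)
  single_auc <- .aurocRows(l2, is_case)
  idx <- combn(nrow(sig), 2)
  pid <- rownames(sig)
  out <- list()
  if ("ratio" %in% modes) {
    feat <- l2[idx[1, ], , drop = FALSE] - l2[idx[2, ], , drop = FALSE]
    auc <- .aurocRows(feat, is_case)
    flip <- auc < 0.5
    out$ratio <- data.frame(
      probe_a = pid[idx[1, ]], probe_b = pid[idx[2, ]], mode = "ratio",
      oriented = flip, auroc = ifelse(flip, 1 - auc, auc),
      stringsAsFactors = FALSE
    )
  }
  if ("sum" %in% modes) {
    feat <- log2(sig[idx[1, ], , drop = FALSE] +
                   sig[idx[2, ], , drop = FALSE])
    auc <- .aurocRows(feat, is_case)
    flip <- auc < 0.5
    oa <- ifelse(flip, 1 - auc, auc)
    best_single <- pmax(pmax(single_auc[idx[1, ]], 1 - single_auc[idx[1, ]]),
                        pmax(single_auc[idx[2, ]], 1 - single_auc[idx[2, ]]))
    df <- data.frame(
      probe_a = pid[idx[1, ]], probe_b = pid[idx[2, ]], mode = "sum",
      oriented = flip, auroc = oa, stringsAsFactors = FALSE
    )
    df$sum_gain <- oa - best_single
    out$sum <- df
  }
  pairs <- do.call(rbind, lapply(out, function(d) {
    d$sum_gain <- if (is.null(d$sum_gain)) NA_real_ else d$sum_gain
    d
  }))
  rownames(pairs) <- NULL
  pairs$klass <- ifelse(
    pairs$auroc >= sig_threshold &
      (pairs$mode != "sum" | pairs$sum_gain >= sum_margin),
    "significant", "neither")
  pairs
}

.asCaseLogical <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  if (is.null(positive)) {
    lv <- unique(labels)
    if (length(lv) != 2)
      stop("labels must be logical or two-level; give 'positive' otherwise")
    positive <- lv[1]
  }
  labels == positive
}

#' Detect suppressor pairs
#'
#' A suppressor pair carries almost no disease information on its own
#' (screening AUROC within \code{delta} of 0.5) but tracks the shared
#' nuisance component of the significant pairs: the magnitude of its
#' Pearson correlation with at least one significant pair's feature
#' reaches \code{rho_min}. Adding such pairs lets the logistic model
#' subtract the confounder — the differential-amplifier idea.
#'
#' @param pairs data.frame from [evaluatePairs()].
#' @param feature_matrix matrix of pair-feature values (rows aligned with
#'   \code{pairs}, columns samples), e.g. from [pairFeatureValues()];
#'   computed over all samples.
#' @param delta half-width of the "uninformative" AUROC band around 0.5.
#' @param rho_min minimum |Pearson r| with some significant pair.
#' @return \code{pairs} with \code{klass} upgraded to "suppressor" where
#'   the rule fires, plus a \code{max_cor_significant} column.
#' @export
findSuppressors <- function(pairs, feature_matrix, delta = 0.05,
                            rho_min = 0.6) {
  sig_idx <- which(pairs$klass == "significant")
  pairs$max_cor_significant <- NA_real_
  if (!length(sig_idx)) {
    warning("no significant pairs; suppressor detection skipped")
    return(pairs)
  }
  cand_idx <- which(abs(pairs$auroc - 0.5) <= delta)
  if (length(cand_idx)) {
    cm <- abs(cor(t(feature_matrix[cand_idx, , drop = FALSE]),
                  t(feature_matrix[sig_idx, , drop = FALSE])))
    cm[!is.finite(cm)] <- 0  # zero-variance features correlate with nothing
    mx <- apply(cm, 1, max)
    pairs$max_cor_significant[cand_idx] <- mx
    pairs$klass[cand_idx][mx >= rho_min] <- "suppressor"
  }
  pairs
}

#' Write the candidate pair table as CSV
#' @param pairs data.frame from [evaluatePairs()] / [findSuppressors()].
#' @param path output path.
#' @export
writePairTable <- function(pairs, path) {
  write.csv(pairs[, c("probe_a", "probe_b", "mode", "oriented", "auroc",
                      "klass")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
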