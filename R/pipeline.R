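#' Pipeline configuration
#'
#' Bundles every tunable of the signature-discovery pipeline so the whole
#' chain (probe filtering, replication balancing, pair screening,
#' suppressor detection, Monte-Carlo panel search) can be re-run inside
#' each training fold without touching held-out samples.
#'
#' @param maqc,edta_stable,pax_stable probe whitelists for
#'   [filterProbes()]; NULL skips the corresponding rule.
#' @param plan replication plan for [replicateWithNoise()], or NULL for
#'   no balancing.
#' @param modes pair-feature modes to screen, subset of c("ratio","sum").
#' @param sig_threshold screening AUROC for significance (default 0.7).
#' @param sum_margin complementary-noise margin for sum pairs.
#' @param suppressor_delta,rho_min suppressor-rule parameters, see
#'   [findSuppressors()].
#' @param search a [searchConfig()].
#' @return list of class "PipelineConfig".
#' @export
pipelineConfig <- function(maqc = NULL, edta_stable = NULL,
                           pax_stable = NULL, plan = NULL,
                           modes = c("ratio", "sum"),
                           sig_threshold = 0.7, sum_margin = 0.05,
                           suppressor_delta = 0.05, rho_min = 0.6,
                           search = searchConfig()) {
  structure(list(maqc = maqc, edta_stable = edta_stable,
                 pax_stable = pax_stable, plan = plan, modes = modes,
                 sig_threshold = sig_threshold, sum_margin = sum_margin,
                 suppressor_delta = suppressor_delta, rho_min = rho_min,
                 search = search),
            class = "PipelineConfig")
}

#' Train the full signature pipeline on one training set
#'
#' Runs, strictly on the given training samples: the probe filter chain;
#' replication balancing (when a plan is configured); pair screening and
#' suppressor detection on the (possibly augmented) training matrix; and
#' Monte-Carlo panel search. If fewer than \code{panel_size} candidates
#' clear the screening rules the candidate set is padded with the
#' highest-AUROC remaining pairs, so a panel can always be fitted
#' (relevant for null / permuted-label inputs).
#'
#' @param es training \linkS4class{BloodExpressionSet}.
#' @param labels logical per training sample (TRUE = case), or NULL to
#'   use \code{positive} against colData \code{group}.
#' @param config a [pipelineConfig()].
#' @param positive disease label treated as case when \code{labels} is
#'   NULL.
#' @param seed seed for balancing noise (the search uses its own seed
#'   from \code{config$search}).
#' @return list: \code{panel} (\linkS4class{Panel}), \code{filter_report},
#'   \code{pairs} (screened pair table), \code{candidates} (rows offered
#'   to the search), \code{retained} (probe ids after filtering).
#' @export
trainPipeline <- function(es, labels = NULL, config = pipelineConfig(),
                          positive = NULL, seed = 1L) {
  if (is.null(labels)) {
    if (is.null(positive)) stop("give either labels or positive")
    labels <- oneAgainstAll(sampleInfo(es), positive)
  }
  labels <- .asCaseLogical(labels, positive)
  report <- filterProbes(es, maqc = config$maqc,
                         edta_stable = config$edta_stable,
                         pax_stable = config$pax_stable)
  retained <- retainedProbes(report)
  if (length(retained) < 2)
    stop("fewer than 2 probes survive the filter chain")
  es_f <- es[retained, ]
  if (!is.null(config$plan)) {
    n0 <- ncol(es_f)
    es_f <- replicateWithNoise(es_f, config$plan, seed = seed)
    parent <- sampleInfo(es_f)$parent_sample_id
    orig_id <- sampleInfo(es_f)$sample_id[seq_len(n0)]
    labels <- labels[match(ifelse(is.na(parent),
                                  sampleInfo(es_f)$sample_id, parent),
                           orig_id)]
  }
  pairs <- evaluatePairs(es_f, labels, modes = config$modes,
                         sig_threshold = config$sig_threshold,
                         sum_margin = config$sum_margin)
  feats <- pairFeatureValues(es_f, pairs)
  pairs <- suppressWarnings(
    findSuppressors(pairs, feats, delta = config$suppressor_delta,
                    rho_min = config$rho_min))
  cand_idx <- which(pairs$klass != "neither")
  k <- config$search$panel_size
  if (length(cand_idx) < k) {
    pool <- setdiff(order(pairs$auroc, decreasing = TRUE), cand_idx)
    cand_idx <- c(cand_idx, pool[seq_len(k - length(cand_idx))])
  }
  candidates <- pairs[cand_idx, , drop = FALSE]
  panel <- mcSearch(candidates, feats[cand_idx, , drop = FALSE], labels,
                    config = config$search)
  list(panel = panel, filter_report = report, pairs = pairs,
       candidates = candidates, retained = retained)
}
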