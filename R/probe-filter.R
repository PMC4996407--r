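#' Build a replicate-stability probe list
#'
#' Given technical-replicate hybridizations of the same RNA (e.g. one
#' pooled sample run across chip lots), ranks probe sets by their observed
#' replicate variability and keeps those whose maximum relative deviation
#' from the replicate median is within \code{tolerance}. This yields the
#' tube-chemistry stability lists consumed by [filterProbes()]
#' (conventionally 0.10 for EDTA replicates and 0.15 for PAXgene).
#'
#' The stability metric for probe p with replicate signals x is
#' \code{max(|x - median(x)|) / median(x)} — robust to a single bad
#' replicate. Probes with a zero replicate median cannot be scored and are
#' excluded with reason \code{"zero median"}.
#'
#' @param replicates a \linkS4class{BloodExpressionSet} or numeric matrix
#'   restricted to technical-replicate columns (>= 2).
#' @param tolerance maximum allowed relative deviation (> 0), e.g. 0.10.
#' @param label label for the returned list, e.g. "EDTA-stable".
#' @return list with \code{probes} (character vector, stable probe ids,
#'   \code{label} attribute set) and \code{report} (data.frame: probe_id,
#'   max_relative_deviation, n_replicates, included, reason).
#' @export
buildStabilityList <- function(replicates, tolerance, label = "custom") {
  m <- if (is(replicates, "BloodExpressionSet")) signals(replicates)
       else as.matrix(replicates)
  if (ncol(m) < 2)
    stop("at least 2 replicate columns are required to assess stability")
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be a positive fraction")
  med <- apply(m, 1, median)
  dev <- apply(abs(m - med), 1, max) / med
  zero <- med == 0
  dev[zero] <- NA_real_
  included <- !zero & dev <= tolerance
  report <- data.frame(
    probe_id = rownames(m),
    max_relative_deviation = dev,
    n_replicates = ncol(m),
    included = included,
    reason = ifelse(zero, "zero median",
                    ifelse(included, "", "deviation above tolerance")),
    stringsAsFactors = FALSE, row.names = NULL
  )
  probes <- report$probe_id[report$included]
  attr(probes, "label") <- label
  list(probes = probes, report = report)
}

#' Apply the probe-set filter chain
#'
#' Reduces the probe universe to candidates reliable enough for pair
#' screening. A probe set is retained iff all of:
#' \enumerate{
#'   \item present (call "P") in every sample;
#'   \item every signal within [100, 10000] (inclusive; below 100 is
#'     treated as noise-dominated, above 10000 as saturated);
#'   \item on the MAQC cross-platform reproducibility list;
#'   \item on the EDTA replicate-stability list;
#'   \item on the PAXgene replicate-stability list;
#'   \item not an outlier: no signal more than 2-fold outside the probe's
#'     own central 95\% signal range (above 2 x its 97.5th percentile or
#'     below half its 2.5th percentile, percentiles taken across samples).
#' }
#' The chain is a pure conjunction: order-independent and idempotent.
#' Passing \code{NULL} for a list skips that membership rule (useful for
#' synthetic cohorts with no external whitelist).
#'
#' @param es a \linkS4class{BloodExpressionSet}.
#' @param maqc,edta_stable,pax_stable character vectors of probe ids, or
#'   NULL to skip the corresponding rule.
#' @return a FilterReport data.frame: probe_id, six logical rule columns
#'   (present_all, in_range, on_maqc, edta_stable, pax_stable, outlier)
#'   and \code{retained}.
#' @export
filterProbes <- function(es, maqc = NULL, edta_stable = NULL,
                         pax_stable = NULL) {
  if (!nrow(es)) stop("expression matrix is empty")
  for (nm in c("maqc", "edta_stable", "pax_stable")) {
    l <- get(nm)
    if (!is.null(l) && !length(l))
      stop(sprintf("probe list '%s' is empty; pass NULL to skip the rule",
                   nm))
  }
  sig <- signals(es)
  cl <- detectionCalls(es)
  present_all <- apply(cl == "P", 1, all)
  in_range <- apply(sig >= 100 & sig <= 10000, 1, all)
  on_maqc <- if (is.null(maqc)) rep(TRUE, nrow(sig))
             else rownames(sig) %in% maqc
  on_edta <- if (is.null(edta_stable)) rep(TRUE, nrow(sig))
             else rownames(sig) %in% edta_stable
  on_pax <- if (is.null(pax_stable)) rep(TRUE, nrow(sig))
            else rownames(sig) %in% pax_stable
  qs <- t(apply(sig, 1, quantile, probs = c(0.025, 0.975), names = FALSE))
  outlier <- apply(sig > 2 * qs[, 2] | sig < qs[, 1] / 2, 1, any)
  report <- data.frame(
    probe_id = rownames(sig),
    present_all = present_all,
    in_range = in_range,
    on_maqc = on_maqc,
    edta_stable = on_edta,
    pax_stable = on_pax,
    outlier = outlier,
    stringsAsFactors = FALSE, row.names = NULL
  )
  report$retained <- present_all & in_range & on_maqc & on_edta &
    on_pax & !outlier
  if (!any(report$retained))
    message("filter chain retained no probes")
  report
}

#' Retained probe ids from a FilterReport
#' @param report a data.frame from [filterProbes()].
#' @return character vector of retained probe ids.
#' @export
retainedProbes <- function(report) report$probe_id[report$retained]

#' Write a FilterReport as CSV
#' @param report data.frame from [filterProbes()].
#' @param path output path.
#' @export
writeFilterReport <- function(report, path) {
  write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
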