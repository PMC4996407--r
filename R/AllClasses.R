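#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats median quantile rnorm runif cor glm binomial coef
#'   setNames
#' @importFrom utils read.delim write.table read.csv write.csv combn
NULL

VALID_CALLS <- c("P", "M", "A")
VALID_TUBES <- c("EDTA", "PAXgene")

#' Container for blood expression profiles
#'
#' A \linkS4class{SummarizedExperiment} holding MAS5-style probe-set
#' summaries of whole-blood microarrays: a \code{signal} assay of
#' nonnegative expression values and a parallel \code{calls} assay of
#' Present/Marginal/Absent detection calls. Per-sample annotations
#' (disease group, collection tube, source study, RNA quality metrics,
#' replication weight) live in \code{colData}.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}.
#' @seealso [BloodExpressionSet()] for construction,
#'   [readExpressionSet()] to load from tab-delimited files.
#' @export
setClass("BloodExpressionSet", contains = "SummarizedExperiment")

setValidity("BloodExpressionSet", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("signal", "calls") %in% an))
    msg <- c(msg, "assays must include 'signal' and 'calls'")
  else {
    sig <- SummarizedExperiment::assay(object, "signal")
    cl <- SummarizedExperiment::assay(object, "calls")
    if (!is.numeric(sig) || any(!is.finite(sig)) || any(sig < 0))
      msg <- c(msg, "signal assay must be finite and nonnegative")
    if (!all(cl %in% VALID_CALLS))
      msg <- c(msg, "calls assay may only contain P, M or A")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be unique")
  cd <- SummarizedExperiment::colData(object)
  if ("tube" %in% colnames(cd) && !all(cd$tube %in% VALID_TUBES))
    msg <- c(msg, "tube must be one of 'EDTA', 'PAXgene'")
  if ("weight" %in% colnames(cd) && any(cd$weight < 1))
    msg <- c(msg, "replication weight must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a BloodExpressionSet
#'
#' @param signals numeric matrix of MAS5-style signal values, probes in
#'   rows, samples in columns; rownames are probe ids, colnames sample ids.
#' @param calls character matrix over \code{{"P","M","A"}} with the same
#'   dimensions as \code{signals}. Defaults to "P" everywhere.
#' @param sampleInfo optional data.frame of per-sample annotations (one row
#'   per column of \code{signals}): \code{group}, \code{tube},
#'   \code{source}, \code{rin}, \code{rrna_ratio}, \code{weight}. Missing
#'   columns are filled with defaults.
#' @return A \linkS4class{BloodExpressionSet}.
#' @examples
#' sig <- matrix(c(200, 400, 300, 150), 2,
#'               dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' es <- BloodExpressionSet(sig)
#' signals(es)
#' @export
BloodExpressionSet <- function(signals, calls = NULL, sampleInfo = NULL) {
  signals <- as.matrix(signals)
  if (is.null(rownames(signals)))
    rownames(signals) <- paste0("probe", seq_len(nrow(signals)))
  if (is.null(colnames(signals)))
    colnames(signals) <- paste0("sample", seq_len(ncol(signals)))
  if (is.null(calls)) {
    calls <- matrix("P", nrow(signals), ncol(signals),
                    dimnames = dimnames(signals))
  } else {
    calls <- as.matrix(calls)
    dimnames(calls) <- dimnames(signals)
  }
  if (!identical(dim(signals), dim(calls)))
    stop("signals and calls must have identical dimensions")
  if (is.null(sampleInfo)) {
    sampleInfo <- data.frame(row.names = colnames(signals))
  }
  sampleInfo <- .completeSampleInfo(sampleInfo, colnames(signals))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = signals, calls = calls),
    colData = S4Vectors::DataFrame(sampleInfo)
  )
  new("BloodExpressionSet", se)
}

.completeSampleInfo <- function(df, ids) {
  df <- as.data.frame(df)
  if (nrow(df) == 0L && length(ids)) df <- data.frame(row.names = ids)
  if (nrow(df) != length(ids))
    stop("sampleInfo must have one row per sample")
  if (!is.null(df$sample_id)) rownames(df) <- df$sample_id
  else rownames(df) <- ids
  defaults <- list(group = "Control", tube = "EDTA", source = "unknown",
                   rin = NA_real_, rrna_ratio = NA_real_, weight = 1L)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  df$sample_id <- rownames(df)
  df[c("sample_id", "group", "tube", "source", "rin", "rrna_ratio",
       "weight", setdiff(colnames(df), c("sample_id", "group", "tube",
                                         "source", "rin", "rrna_ratio",
                                         "weight")))]
}

#' @describeIn BloodExpressionSet-accessors signal matrix (probes x samples)
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))

#' @describeIn BloodExpressionSet-accessors detection-call matrix
#' @export
setGeneric("detectionCalls", function(x) standardGeneric("detectionCalls"))

#' @describeIn BloodExpressionSet-accessors sample annotations as data.frame
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' Accessors for BloodExpressionSet
#'
#' @param x a \linkS4class{BloodExpressionSet}.
#' @name BloodExpressionSet-accessors
#' @aliases signals detectionCalls sampleInfo
NULL

#' @rdname BloodExpressionSet-accessors
#' @export
setMethod("signals", "BloodExpressionSet", function(x)
  SummarizedExperiment::assay(x, "signal"))

#' @rdname BloodExpressionSet-accessors
#' @export
setMethod("detectionCalls", "BloodExpressionSet", function(x)
  SummarizedExperiment::assay(x, "calls"))

#' @rdname BloodExpressionSet-accessors
#' @export
setMethod("sampleInfo", "BloodExpressionSet", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

setMethod("show", "BloodExpressionSet", function(object) {
  cat("BloodExpressionSet:", nrow(object), "probe sets x",
      ncol(object), "samples\n")
  cd <- sampleInfo(object)
  if (nrow(cd)) {
    cat("  groups:", paste(names(table(cd$group)),
                           table(cd$group), collapse = ", "), "\n")
    cat("  tubes: ", paste(names(table(cd$tube)),
                           table(cd$tube), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' A fitted gene-pair panel
#'
#' The product of [fitPanel()] / [mcSearch()]: a set of pair features
#' (significant and possibly suppressor pairs) with logistic-regression
#' coefficients and intercept. A sample's risk score is
#' \code{intercept + sum(coefficients * features)}; the decision rule
#' calls a sample positive when its score exceeds 0 (the logit-scale
#' midpoint, probability one half).
#'
#' @slot pairs data.frame of member pairs (probe_a, probe_b, mode,
#'   oriented, auroc, klass).
#' @slot coefficients numeric, one per pair, aligned to \code{pairs} rows.
#' @slot intercept numeric scalar.
#' @slot trainingAuroc numeric, in-sample AUROC of the fitted scores.
#' @slot ridged logical, TRUE when a ridge-stabilized fit was needed
#'   (perfect separation).
#' @slot metadata list: seed, search configuration, provenance.
#' @export
setClass("Panel", representation(
  pairs = "data.frame",
  coefficients = "numeric",
  intercept = "numeric",
  trainingAuroc = "numeric",
  ridged = "logical",
  metadata = "list"
))

setValidity("Panel", function(object) {
  if (length(object@coefficients) != nrow(object@pairs))
    return("coefficients must align with pairs (one per pair)")
  if (any(object@pairs$probe_a == object@pairs$probe_b))
    return("a pair may not use the same probe twice")
  TRUE
})

setMethod("show", "Panel", function(object) {
  cat("Gene-pair panel:", nrow(object@pairs), "pairs",
      sprintf("(%d suppressor)", sum(object@pairs$klass == "suppressor")),
      "\n")
  cat("  training AUROC:", round(object@trainingAuroc, 4),
      if (object@ridged) " [ridge-stabilized fit]" else "", "\n")
  cat("  decision threshold: score > 0\n")
  pj <- paste0(object@pairs$probe_a, ifelse(object@pairs$mode == "ratio",
                                            "/", "+"), object@pairs$probe_b)
  cat("  pairs:", paste(pj, collapse = ", "), "\n")
  invisible(NULL)
})

#' @describeIn Panel member pair table
#' @param object,x a \code{Panel}.
#' @export
panelPairs <- function(x) x@pairs

#' @describeIn Panel logistic coefficients (named by pair label)
#' @export
panelCoefficients <- function(x)
  setNames(x@coefficients, pairLabels(x@pairs))

#' @describeIn Panel logistic intercept
#' @export
panelIntercept <- function(x) x@intercept

#' Human-readable labels for a pair table
#' @param pairs data.frame with probe_a, probe_b, mode columns.
#' @return character vector like \code{"p1/p2"} or \code{"p1+p2"}.
#' @export
pairLabels <- function(pairs) {
  if (!nrow(pairs)) return(character())
  paste0(pairs$probe_a, ifelse(pairs$mode == "ratio", "/", "+"),
         pairs$probe_b)
}
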