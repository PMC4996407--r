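#' Read signal and call matrices into a BloodExpressionSet
#'
#' Reads a pair of tab-delimited text files (probe rows, sample columns,
#' header row of sample ids, first column probe ids): the MAS5-style signal
#' matrix and the matching Present/Marginal/Absent call matrix. The two
#' files must agree exactly in probe and sample ordering.
#'
#' @param signal_path path to the tab-delimited signal matrix.
#' @param call_path path to the tab-delimited call matrix.
#' @param annotation_path optional path to a sample-annotation CSV (see
#'   [readSampleAnnotations()]); rows are matched to samples by
#'   \code{sample_id}.
#' @return A \linkS4class{BloodExpressionSet}.
#' @export
readExpressionSet <- function(signal_path, call_path,
                              annotation_path = NULL) {
  sig <- .readMatrixFile(signal_path, "signal")
  cl <- .readMatrixFile(call_path, "call")
  if (!identical(dim(sig), dim(cl))) {
    stop(sprintf(
      "dimension mismatch between signal (%d x %d) and call (%d x %d) files",
      nrow(sig), ncol(sig), nrow(cl), ncol(cl)))
  }
  if (!identical(rownames(sig), rownames(cl))) {
    bad <- which(rownames(sig) != rownames(cl))[1]
    stop(sprintf("probe id mismatch at row %d: '%s' (signal) vs '%s' (call)",
                 bad, rownames(sig)[bad], rownames(cl)[bad]))
  }
  if (!identical(colnames(sig), colnames(cl)))
    stop("sample id mismatch between signal and call files")
  bad <- which(matrix(!(cl %in% VALID_CALLS), nrow(cl)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "invalid detection call '%s' at probe row '%s' (sample '%s'); calls must be P, M or A",
      cl[bad[1, 1], bad[1, 2]], rownames(cl)[bad[1, 1]],
      colnames(cl)[bad[1, 2]]))
  }
  mode(sig) <- "numeric"
  if (any(is.na(sig)))
    stop("non-numeric or missing signal values encountered")
  info <- NULL
  if (!is.null(annotation_path)) {
    ann <- readSampleAnnotations(annotation_path)
    miss <- setdiff(colnames(sig), ann$sample_id)
    if (length(miss))
      stop("annotation file lacks samples: ", paste(miss, collapse = ", "))
    info <- ann[match(colnames(sig), ann$sample_id), , drop = FALSE]
  }
  message(sprintf("loaded %d probe sets x %d samples", nrow(sig), ncol(sig)))
  BloodExpressionSet(sig, cl, sampleInfo = info)
}

.readMatrixFile <- function(path, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop(sprintf("%s file %s has no sample columns", what, path))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m)))
    stop(sprintf("duplicate probe id '%s' in %s file",
                 rownames(m)[duplicated(rownames(m))][1], what))
  m
}

#' Write a BloodExpressionSet to tab-delimited files
#'
#' Inverse of [readExpressionSet()]; round-trips dimensions, ids and
#' calls exactly and signals to text-serialization precision.
#'
#' @param es a \linkS4class{BloodExpressionSet}.
#' @param signal_path,call_path output file paths.
#' @param annotation_path optional path for the sample-annotation CSV.
#' @return invisibly, the paths written.
#' @export
writeExpressionSet <- function(es, signal_path, call_path,
                               annotation_path = NULL) {
  .writeMatrixFile(signals(es), signal_path)
  .writeMatrixFile(detectionCalls(es), call_path)
  if (!is.null(annotation_path))
    write.csv(sampleInfo(es), annotation_path, row.names = FALSE,
              quote = FALSE)
  invisible(c(signal_path, call_path))
}

.writeMatrixFile <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sample-annotation CSV
#'
#' Expected named columns: \code{sample_id}, \code{group} (disease label,
#' "Control" or "Other"), \code{tube} (EDTA or PAXgene), \code{source},
#' \code{rin} (RNA Integrity Number), \code{rrna_ratio} (28S:18S);
#' optional \code{weight} (positive integer replication count, default 1).
#'
#' @param path CSV path.
#' @return data.frame with the columns above.
#' @export
readSampleAnnotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "tube")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("annotation CSV lacks required columns: ",
         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$tube), VALID_TUBES)
  if (length(bad))
    stop("unknown tube type(s): ", paste(bad, collapse = ", "),
         " (expected EDTA or PAXgene)")
  if (is.null(df$weight)) df$weight <- 1L
  df
}

#' Read / write a probe list
#'
#' One probe id per line, as used for the MAQC whitelist and the
#' replicate-stability lists.
#'
#' @param path file path.
#' @param label optional label recorded on the returned vector
#'   (e.g. "MAQC", "EDTA-stable", "PAXgene-stable", "custom").
#' @return character vector of probe ids (attribute \code{label} set).
#' @export
readProbeList <- function(path, label = "custom") {
  ids <- readLines(path)
  ids <- ids[nzchar(trimws(ids))]
  ids <- trimws(ids)
  if (anyDuplicated(ids)) ids <- unique(ids)
  attr(ids, "label") <- label
  ids
}

#' @rdname readProbeList
#' @param ids character vector of probe ids.
#' @export
writeProbeList <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' RNA-quality gating of samples
#'
#' Partitions samples into kept and rejected by the RNA quality gate:
#' a sample is kept iff RIN >= 7.0 and 28S:18S ratio >= 1.0 (both
#' comparisons inclusive). Samples with missing quality metrics are
#' rejected with reason "missing QC" — a conservative clinical-style gate.
#'
#' @param samples data.frame of sample records with \code{rin} and
#'   \code{rrna_ratio} columns (e.g. from [sampleInfo()] or
#'   [readSampleAnnotations()]).
#' @param rin_min,rrna_min inclusive thresholds; defaults 7.0 and 1.0.
#' @return list with \code{kept} (data.frame) and \code{rejected}
#'   (data.frame with an extra \code{reason} column). The two parts
#'   partition the input exactly.
#' @examples
#' recs <- data.frame(sample_id = c("a", "b"), rin = c(7, 6.9),
#'                    rrna_ratio = c(1, 2))
#' qcFilterSamples(recs)$rejected$reason
#' @export
qcFilterSamples <- function(samples, rin_min = 7.0, rrna_min = 1.0) {
  samples <- as.data.frame(samples)
  if (is.null(samples$rin) || is.null(samples$rrna_ratio))
    stop("samples must carry 'rin' and 'rrna_ratio' columns")
  reason <- character(nrow(samples))
  missing_qc <- is.na(samples$rin) | is.na(samples$rrna_ratio)
  reason[missing_qc] <- "missing QC"
  low_rin <- !missing_qc & samples$rin < rin_min
  low_ratio <- !missing_qc & samples$rrna_ratio < rrna_min
  reason[low_rin] <- sprintf("RIN %.2f < %.1f", samples$rin[low_rin],
                             rin_min)
  reason[low_ratio & !low_rin] <-
    sprintf("28S:18S %.2f < %.1f", samples$rrna_ratio[low_ratio & !low_rin],
            rrna_min)
  reason[low_ratio & low_rin] <-
    paste0(reason[low_ratio & low_rin], "; 28S:18S below threshold")
  keep <- !nzchar(reason)
  rejected <- samples[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(kept = samples[keep, , drop = FALSE], rejected = rejected)
}
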