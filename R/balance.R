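#' Replication plan for group balancing
#'
#' One row per (group, tube) stratum: \code{r} extra replicates to make
#' of every sample in the stratum (so each sample contributes \code{r + 1}
#' effective copies) and \code{sigma}, the standard deviation of the
#' Gaussian noise added to each copy's log2 signals. Replicating
#' pathology-confirmed samples up-weights them against the much larger
#' pool of unconfirmed "Other" samples in one-against-all training.
#'
#' @param group,tube,r vectors of equal length; \code{r >= 0} integers.
#' @param sigma noise SD on the log2 scale, recycled; default 0.05
#'   (about 3.5\% CV), a deliberately small measurement-uncertainty scale.
#' @return data.frame with columns group, tube, r, sigma.
#' @export
replicationPlan <- function(group, tube, r, sigma = 0.05) {
  if (any(r < 0)) stop("replicate counts r must be >= 0")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  data.frame(group = as.character(group), tube = as.character(tube),
             r = as.integer(r), sigma = sigma, stringsAsFactors = FALSE)
}

#' Effective per-stratum counts under a replication plan
#'
#' Pure integer arithmetic: a stratum of n samples with r extra replicates
#' per sample contributes \code{n * (r + 1)} effective samples. Strata
#' absent from the plan default to r = 0.
#'
#' @param design data.frame with columns group, tube, n (sample counts).
#' @param plan data.frame from [replicationPlan()] (columns group, tube,
#'   r). If \code{design} itself carries an \code{r} column and
#'   \code{plan} is NULL, that column is used.
#' @return data.frame: group, tube, n, r, effective; attributes
#'   \code{tube_totals} (named vector of per-tube effective subtotals) and
#'   \code{total} (grand total).
#' @examples
#' d <- hccTrainingDesign()
#' ec <- effectiveCounts(d)
#' ec[ec$group == "HCC" & ec$tube == "PAXgene", "effective"]  # 416
#' attr(ec, "total")                                          # 2513
#' @export
effectiveCounts <- function(design, plan = NULL) {
  design <- as.data.frame(design)
  if (any(design$n < 0)) stop("sample counts must be >= 0")
  if (is.null(plan)) {
    if (is.null(design$r)) stop("no replication plan given")
    r <- design$r
  } else {
    key <- paste(design$group, design$tube)
    pkey <- paste(plan$group, plan$tube)
    r <- plan$r[match(key, pkey)]
    r[is.na(r)] <- 0L
  }
  out <- data.frame(group = design$group, tube = design$tube,
                    n = design$n, r = as.integer(r),
                    effective = design$n * (as.integer(r) + 1L),
                    stringsAsFactors = FALSE)
  attr(out, "tube_totals") <- tapply(out$effective, out$tube, sum)
  attr(out, "total") <- sum(out$effective)
  out
}

#' Replicate samples with controlled Gaussian noise
#'
#' Augments an expression set per a replication plan: every sample in a
#' stratum with r extra replicates contributes itself plus r noisy copies.
#' Each copy's log2 signals are the original plus i.i.d. N(0, sigma^2)
#' noise per probe — a controlled simulation of measurement uncertainty
#' that also stops any single data point from dominating the fit. With
#' sigma = 0 the operator is pure replication. Copies inherit the parent's
#' detection calls and annotations and gain a \code{parent_sample_id}
#' column; the original columns keep \code{parent_sample_id = NA}.
#'
#' @param es a \linkS4class{BloodExpressionSet} whose colData carries
#'   group and tube.
#' @param plan data.frame from [replicationPlan()]; must cover every
#'   (group, tube) stratum present in \code{es}.
#' @param seed integer; the same seed reproduces the augmentation exactly.
#' @return augmented \linkS4class{BloodExpressionSet}; column count equals
#'   \code{attr(effectiveCounts(...), "total")} for the matching design.
#' @export
replicateWithNoise <- function(es, plan, seed = 1L) {
  info <- sampleInfo(es)
  key <- paste(info$group, info$tube)
  pkey <- paste(plan$group, plan$tube)
  uncovered <- setdiff(unique(key), pkey)
  if (length(uncovered))
    stop("replication plan does not cover strata: ",
         paste(uncovered, collapse = ", "))
  r <- plan$r[match(key, pkey)]
  sigma <- plan$sigma[match(key, pkey)]
  if (is.null(sigma)) sigma <- rep(0.05, length(r))
  sig <- signals(es)
  cl <- detectionCalls(es)
  set.seed(as.integer(seed))
  orig_idx <- seq_len(ncol(sig))
  rep_parent <- rep(orig_idx, times = r)
  if (length(rep_parent)) {
    l2 <- log2(pmax(sig[, rep_parent, drop = FALSE], .Machine$double.xmin))
    noise <- matrix(rnorm(length(l2), 0,
                          rep(sigma[rep_parent], each = nrow(sig))),
                    nrow(sig), length(rep_parent))
    new_sig <- 2^(l2 + noise)
    new_cl <- cl[, rep_parent, drop = FALSE]
    copy_id <- paste0(colnames(sig)[rep_parent], ".rep",
                      unlist(lapply(r, seq_len)))
    colnames(new_sig) <- copy_id
    sig_all <- cbind(sig, new_sig)
    cl_all <- cbind(cl, new_cl)
    colnames(cl_all) <- colnames(sig_all)
    new_info <- info[rep_parent, , drop = FALSE]
    new_info$parent_sample_id <- info$sample_id[rep_parent]
    new_info$sample_id <- copy_id
    info$parent_sample_id <- NA_character_
    info_all <- rbind(info, new_info)
    rownames(info_all) <- info_all$sample_id
  } else {
    sig_all <- sig; cl_all <- cl
    info_all <- info
    info_all$parent_sample_id <- NA_character_
  }
  BloodExpressionSet(sig_all, cl_all, sampleInfo = info_all)
}

#' Training design of the collection-tube bias demonstration
#'
#' The HCC (hepatocellular carcinoma) vs chronic hepatitis B vs control
#' blood study used to demonstrate tube-bias suppression: per-stratum
#' training sample counts together with the replication plan that balances
#' PAXgene against EDTA contributions and confirmed cases against the 830
#' unconfirmed "Other" samples. Each HCC PAXgene sample gets 15 extra
#' copies (16 effective), each HCC EDTA sample 20, each Control PAXgene
#' sample 14 and each Control EDTA sample 56, giving effective strata of
#' 416 / 420 / 420 / 399 and a grand total of 2513.
#'
#' @return data.frame with columns group, tube, n, r suitable for
#'   [effectiveCounts()].
#' @export
hccTrainingDesign <- function() {
  data.frame(
    group = c("HCC", "HCC", "HpB", "Control", "Control", "Other"),
    tube = c("PAXgene", "EDTA", "PAXgene", "PAXgene", "EDTA", "EDTA"),
    n = c(26L, 20L, 28L, 28L, 7L, 830L),
    r = c(15L, 20L, 0L, 14L, 56L, 0L),
    stringsAsFactors = FALSE
  )
}

#' Cohort design of the tube-bias demonstration study
#'
#' Per-stratum sample counts of the liver-cancer study's training set
#' (82 PAXgene + 857 EDTA = 939 samples) or its independent test set
#' (79 PAXgene + 882 EDTA = 961 samples).
#'
#' @param set "training" or "test".
#' @return data.frame with columns group, tube, n.
#' @export
hccCohortDesign <- function(set = c("training", "test")) {
  set <- match.arg(set)
  if (set == "training") {
    d <- hccTrainingDesign()[, c("group", "tube", "n")]
  } else {
    d <- data.frame(
      group = c("HCC", "HCC", "HpB", "Control", "Control", "Other"),
      tube = c("PAXgene", "EDTA", "PAXgene", "PAXgene", "EDTA", "EDTA"),
      n = c(25L, 15L, 27L, 27L, 7L, 860L),
      stringsAsFactors = FALSE
    )
  }
  d
}
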