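#' Monte-Carlo search configuration
#'
#' @param panel_size number of pairs per candidate panel (default 6, the
#'   size of the liver-cancer demonstration panel).
#' @param n_iterations number of random subsets to draw and score.
#' @param max_suppressors maximum suppressor pairs allowed in a panel.
#' @param seed integer seed; fixes the whole search stream.
#' @param objective "validation" scores each panel by AUROC on an internal
#'   70/30 stratified split (resists selection overfitting);
#'   "training" uses in-sample AUROC.
#' @param val_fraction held-out fraction for the internal split.
#' @return list of class "SearchConfig".
#' @export
searchConfig <- function(panel_size = 6L, n_iterations = 200L,
                         max_suppressors = 2L, seed = 1L,
                         objective = c("validation", "training"),
                         val_fraction = 0.3) {
  stopifnot(panel_size >= 1, n_iterations >= 1, max_suppressors >= 0)
  structure(list(panel_size = as.integer(panel_size),
                 n_iterations = as.integer(n_iterations),
                 max_suppressors = as.integer(max_suppressors),
                 seed = as.integer(seed),
                 objective = match.arg(objective),
                 val_fraction = val_fraction),
            class = "SearchConfig")
}

# Ridge-penalized logistic regression by IRLS; intercept unpenalized.
# Used as the stabilized fallback when ML logistic separates perfectly.
.ridgeLogistic <- function(X, y, lambda = 1e-6, max_iter = 100L,
                           tol = 1e-10) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (i in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    H <- crossprod(X1 * w, X1) + pen
    beta_new <- solve(H, crossprod(X1 * w, z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

#' Fit a logistic panel on a pair subset
#'
#' Maximum-likelihood logistic regression of the case/control label on
#' the selected pair-feature columns. The panel scores a sample as
#' \code{intercept + coefficients . features} (the logit); the decision
#' rule is positive iff score > 0. Perfect separation (common after
#' replication balancing) is handled by refitting with a tiny ridge
#' penalty (1e-6) instead of failing; the panel is flagged \code{ridged}.
#'
#' @param features matrix of pair-feature values, rows = pairs (aligned
#'   with \code{pairs}), columns = samples, as from [pairFeatureValues()].
#' @param labels logical (or two-level) vector per sample; TRUE = case.
#' @param pairs data.frame describing the rows of \code{features}.
#' @param subset integer or logical index of pairs to use; default all.
#' @param positive passed to label coercion for non-logical labels.
#' @return a \linkS4class{Panel}.
#' @export
fitPanel <- function(features, labels, pairs, subset = NULL,
                     positive = NULL) {
  y <- as.numeric(.asCaseLogical(labels, positive))
  if (all(y == 1) || all(y == 0)) stop("both classes must be present")
  if (is.null(subset)) subset <- seq_len(nrow(pairs))
  X <- t(features[subset, , drop = FALSE])
  if (any(!is.finite(X))) stop("features must be finite")
  fit_warned <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ X, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        fit_warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- coef(fit)
  if (fit_warned || any(!is.finite(beta))) {
    beta <- .ridgeLogistic(X, y, lambda = 1e-6)
    ridged <- TRUE
  } else ridged <- FALSE
  beta[!is.finite(beta)] <- 0
  scores <- drop(cbind(1, X) %*% beta)
  new("Panel",
      pairs = pairs[subset, , drop = FALSE],
      coefficients = unname(beta[-1]),
      intercept = unname(beta[1]),
      trainingAuroc = auroc(scores[y == 1], scores[y == 0]),
      ridged = ridged,
      metadata = list())
}

#' Score samples with a fitted panel
#'
#' @param panel a \linkS4class{Panel}.
#' @param x either a \linkS4class{BloodExpressionSet} (or signal matrix)
#'   containing the panel's probes, or a precomputed feature matrix whose
#'   rows align with the panel's pairs.
#' @param features_precomputed set TRUE when \code{x} is already a
#'   pair-feature matrix.
#' @return numeric vector of risk scores, one per sample; positive call
#'   iff score > 0.
#' @export
panelScore <- function(panel, x, features_precomputed = FALSE) {
  f <- if (features_precomputed) x else pairFeatureValues(x, panel@pairs)
  drop(panel@intercept + t(f) %*% panel@coefficients)
}

#' Monte-Carlo search for the best pair combination
#'
#' Systematic evaluation of all pair combinations is combinatorially
#' infeasible at realistic candidate counts; since any combination that
#' predicts well enough is useful, random subset sampling is used
#' instead. Each iteration draws \code{panel_size} pairs from the
#' candidate set (at most \code{max_suppressors} of them suppressor
#' pairs), fits a logistic panel, and scores it by the configured
#' objective (validation-split AUROC by default). The best-scoring panel
#' wins; ties break to fewer distinct probes, then lexicographically
#' smallest probe-id set. With a fixed seed the search is fully
#' reproducible, and because iterations share one random stream the best
#' objective is non-decreasing in the iteration budget.
#'
#' @param candidates data.frame of candidate pairs (significant and
#'   suppressor rows of an [evaluatePairs()]/[findSuppressors()] table).
#' @param features feature matrix aligned with \code{candidates} rows.
#' @param labels per-sample labels; TRUE/positive = case.
#' @param config a [searchConfig()].
#' @param positive passed to label coercion.
#' @return the winning \linkS4class{Panel}; its \code{metadata} records
#'   the objective value, seed and config.
#' @export
mcSearch <- function(candidates, features, labels, config = searchConfig(),
                     positive = NULL) {
  y <- .asCaseLogical(labels, positive)
  k <- config$panel_size
  n_cand <- nrow(candidates)
  if (n_cand < k)
    stop(sprintf("need at least panel_size=%d candidate pairs, have %d",
                 k, n_cand))
  sup <- which(candidates$klass == "suppressor")
  nonsup <- setdiff(seq_len(n_cand), sup)
  set.seed(config$seed)
  objective <- config$objective
  val <- rep(FALSE, length(y))
  if (objective == "validation") {
    val <- .stratifiedIndex(y, config$val_fraction)
    # tiny classes can leave a split without both classes; fall back
    if (length(unique(y[val])) < 2 || length(unique(y[!val])) < 2) {
      val[] <- FALSE
      objective <- "training"
    }
  }
  train <- !val
  best <- NULL
  best_key <- NULL
  for (it in seq_len(config$n_iterations)) {
    subset <- .drawSubset(n_cand, k, sup, nonsup, config$max_suppressors)
    panel <- fitPanel(features[, train, drop = FALSE], y[train],
                      candidates, subset = subset)
    obj <- if (objective == "validation") {
      s <- panelScore(panel, features[subset, val, drop = FALSE],
                      features_precomputed = TRUE)
      auroc(s[y[val]], s[!y[val]])
    } else panel@trainingAuroc
    key <- list(
      -obj,
      length(unique(c(candidates$probe_a[subset],
                      candidates$probe_b[subset]))),
      paste(sort(unique(c(candidates$probe_a[subset],
                          candidates$probe_b[subset]))), collapse = "|")
    )
    if (is.null(best) || .keyLess(key, best_key)) {
      panel@metadata <- list(objective = objective,
                             objective_value = obj,
                             subset = subset, seed = config$seed,
                             config = unclass(config))
      best <- panel
      best_key <- key
    }
  }
  best
}

# lexicographic comparison of (negated objective, n_probes, id string)
.keyLess <- function(a, b) {
  if (a[[1]] != b[[1]]) return(a[[1]] < b[[1]])
  if (a[[2]] != b[[2]]) return(a[[2]] < b[[2]])
  a[[3]] < b[[3]]
}

.drawSubset <- function(n_cand, k, sup, nonsup, max_sup) {
  for (try in 1:100) {
    s <- sample.int(n_cand, k)
    if (sum(s %in% sup) <= max_sup) return(s)
  }
  # suppressors dominate the pool: draw the allowed quota directly
  n_sup <- min(max_sup, length(sup), k)
  n_non <- k - n_sup
  if (n_non > length(nonsup))
    stop("not enough non-suppressor candidates for the requested panel")
  c(if (n_sup) sup[sample.int(length(sup), n_sup)],
    if (n_non) nonsup[sample.int(length(nonsup), n_non)])
}

.stratifiedIndex <- function(y, fraction) {
  val <- rep(FALSE, length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_take <- max(1L, round(length(idx) * fraction))
    if (n_take >= length(idx)) n_take <- length(idx) - 1L
    if (n_take > 0) val[idx[sample.int(length(idx), n_take)]] <- TRUE
  }
  val
}

#' Monte-Carlo estimation of pi (search-speed demonstrator)
#'
#' Estimates pi by the inside-circle ratio: points are placed in the
#' square [-1, 1]^2 enclosing the unit circle and pi is approximated as
#' 4 x (points inside the circle) / (points placed). \code{mode="grid"}
#' marches a regular m x m lattice of cell centers (m = round(sqrt(n)));
#' \code{mode="random"} draws points uniformly. The random estimator
#' reaches a given accuracy with far fewer points than the systematic
#' march — the same economics that motivate Monte-Carlo panel search.
#'
#' @param n_points number of points (>= 1; grid mode uses the nearest
#'   perfect square).
#' @param seed integer seed (random mode).
#' @param mode "random" or "grid".
#' @return the pi estimate.
#' @examples
#' estimatePi(4, mode = "grid")    # 2x2 lattice at (+-0.5, +-0.5): 4
#' estimatePi(1e5, seed = 1)       # within a few tenths of a percent
#' @export
estimatePi <- function(n_points, seed = 1L, mode = c("random", "grid")) {
  mode <- match.arg(mode)
  if (n_points < 1) stop("n_points must be >= 1")
  if (mode == "random") {
    set.seed(as.integer(seed))
    x <- runif(n_points, -1, 1)
    y <- runif(n_points, -1, 1)
    return(4 * sum(x * x + y * y <= 1) / n_points)
  }
  m <- max(1L, round(sqrt(n_points)))
  g <- -1 + (seq_len(m) - 0.5) * (2 / m)
  inside <- sum(outer(g^2, g^2, `+`) <= 1)
  4 * inside / (m * m)
}

#' Serialize / load a panel as a self-contained text artifact
#'
#' The file carries everything needed to score a new sample without the
#' training data: the member pairs with modes and orientations, the
#' logistic coefficients and intercept, the fixed decision threshold 0,
#' and provenance (seed, search configuration).
#'
#' @param panel a \linkS4class{Panel}.
#' @param path output (input) file path.
#' @export
writePanel <- function(panel, path) {
  meta <- panel@metadata
  lines <- c(
    "# bloodPairs panel v1",
    paste0("intercept\t", format(panel@intercept, digits = 17)),
    paste0("training_auroc\t", format(panel@trainingAuroc, digits = 17)),
    paste0("ridged\t", panel@ridged),
    "threshold\t0",
    paste0("seed\t", if (is.null(meta$seed)) NA else meta$seed),
    paste0("config\t", if (is.null(meta$config)) "" else
      paste(names(meta$config), unlist(lapply(meta$config, paste,
                                              collapse = ",")),
            sep = "=", collapse = ";")),
    "probe_a\tprobe_b\tmode\toriented\tcoefficient"
  )
  p <- panel@pairs
  lines <- c(lines, paste(p$probe_a, p$probe_b, p$mode, p$oriented,
                          format(panel@coefficients, digits = 17),
                          sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writePanel
#' @return \code{readPanel} returns the reconstructed
#'   \linkS4class{Panel}.
#' @export
readPanel <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  kv <- strsplit(lines, "\t")
  hdr_end <- which(vapply(kv, `[`, "", 1) == "probe_a")
  meta <- kv[seq_len(hdr_end - 1)]
  names(meta) <- vapply(meta, `[`, "", 1)
  tab <- do.call(rbind, kv[(hdr_end + 1):length(kv)])
  pairs <- data.frame(probe_a = tab[, 1], probe_b = tab[, 2],
                      mode = tab[, 3],
                      oriented = as.logical(tab[, 4]),
                      auroc = NA_real_, klass = NA_character_,
                      stringsAsFactors = FALSE)
  new("Panel", pairs = pairs,
      coefficients = as.numeric(tab[, 5]),
      intercept = as.numeric(meta$intercept[2]),
      trainingAuroc = as.numeric(meta$training_auroc[2]),
      ridged = as.logical(meta$ridged[2]),
      metadata = list(seed = meta$seed[2]))
}
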