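# Shared fixtures and independent oracles.

# Exhaustive Mann-Whitney AUROC: count all case-control comparisons.
# Deliberately naive; the reference the package implementation is held to.
bruteAuroc <- function(cases, controls) {
  wins <- 0
  for (x in cases) for (y in controls) {
    if (x > y) wins <- wins + 1
    else if (x == y) wins <- wins + 0.5
  }
  wins / (length(cases) * length(controls))
}

# Small well-formed expression set with annotations.
tinyExpressionSet <- function(n_probes = 3, n_samples = 2,
                              signal = NULL, calls = NULL,
                              groups = NULL, tubes = NULL) {
  if (is.null(signal))
    signal <- matrix(seq(100, by = 50,
                         length.out = n_probes * n_samples),
                     n_probes, n_samples,
                     dimnames = list(paste0("p", seq_len(n_probes)),
                                     paste0("s", seq_len(n_samples))))
  info <- data.frame(
    sample_id = colnames(signal),
    group = if (is.null(groups)) rep("Control", ncol(signal)) else groups,
    tube = if (is.null(tubes)) rep("EDTA", ncol(signal)) else tubes,
    rin = 9, rrna_ratio = 2, stringsAsFactors = FALSE)
  BloodExpressionSet(signal, calls, sampleInfo = info)
}

# Cohort with a single clean multiplicative-confounder pair: probe pa
# carries the disease effect and the shared per-sample factor, probe pb
# only the factor, so only the ratio separates the classes.
confoundedPairCohort <- function(n_per_class = 40, shift = 1,
                                 confounder_sd = 2, noise_sd = 0.05,
                                 seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  is_case <- rep(c(TRUE, FALSE), each = n_per_class)
  conf <- rnorm(n, 0, confounder_sd)
  la <- 9 + shift * is_case + conf + rnorm(n, 0, noise_sd)
  lb <- 9 + conf + rnorm(n, 0, noise_sd)
  sig <- rbind(pa = 2^la, pb = 2^lb)
  colnames(sig) <- paste0("s", seq_len(n))
  list(es = BloodExpressionSet(sig), is_case = is_case)
}
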