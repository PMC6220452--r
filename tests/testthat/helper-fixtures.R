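# Shared fixtures, built once per test run. The default-sized study is
# the expensive one; tests that can use a smaller genome build their own
# config instead.

fixture_env <- new.env(parent = emptyenv())

get_study <- function() {
  if (is.null(fixture_env$study)) {
    fixture_env$study <- simulate_study(sim_config(seed = 101))
  }
  fixture_env$study
}

# A two-condition methylome pair with background DMRs only (delta 0.8),
# used by the region-recovery checks.
get_recovery_study <- function() {
  if (is.null(fixture_env$recovery)) {
    cfg <- sim_config(seed = 202,
                      epireg = list(n_negative = 0L, n_positive = 0L),
                      dmr = list(n_per_context = 8L, shared_fraction = 0))
    fixture_env$recovery <- simulate_study(cfg)
  }
  fixture_env$recovery
}

# Tiny genome for fast unit-level work.
small_config <- function(seed = 7, ...) {
  sim_config(seed = seed,
             genome = list(n_chrom = 1L, length = 60000L),
             annotation = list(n_genes = 6L, n_tes = 10L),
             dmr = list(n_per_context = 2L),
             epireg = list(n_negative = 2L, n_positive = 1L),
             expression = list(n_degs = 4L, min_base_count = 0,
                               max_base_quantile = 1),
             ...)
}

# Build a cytosine report from explicit per-site counts.
toy_report <- function(pos, meth, total, context = "CHH", strand = "+",
                       chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             meth = meth, total = total)
}

# Exhaustive two-sided rank-sum permutation p, written independently of
# the package implementation (direct statistic recomputation per
# labeling, no shared code path).
brute_force_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(pooled) + 1) / 2
  labelings <- combn(length(pooled), n1)
  stats <- apply(labelings, 2, function(idx) sum(r[idx]))
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Two-sided Fisher p by direct hypergeometric enumeration.
brute_force_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  sum(probs[probs <= probs[match(a, xs)] * (1 + 1e-7)])
}
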