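#' Simulate gene and TE expression matrices
#'
#' Counts are negative-binomial around each feature's log-normal
#' baseline mean (drawn in [gen_truth()]); planted DEGs/DETs multiply
#' the mean by `2^log2fc` in their carrying condition, and promoter
#' coupling genes carry their planted expression shift so that a gene
#' whose promoter is hypermethylated in a treatment is down-regulated
#' there (for the negative couplings). FPKM is derived from the counts,
#' feature lengths and per-sample library sizes, so the two matrices
#' stay mutually consistent.
#'
#' @param annotation List from [gen_annotation()].
#' @param truth Truth table from [gen_truth()].
#' @param config A [sim_config()].
#' @return List: `counts` and `fpkm` (gene x sample matrices),
#'   `te_counts` (TE x sample), `samples` (sample sheet: sample,
#'   condition, replicate), `gene_lengths`, `te_lengths`,
#'   `library_sizes` (total aligned fragments per sample, genes + TEs).
#' @export
gen_expression <- function(annotation, truth, config) {
  ex <- config$expression
  set.seed(stage_seed(config$seed, "expression"))

  samples <- data.frame(
    sample = paste0(rep(CONDITIONS, each = ex$n_reps), "_r",
                    rep(seq_len(ex$n_reps), times = length(CONDITIONS))),
    condition = rep(CONDITIONS, each = ex$n_reps),
    replicate = rep(seq_len(ex$n_reps), times = length(CONDITIONS)))

  gene_ids <- annotation$genes$gene_id
  mu <- matrix(truth$base_means[gene_ids], nrow = length(gene_ids),
               ncol = nrow(samples),
               dimnames = list(gene_ids, samples$sample))
  effects <- truth$planted_degs
  for (i in seq_len(nrow(effects))) {
    cols <- samples$sample[samples$condition == effects$condition[i]]
    mu[effects$gene_id[i], cols] <- mu[effects$gene_id[i], cols] *
      2^effects$log2fc[i]
  }
  counts <- matrix(rnbinom(length(mu), size = ex$nb_size, mu = mu),
                   nrow = nrow(mu), dimnames = dimnames(mu))

  te_ids <- annotation$tes$te_id
  te_mu <- matrix(truth$te_base_means[te_ids], nrow = length(te_ids),
                  ncol = nrow(samples),
                  dimnames = list(te_ids, samples$sample))
  td <- truth$planted_dets
  for (i in seq_len(nrow(td))) {
    cols <- samples$sample[samples$condition == td$condition[i]]
    te_mu[td$te_id[i], cols] <- te_mu[td$te_id[i], cols] * 2^td$log2fc[i]
  }
  te_counts <- matrix(rnbinom(length(te_mu), size = ex$nb_size, mu = te_mu),
                      nrow = nrow(te_mu), dimnames = dimnames(te_mu))

  gene_lengths <- stats::setNames(
    annotation$genes$end - annotation$genes$start + 1L, gene_ids)
  te_lengths <- stats::setNames(
    annotation$tes$end - annotation$tes$start + 1L, te_ids)
  background <- rnbinom(nrow(samples), size = ex$background_size,
                        mu = ex$background_mean)
  library_sizes <- colSums(counts) + colSums(te_counts) + background
  if (any(library_sizes == 0)) stop("zero library size")

  fpkm <- counts / (gene_lengths / 1e3) / rep(library_sizes / 1e6,
                                              each = nrow(counts))
  list(counts = counts, fpkm = fpkm, te_counts = te_counts,
       samples = samples, gene_lengths = gene_lengths,
       te_lengths = te_lengths, library_sizes = library_sizes)
}

#' Write an expression bundle as TSV files
#'
#' Emits `<prefix>_counts.tsv`, `<prefix>_fpkm.tsv`,
#' `<prefix>_te_counts.tsv` (features x samples) and
#' `<prefix>_samples.tsv` (sample sheet).
#' @param expr List from [gen_expression()].
#' @param prefix Path prefix.
#' @export
write_expression <- function(expr, prefix) {
  wr <- function(m, suffix) {
    df <- data.frame(feature = rownames(m), m, check.names = FALSE)
    write.table(df, paste0(prefix, suffix), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(expr$counts, "_counts.tsv")
  wr(round(expr$fpkm, 4), "_fpkm.tsv")
  wr(expr$te_counts, "_te_counts.tsv")
  write.table(expr$samples, paste0(prefix, "_samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
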