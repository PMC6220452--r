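#' Divergence probability for differential expression
#'
#' Nonparametric scheme in the spirit of noise-distribution differential
#' expression screens: each gene's signal is the pair (|log2 ratio|,
#' |difference|) of its two condition means (pseudocount of 1 FPKM on
#' both means); the noise cloud pools the same statistics over every
#' within-condition replicate pair of every gene; the divergence
#' probability is the fraction of noise points strictly dominated by the
#' gene's signal point in both coordinates.
#'
#' @param fpkm Gene x sample FPKM matrix.
#' @param samples Sample sheet (sample, condition).
#' @param cond_a,cond_b Condition labels (A = control, B = treatment).
#' @param pseudo Pseudocount added to means and replicate values.
#' @return data.frame: gene_id, mean_a, mean_b, log2fc (B over A),
#'   prob.
#' @export
divergence_probability <- function(fpkm, samples, cond_a, cond_b,
                                   pseudo = 1) {
  cols_a <- samples$sample[samples$condition == cond_a]
  cols_b <- samples$sample[samples$condition == cond_b]
  if (length(cols_a) < 2L || length(cols_b) < 2L)
    stop("need at least 2 replicates per condition")
  xa <- fpkm[, cols_a, drop = FALSE]
  xb <- fpkm[, cols_b, drop = FALSE]
  mean_a <- rowMeans(xa); mean_b <- rowMeans(xb)
  m_sig <- abs(log2((mean_b + pseudo) / (mean_a + pseudo)))
  d_sig <- abs(mean_b - mean_a)

  noise_md <- function(x) {
    pr <- combn(ncol(x), 2)
    m <- d <- NULL
    for (k in seq_len(ncol(pr))) {
      i <- pr[1, k]; j <- pr[2, k]
      m <- c(m, abs(log2((x[, i] + pseudo) / (x[, j] + pseudo))))
      d <- c(d, abs(x[, i] - x[, j]))
    }
    cbind(m, d)
  }
  noise <- rbind(noise_md(xa), noise_md(xb))
  nm <- sort(noise[, 1]); nd <- noise[, 2]
  # domination fraction: P(noise_m < m & noise_d < d); exact loop is
  # O(genes x noise) -- fine at pipeline scale, chunked to bound memory
  prob <- numeric(nrow(fpkm))
  chunk <- 500L
  for (s in seq(1, nrow(fpkm), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(fpkm))
    dom <- outer(noise[, 1], m_sig[idx], "<") & outer(noise[, 2], d_sig[idx], "<")
    prob[idx] <- colMeans(dom)
  }
  data.frame(gene_id = rownames(fpkm), mean_a = mean_a, mean_b = mean_b,
             log2fc = log2((mean_b + pseudo) / (mean_a + pseudo)),
             prob = prob, row.names = NULL)
}

#' Call differentially expressed genes
#'
#' A gene is a DEG for an ordered condition change when its divergence
#' probability is at least `min_prob` and the fold-change between the
#' pseudocounted condition means is at least `min_fc`.
#'
#' @param expr Expression bundle (list with `fpkm`, `samples`) or an
#'   FPKM matrix (then pass `samples`).
#' @param cond_a,cond_b Ordered condition pair (A = control).
#' @param min_fc Fold-change threshold (on the larger/smaller mean
#'   ratio).
#' @param min_prob Divergence-probability threshold.
#' @param samples Sample sheet when `expr` is a matrix.
#' @param probs Optional externally computed probabilities (data.frame
#'   gene_id, prob) overriding the built-in scheme.
#' @return data.frame of DEGs: gene_id, cond_a, cond_b, mean_a, mean_b,
#'   log2fc, prob, direction.
#' @export
call_degs <- function(expr, cond_a, cond_b, min_fc = 2, min_prob = 0.8,
                      samples = NULL, probs = NULL) {
  if (is.list(expr) && !is.null(expr$fpkm)) {
    samples <- expr$samples
    expr <- expr$fpkm
  }
  res <- divergence_probability(expr, samples, cond_a, cond_b)
  if (!is.null(probs))
    res$prob <- probs$prob[match(res$gene_id, probs$gene_id)]
  keep <- abs(res$log2fc) >= log2(min_fc) & res$prob >= min_prob &
    !is.na(res$prob)
  out <- res[keep, , drop = FALSE]
  out$cond_a <- rep(cond_a, nrow(out))
  out$cond_b <- rep(cond_b, nrow(out))
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out[, c("gene_id", "cond_a", "cond_b", "mean_a", "mean_b", "log2fc",
          "prob", "direction")]
}

#' Venn region counts of DEG sets
#' @param deg_sets Named list of DEG data.frames (or character vectors
#'   of gene ids).
#' @return data.frame of region / count.
#' @export
deg_overlap <- function(deg_sets) {
  sets <- lapply(deg_sets, function(s) if (is.data.frame(s)) s$gene_id else s)
  venn_counts(sets)
}

#' Per-gene two-factor ANOVA over the 2x2 condition design
#'
#' Fixed-effects two-way ANOVA of log2(FPKM + 1) on temperature (L/H),
#' photoperiod (S/L) and their interaction, computed from the balanced
#' closed-form sums of squares vectorised across genes (on a balanced
#' design all classical SS types coincide). Conditions are decoded from
#' their labels: first letter = temperature, second = photoperiod.
#'
#' @param fpkm Gene x sample FPKM matrix.
#' @param samples Sample sheet (sample, condition); all four conditions
#'   with equal replicate counts are required.
#' @param alpha Significance threshold for the term counts.
#' @return List: `per_gene` (gene_id, p_temperature, p_photoperiod,
#'   p_interaction), `n_significant` (named counts of genes with
#'   p < alpha per term), `alpha`.
#' @export
gene_anova <- function(fpkm, samples, alpha = 0.05) {
  cond <- samples$condition[match(colnames(fpkm), samples$sample)]
  if (!setequal(unique(cond), CONDITIONS))
    stop("need all four LS/LL/HS/HL conditions")
  reps <- table(cond)
  if (length(unique(reps)) != 1L) stop("unbalanced design")
  r <- unname(reps[1])
  if (r < 2L) stop("need replicates in every cell")

  y <- log2(fpkm + 1)
  temp <- substr(cond, 1, 1)   # L / H
  photo <- substr(cond, 2, 2)  # S / L
  cellmean <- function(sel) rowMeans(y[, sel, drop = FALSE])
  m_ls <- cellmean(cond == "LS"); m_ll <- cellmean(cond == "LL")
  m_hs <- cellmean(cond == "HS"); m_hl <- cellmean(cond == "HL")
  m_l <- (m_ls + m_ll) / 2; m_h <- (m_hs + m_hl) / 2
  m_s <- (m_ls + m_hs) / 2; m_lg <- (m_ll + m_hl) / 2
  m <- (m_l + m_h) / 2

  ss_t <- 2 * r * ((m_l - m)^2 + (m_h - m)^2)
  ss_p <- 2 * r * ((m_s - m)^2 + (m_lg - m)^2)
  ss_i <- r * ((m_ls - m_l - m_s + m)^2 + (m_ll - m_l - m_lg + m)^2 +
               (m_hs - m_h - m_s + m)^2 + (m_hl - m_h - m_lg + m)^2)
  cellm <- cbind(LS = m_ls, LL = m_ll, HS = m_hs, HL = m_hl)
  ss_e <- rowSums((y - cellm[, cond])^2)
  df_e <- 4 * (r - 1)
  f_of <- function(ss) (ss / 1) / (ss_e / df_e)
  p_of <- function(ss) pf(f_of(ss), 1, df_e, lower.tail = FALSE)
  per_gene <- data.frame(gene_id = rownames(fpkm),
                         p_temperature = p_of(ss_t),
                         p_photoperiod = p_of(ss_p),
                         p_interaction = p_of(ss_i), row.names = NULL)
  list(per_gene = per_gene,
       n_significant = c(
         temperature = sum(per_gene$p_temperature < alpha, na.rm = TRUE),
         photoperiod = sum(per_gene$p_photoperiod < alpha, na.rm = TRUE),
         interaction = sum(per_gene$p_interaction < alpha, na.rm = TRUE)),
       alpha = alpha)
}

#' TE FPKM from raw counts
#'
#' `FPKM = count / (length / 1e3) / (library_size / 1e6)`, normalising
#' each TE's transcript count to its length and the total aligned
#' fragments of the sample.
#'
#' @param te_counts TE x sample count matrix.
#' @param te_lengths Named TE lengths (bp).
#' @param library_sizes Named per-sample totals.
#' @return TE x sample FPKM matrix.
#' @export
te_expression <- function(te_counts, te_lengths, library_sizes) {
  if (any(te_lengths <= 0)) stop("TE lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  te_counts / (te_lengths[rownames(te_counts)] / 1e3) /
    rep(library_sizes[colnames(te_counts)] / 1e6, each = nrow(te_counts))
}

#' Call differentially expressed TEs
#'
#' TEs overlapping any protein-coding gene body are discarded first.
#' The remaining TEs' replicate counts in the two conditions are
#' compared with edgeR's exact negative-binomial test (library sizes
#' taken as the totals of aligned fragments, no additional scaling
#' normalisation), p-values are Benjamini-Hochberg adjusted across
#' tested TEs, and survivors with adjusted p < alpha are reported.
#'
#' @param te_counts TE x sample count matrix.
#' @param samples Sample sheet.
#' @param cond_a,cond_b Ordered condition pair.
#' @param annotation List with `genes` and `tes` (for the overlap
#'   filter).
#' @param library_sizes Named per-sample totals.
#' @param alpha Adjusted-p threshold.
#' @return data.frame of DETs: te_id, cond_a, cond_b, count_a, count_b,
#'   p, padj, direction.
#' @export
call_dets <- function(te_counts, samples, cond_a, cond_b, annotation,
                      library_sizes, alpha = 0.05) {
  tes <- annotation$tes
  keep_ids <- tes$te_id[!overlaps_any_feature(tes, annotation$genes)]
  x <- te_counts[rownames(te_counts) %in% keep_ids, , drop = FALSE]
  cols_a <- samples$sample[samples$condition == cond_a]
  cols_b <- samples$sample[samples$condition == cond_b]
  cols <- c(cols_a, cols_b)
  group <- factor(rep(c(cond_a, cond_b), c(length(cols_a), length(cols_b))),
                  levels = c(cond_a, cond_b))
  y <- edgeR::DGEList(counts = x[, cols, drop = FALSE], group = group,
                      lib.size = unname(library_sizes[cols]))
  y <- suppressMessages(edgeR::estimateDisp(y))
  et <- edgeR::exactTest(y, pair = c(cond_a, cond_b))
  p <- et$table$PValue
  padj <- p.adjust(p, "BH")
  hit <- which(padj < alpha)
  data.frame(te_id = rownames(x)[hit], cond_a = rep(cond_a, length(hit)),
             cond_b = rep(cond_b, length(hit)),
             count_a = rowSums(x[hit, cols_a, drop = FALSE]),
             count_b = rowSums(x[hit, cols_b, drop = FALSE]),
             log2fc = et$table$logFC[hit], p = p[hit], padj = padj[hit],
             direction = ifelse(et$table$logFC[hit] > 0, "up", "down"),
             row.names = NULL)
}
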