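#' Match called DMRs against planted truth
#'
#' A planted region is recovered when some called DMR of the same
#' chromosome and context overlaps it with interval Jaccard at least
#' `min_jaccard`; precision is the fraction of called DMRs matching any
#' planted region by the same rule.
#'
#' @param called DMR data.frame from [call_dmrs()].
#' @param planted Planted-DMR truth (chrom, start, end, context).
#' @param min_jaccard Overlap threshold.
#' @return List: `recall`, `precision`, `n_called`, `n_planted`,
#'   `planted_matched` (logical per planted row).
#' @export
evaluate_dmr_recovery <- function(called, planted, min_jaccard = 0.5) {
  planted <- unique(planted[, c("chrom", "start", "end", "context")])
  jac <- function(s1, e1, s2, e2) {
    i <- pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
    i / ((e1 - s1 + 1) + (e2 - s2 + 1) - i)
  }
  match_one <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      same <- b$chrom == a$chrom[i] & b$context == a$context[i]
      any(jac(a$start[i], a$end[i], b$start[same], b$end[same]) >= min_jaccard)
    }, logical(1))
  }
  planted_matched <- if (nrow(planted)) match_one(planted, called) else logical(0)
  called_matched <- if (nrow(called)) match_one(called, planted) else logical(0)
  list(recall = mean(planted_matched), precision = mean(called_matched),
       n_called = nrow(called), n_planted = nrow(planted),
       planted_matched = planted_matched)
}

#' Evaluate the epiregulation screen against planted couplings
#'
#' @param screen Output of [epireg_screen()].
#' @param planted_epiregs Truth table component (gene_id, sign).
#' @return List: `recall` (planted negative couplings recovered in the
#'   putative gene list), `n_concordant_emitted` (planted positive-
#'   coupling genes wrongly present in the putative list).
#' @export
evaluate_epireg_recovery <- function(screen, planted_epiregs) {
  neg <- planted_epiregs$gene_id[planted_epiregs$sign == "negative"]
  pos <- planted_epiregs$gene_id[planted_epiregs$sign == "positive"]
  list(recall = mean(neg %in% screen$putative_genes),
       n_concordant_emitted = sum(pos %in% screen$putative_genes))
}

#' Evaluate DEG calls against planted truth
#'
#' @param degs DEG data.frame from [call_degs()].
#' @param planted_degs Truth table component (gene_id, direction,
#'   optionally kind).
#' @param n_genes Total genes tested (for the false-positive rate).
#' @return List: `recall`, `n_false`, `fpr`.
#' @export
evaluate_deg_recovery <- function(degs, planted_degs, n_genes) {
  hit <- planted_degs$gene_id %in% degs$gene_id &
    planted_degs$direction ==
      degs$direction[match(planted_degs$gene_id, degs$gene_id)]
  n_false <- sum(!degs$gene_id %in% planted_degs$gene_id)
  list(recall = mean(hit), n_false = n_false,
       fpr = n_false / (n_genes - nrow(planted_degs)))
}
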