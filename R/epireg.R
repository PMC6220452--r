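#' Screen for putative epiregulation of gene expression
#'
#' Joins CG/CHG DMRs to DEGs of the same ordered condition change. A
#' DMR associates with a gene when its midpoint lies inside one of the
#' gene's CDS intervals or within 2 kb of the TSS or TES (mRNA
#' boundaries; distance inclusive). The association sign is positive
#' when the methylation and expression directions agree (hyper with up,
#' hypo with down) and negative otherwise; positive associations are
#' discarded, and the genes remaining in negative associations form the
#' putative epiregulated list (deduplicated). CHH DMRs are filtered
#' out, not an error.
#'
#' @param dmrs DMR data.frame from [call_dmrs()].
#' @param degs DEG data.frame from [call_degs()].
#' @param annotation List with `genes` and `cds`.
#' @param max_dist Maximum midpoint distance from TSS/TES (bp).
#' @return List: `events` (one row per association: dmr_id, gene_id,
#'   region, context, meth_direction, expr_direction, sign),
#'   `putative_genes` (character), `summary` (n_events, n_positive,
#'   frac_positive, n_negative, n_putative).
#' @export
epireg_screen <- function(dmrs, degs, annotation, max_dist = 2000L) {
  d <- dmrs[dmrs$context %in% c("CG", "CHG"), , drop = FALSE]
  genes <- annotation$genes
  events <- list()
  if (nrow(d) && nrow(degs)) {
    mid <- interval_midpoint(d)
    for (i in seq_len(nrow(d))) {
      g <- genes[genes$chrom == d$chrom[i], , drop = FALSE]
      g <- g[g$gene_id %in% degs$gene_id, , drop = FALSE]
      for (j in seq_len(nrow(g))) {
        region <- dmr_gene_region(mid[i], g[j, ], annotation$cds, max_dist)
        if (is.na(region)) next
        deg <- degs[degs$gene_id == g$gene_id[j], ][1, ]
        sign <- if ((d$direction[i] == "hyper") == (deg$direction == "up"))
          "positive" else "negative"
        events[[length(events) + 1L]] <- data.frame(
          dmr_id = d$dmr_id[i], gene_id = g$gene_id[j], region = region,
          context = d$context[i], meth_direction = d$direction[i],
          expr_direction = deg$direction, sign = sign)
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(dmr_id = character(), gene_id = character(),
               region = character(), context = character(),
               meth_direction = character(), expr_direction = character(),
               sign = character())
  neg <- events[events$sign == "negative", , drop = FALSE]
  putative <- unique(neg$gene_id)
  list(events = events, putative_genes = putative,
       summary = c(n_events = nrow(events),
                   n_positive = sum(events$sign == "positive"),
                   frac_positive = if (nrow(events))
                     sum(events$sign == "positive") / nrow(events) else NA,
                   n_negative = nrow(neg), n_putative = length(putative)))
}

# Which eligible region of a gene a DMR midpoint falls in: a CDS
# interval, within max_dist of the TSS, or within max_dist of the TES.
dmr_gene_region <- function(mid, gene, cds, max_dist) {
  cd <- cds[cds$gene_id == gene$gene_id, , drop = FALSE]
  if (any(mid >= cd$start & mid <= cd$end)) return("CDS")
  tss <- if (gene$strand == "+") gene$start else gene$end
  tes <- if (gene$strand == "+") gene$end else gene$start
  if (abs(mid - tss) <= max_dist) return("within-2kb-of-TSS")
  if (abs(mid - tes) <= max_dist) return("within-2kb-of-TES")
  NA_character_
}
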