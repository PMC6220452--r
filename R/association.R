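#' Genic regions: gene body plus 2-kb flanks
#'
#' @param genes Gene data.frame (chrom, start, end).
#' @param flank Flank size in bp.
#' @param lengths Optional named chromosome lengths for clipping.
#' @return The genes with `region_start`, `region_end` columns.
#' @export
genic_region <- function(genes, flank = 2000L, lengths = NULL) {
  genes$region_start <- pmax(1L, genes$start - flank)
  genes$region_end <- genes$end + flank
  if (!is.null(lengths))
    genes$region_end <- pmin(genes$region_end, lengths[genes$chrom])
  genes
}

#' Assign point features to genes and TEs
#'
#' A point (a DmC site, or a DMR/DET midpoint) may sit in more than one
#' genomic feature: TE membership is overlap with a TE body; genic
#' membership is overlap with any genic region (body + 2-kb flanks).
#' Genic points are assigned to the single nearest gene by distance to
#' the gene body (0 inside; ties broken deterministically toward the
#' lexicographically smaller gene id). Categories follow the four-way
#' split: `gene-only`, `TE-only`, `TE&gene`, `none`.
#'
#' @param points data.frame with `chrom`, `pos` (1-based).
#' @param annotation List with `genes` and `tes`.
#' @param lengths Optional chromosome lengths (clips genic regions).
#' @param flank Genic flank in bp.
#' @param nearest_by `"body"` (default) or `"tss"`: distance used to
#'   pick the nearest gene.
#' @return `points` with added columns `category`, `gene_id` (`NA` when
#'   not genic), `te_ids` (comma-joined overlapping TEs, `""` if none).
#' @export
assign_point <- function(points, annotation, lengths = NULL, flank = 2000L,
                         nearest_by = c("body", "tss")) {
  nearest_by <- match.arg(nearest_by)
  genes <- genic_region(annotation$genes, flank, lengths)
  tes <- annotation$tes
  known <- unique(c(genes$chrom, tes$chrom))
  if (!is.null(lengths)) known <- unique(c(known, names(lengths)))
  bad <- setdiff(unique(points$chrom), known)
  if (length(bad)) stop("unknown chromosome: ", paste(bad, collapse = ","))

  n <- nrow(points)
  gene_id <- rep(NA_character_, n)
  te_ids <- character(n)
  pts <- as_granges(points, start = points$pos, end = points$pos)

  if (nrow(tes)) {
    hits <- IRanges::findOverlaps(pts, as_granges(tes))
    if (length(hits)) {
      by_pt <- split(tes$te_id[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))
      te_ids[as.integer(names(by_pt))] <-
        vapply(by_pt, function(x) paste(sort(x), collapse = ","), character(1))
    }
  }
  if (nrow(genes)) {
    genic <- IRanges::overlapsAny(
      pts, as_granges(genes, start = genes$region_start,
                      end = genes$region_end))
    for (ch in unique(points$chrom[genic])) {
      pi <- which(points$chrom == ch & genic)
      p <- points$pos[pi]
      g <- genes[genes$chrom == ch, , drop = FALSE]
      g <- g[order(g$gene_id), , drop = FALSE]
      dist <- if (nearest_by == "tss") {
        tss <- ifelse(g$strand == "+", g$start, g$end)
        abs(outer(tss, p, "-"))
      } else {
        pmax(outer(g$start, p, "-"), -outer(g$end, p, "-"), 0)
      }
      # ties go to the smaller gene id: rows are id-sorted and
      # which.min takes the first minimum
      gene_id[pi] <- g$gene_id[apply(dist, 2, which.min)]
    }
  }
  has_te <- te_ids != ""
  has_gene <- !is.na(gene_id)
  points$category <- ifelse(has_te & has_gene, "TE&gene",
                       ifelse(has_gene, "gene-only",
                         ifelse(has_te, "TE-only", "none")))
  points$gene_id <- gene_id
  points$te_ids <- te_ids
  points
}

# Venn region counts for 2 or 3 named key sets.
venn_counts <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 sets")
  nm <- names(sets) %||% LETTERS[seq_along(sets)]
  keys <- unique(unlist(sets))
  member <- vapply(sets, function(s) keys %in% s, logical(length(keys)))
  if (length(keys) == 1L) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(m) paste(nm[m], collapse = "&"))
  tab <- table(factor(pattern))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("region", "count")
  out
}

#' Intersect DmC sets across condition comparisons
#'
#' Keys are (chrom, pos, strand, context). Reports the all-way shared
#' sites with the methylation-level delta of every comparison, the
#' fraction whose deltas agree in sign across all comparisons
#' (concordance), per-context shared counts, and the Venn region counts
#' of the comparisons.
#'
#' @param dmc_sets Named list (>= 2) of DmC data.frames from
#'   [call_dmcs()].
#' @return List: `shared` (one row per all-way shared site, one delta
#'   column per comparison), `concordance`, `context_counts`, `venn`.
#' @export
shared_dmcs <- function(dmc_sets) {
  if (length(dmc_sets) < 2L) stop("need at least 2 DmC sets")
  nm <- names(dmc_sets) %||% paste0("set", seq_along(dmc_sets))
  key <- function(d) paste(d$chrom, d$pos, d$strand, d$context, sep = ":")
  keys <- lapply(dmc_sets, key)
  common <- Reduce(intersect, keys)
  first <- dmc_sets[[1]][match(common, keys[[1]]),
                         c("chrom", "pos", "strand", "context")]
  deltas <- vapply(seq_along(dmc_sets), function(i)
    dmc_sets[[i]]$delta[match(common, keys[[i]])], numeric(length(common)))
  if (length(common) == 1L) deltas <- matrix(deltas, nrow = 1)
  colnames(deltas) <- paste0("delta_", nm)
  shared <- cbind(first, as.data.frame(deltas))
  rownames(shared) <- NULL
  concord <- if (length(common)) {
    signs <- sign(deltas)
    mean(apply(signs, 1, function(s) all(s == s[1])))
  } else NA_real_
  ctx <- table(factor(shared$context, levels = CONTEXTS))
  list(shared = shared, concordance = concord,
       context_counts = stats::setNames(as.integer(ctx), CONTEXTS),
       venn = venn_counts(stats::setNames(keys, nm)))
}

#' Count features in fixed genomic windows
#'
#' Half-open windows `[k*w, (k+1)*w)` in 0-based coordinates (a 1-based
#' position p falls in window `floor((p - 1) / w)`); the last window of
#' each chromosome is truncated. Windows with zero features are
#' reported when chromosome lengths are given.
#'
#' @param features data.frame with `chrom`, `pos` (1-based; use DMR/DET
#'   midpoints).
#' @param window_size Window width in bp (2 Mb default).
#' @param lengths Optional named chromosome lengths.
#' @return data.frame: chrom, window (0-based index), window_start
#'   (1-based), count.
#' @export
window_counts <- function(features, window_size = 2e6, lengths = NULL) {
  idx <- floor((features$pos - 1) / window_size)
  out <- as.data.frame(table(chrom = features$chrom, window = idx),
                       stringsAsFactors = FALSE)
  out$window <- as.integer(out$window)
  names(out)[3] <- "count"
  if (!is.null(lengths)) {
    full <- do.call(rbind, lapply(names(lengths), function(ch) {
      data.frame(chrom = ch,
                 window = 0:max(0L, floor((lengths[[ch]] - 1) / window_size)))
    }))
    out <- merge(full, out, all.x = TRUE)
    out$count[is.na(out$count)] <- 0L
  } else {
    out <- out[out$count > 0L, ]
  }
  out$window_start <- out$window * window_size + 1
  out <- out[order(out$chrom, out$window), c("chrom", "window",
                                             "window_start", "count")]
  rownames(out) <- NULL
  out
}

#' TE-class breakdown of associated TEs
#'
#' Each TE is counted once no matter how many query sites hit it.
#' @param assignments Output of [assign_point()] (uses `te_ids`).
#' @param tes TE data.frame (te_id, te_class).
#' @return Named integer vector of TE counts per class (hit classes only).
#' @export
te_breakdown <- function(assignments, tes) {
  hit <- unique(unlist(strsplit(assignments$te_ids[assignments$te_ids != ""],
                                ",")))
  if (!length(hit)) return(stats::setNames(integer(0), character(0)))
  cls <- tes$te_class[match(hit, tes$te_id)]
  tab <- table(cls)
  stats::setNames(as.integer(tab), names(tab))
}

#' Midpoints of interval features
#' @param x data.frame with start, end.
#' @return Integer vector of midpoints, `floor((start + end) / 2)`.
#' @export
interval_midpoint <- function(x) {
  as.integer(floor((x$start + x$end) / 2))
}
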