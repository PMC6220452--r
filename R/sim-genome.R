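#' Generate a random genome
#'
#' Draws i.i.d. bases at the configured GC fraction (C and G equally
#' likely, likewise A and T). Chromosomes are named `chr1..chrN`.
#'
#' @param config A [sim_config()].
#' @return A [Biostrings::DNAStringSet] of `config$genome$n_chrom`
#'   chromosomes.
#' @examples
#' genome <- gen_genome(sim_config(seed = 1, genome = list(n_chrom = 1)))
#' @export
gen_genome <- function(config) {
  g <- config$genome
  if (any(g$length <= 0)) stop("non-positive chromosome length")
  lens <- rep_len(g$length, g$n_chrom)
  set.seed(stage_seed(config$seed, "genome"))
  probs <- c(A = (1 - g$gc) / 2, C = g$gc / 2, G = g$gc / 2, T = (1 - g$gc) / 2)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(probs), L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_along(seqs))
  Biostrings::DNAStringSet(seqs)
}

chrom_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Generate gene and TE annotations
#'
#' Places non-overlapping gene models (body = mRNA boundary, 2-4 CDS
#' exons, random strand) in evenly spaced slots along each chromosome,
#' then places transposable elements so that a configurable fraction of
#' them overlap genic regions (gene body plus 2-kb flanks). TE classes
#' are drawn from the configured class mix.
#'
#' @param genome A `DNAStringSet` from [gen_genome()].
#' @param config A [sim_config()].
#' @return A list with elements `genes` (data.frame: gene_id, chrom,
#'   start, end, strand; 1-based inclusive), `cds` (gene_id, start, end),
#'   and `tes` (te_id, chrom, start, end, te_class).
#' @export
gen_annotation <- function(genome, config) {
  a <- config$annotation
  lens <- chrom_lengths(genome)
  set.seed(stage_seed(config$seed, "annotation"))

  per_chrom <- diff(round(seq(0, a$n_genes, length.out = length(lens) + 1)))
  genes <- list(); cds <- list()
  gid <- 0L
  for (ci in seq_along(lens)) {
    n <- per_chrom[ci]
    if (n == 0L) next
    L <- lens[ci]
    slot <- floor(L / n)
    if (slot < max(a$gene_length) + 4000L)
      stop("more genes than fit on the genome with 2-kb flanks")
    for (k in seq_len(n)) {
      gid <- gid + 1L
      glen <- sample(a$gene_length[1]:a$gene_length[2], 1L)
      lo <- (k - 1L) * slot + 2001L
      hi <- k * slot - glen - 2000L
      start <- sample(lo:hi, 1L)
      end <- start + glen - 1L
      id <- sprintf("gene%03d", gid)
      genes[[gid]] <- data.frame(gene_id = id, chrom = names(lens)[ci],
                                 start = start, end = end,
                                 strand = sample(c("+", "-"), 1L))
      cds[[gid]] <- gene_cds_intervals(id, start, end, a$n_exons)
    }
  }
  genes <- do.call(rbind, genes)
  cds <- do.call(rbind, cds)

  tes <- place_tes(genes, lens, a)
  list(genes = genes, cds = cds, tes = tes)
}

# Split a gene body into exon-like CDS intervals separated by introns.
gene_cds_intervals <- function(id, start, end, n_exons_range) {
  n_ex <- sample(n_exons_range[1]:n_exons_range[2], 1L)
  glen <- end - start + 1L
  cuts <- sort(sample(seq_len(glen - 1L), 2L * n_ex - 1L))
  bounds <- c(0L, cuts, glen)
  pieces <- data.frame(start = start + bounds[-length(bounds)],
                       end = start + bounds[-1] - 1L)
  ex <- pieces[seq(1, nrow(pieces), by = 2), , drop = FALSE]
  data.frame(gene_id = id, start = ex$start, end = ex$end, row.names = NULL)
}

place_tes <- function(genes, lens, a) {
  n_overlap <- round(a$te_overlap_fraction * a$n_tes)
  genic <- data.frame(chrom = genes$chrom,
                      start = pmax(1L, genes$start - 2000L),
                      end = genes$end + 2000L)
  tes <- vector("list", a$n_tes)
  for (k in seq_len(a$n_tes)) {
    tlen <- sample(a$te_length[1]:a$te_length[2], 1L)
    want_overlap <- k <= n_overlap
    for (try in 1:500) {
      if (want_overlap) {
        gi <- sample(nrow(genes), 1L)
        ci <- genes$chrom[gi]
        lo <- max(1L, genes$start[gi] - 2000L - tlen + 1L)
        hi <- min(lens[[ci]] - tlen + 1L, genes$end[gi] + 2000L)
        start <- sample(lo:hi, 1L)
        ok <- TRUE
      } else {
        ci <- sample(names(lens), 1L)
        start <- sample(seq_len(lens[[ci]] - tlen + 1L), 1L)
        g <- genic[genic$chrom == ci, , drop = FALSE]
        ok <- !any(start <= g$end & (start + tlen - 1L) >= g$start)
      }
      if (ok) break
      if (try == 500) stop("could not place TE ", k, "; genome too crowded")
    }
    tes[[k]] <- data.frame(te_id = sprintf("te%03d", k), chrom = ci,
                           start = start, end = start + tlen - 1L)
  }
  tes <- do.call(rbind, tes)
  tes$te_class <- sample(names(a$te_class_probs), a$n_tes, replace = TRUE,
                         prob = a$te_class_probs)
  tes[order(tes$chrom, tes$start), ]
}

#' Write a genome as FASTA
#' @param genome `DNAStringSet`.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write gene and TE annotations as GFF3
#'
#' Genes become `gene`/`mRNA`/`CDS` feature triples; TEs become
#' `repeat_region` features with a `te_class` attribute.
#' @param annotation List from [gen_annotation()].
#' @param path Output file.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  g <- annotation$genes
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    id <- g$gene_id[i]
    lines <- c(lines,
      sprintf("%s\tepiregseek\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom[i], g$start[i], g$end[i], g$strand[i], id),
      sprintf("%s\tepiregseek\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
              g$chrom[i], g$start[i], g$end[i], g$strand[i], id, id))
    cd <- annotation$cds[annotation$cds$gene_id == id, , drop = FALSE]
    lines <- c(lines, sprintf(
      "%s\tepiregseek\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s.1",
      g$chrom[i], cd$start, cd$end, g$strand[i], id))
  }
  t <- annotation$tes
  lines <- c(lines, sprintf(
    "%s\tepiregseek\trepeat_region\t%d\t%d\t.\t.\t.\tID=%s;te_class=%s",
    t$chrom, t$start, t$end, t$te_id, t$te_class))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene and TE annotations from GFF3
#'
#' Inverse of [write_annotation_gff3()]: expects `gene`, `CDS` (with a
#' `Parent=<gene>.1` attribute) and `repeat_region` (with `te_class`)
#' features; 1-based inclusive coordinates per the GFF3 standard.
#' @param path GFF3 file.
#' @return List with `genes`, `cds`, `tes` as in [gen_annotation()].
#' @export
read_annotation_gff3 <- function(path) {
  raw <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  names(raw) <- c("chrom", "source", "type", "start", "end", "score",
                  "strand", "phase", "attr")
  attr_val <- function(attr, key) {
    m <- regmatches(attr, regexpr(paste0(key, "=[^;]+"), attr))
    sub(paste0(key, "="), "", m)
  }
  g <- raw[raw$type == "gene", ]
  genes <- data.frame(gene_id = attr_val(g$attr, "ID"), chrom = g$chrom,
                      start = g$start, end = g$end, strand = g$strand)
  cd <- raw[raw$type == "CDS", ]
  cds <- data.frame(gene_id = sub("\\.1$", "", attr_val(cd$attr, "Parent")),
                    start = cd$start, end = cd$end)
  t <- raw[raw$type == "repeat_region", ]
  tes <- data.frame(te_id = attr_val(t$attr, "ID"), chrom = t$chrom,
                    start = t$start, end = t$end,
                    te_class = attr_val(t$attr, "te_class"))
  list(genes = genes, cds = cds, tes = tes)
}
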