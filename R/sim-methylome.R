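#' Simulate per-condition cytosine reports
#'
#' Every classifiable cytosine on both strands receives a true
#' methylation level: a Beta draw around the context baseline (shared
#' across conditions), overridden inside planted DMR intervals where the
#' control level is set so the planted delta fits inside `[0,1]` and the
#' carrying condition is shifted by the planted delta. Observed counts
#' are then binomial draws at negative-binomial coverage, with
#' unconverted cytosines reading as methylated at rate
#' `1 - conversion_rate`.
#'
#' @param genome `DNAStringSet`.
#' @param truth Truth table from [gen_truth()] (or `NULL` for a pure
#'   null methylome with no planted signal).
#' @param config A [sim_config()].
#' @param conditions Condition labels to emit (one pooled library each).
#' @param cmap Optional precomputed [cytosine_map()].
#' @return Named list of cytosine reports, one per condition:
#'   data.frames with chrom, pos, strand, context, meth, total.
#' @export
gen_methylome <- function(genome, truth, config,
                          conditions = CONDITIONS, cmap = NULL) {
  if (is.null(cmap)) cmap <- cytosine_map(genome)
  m <- config$methylome
  set.seed(stage_seed(config$seed, "methylome"))
  n <- nrow(cmap)

  base <- m$baseline_ml[cmap$context]
  k <- m$baseline_concentration
  ml0 <- if (is.finite(k)) rbeta(n, base * k, (1 - base) * k) else base
  ml <- matrix(ml0, nrow = n, ncol = length(conditions),
               dimnames = list(NULL, conditions))

  pd <- truth$planted_dmrs
  if (!is.null(pd) && nrow(pd)) {
    regions <- unique(pd[c("dmr_id", "chrom", "start", "end", "context",
                           "delta", "direction")])
    for (i in seq_len(nrow(regions))) {
      r <- regions[i, ]
      idx <- which(cmap$chrom == r$chrom & cmap$context == r$context &
                   cmap$pos >= r$start & cmap$pos <= r$end)
      a_level <- if (r$direction == "hyper") config$dmr$low_ml
                 else config$dmr$low_ml + abs(r$delta)
      b_level <- a_level + r$delta
      if (b_level < 0 || b_level > 1 || a_level < 0 || a_level > 1)
        stop("planted delta pushes methylation level outside [0,1]")
      ml[idx, ] <- a_level
      conds <- intersect(pd$condition[pd$dmr_id == r$dmr_id], conditions)
      ml[idx, conds] <- b_level
    }
  }

  err <- 1 - m$conversion_rate
  out <- lapply(conditions, function(cond) {
    total <- rnbinom(n, size = m$coverage_size, mu = m$coverage_mean)
    p_read <- ml[, cond] + (1 - ml[, cond]) * err
    meth <- rbinom(n, total, p_read)
    data.frame(cmap, meth = meth, total = total, row.names = NULL)
  })
  stats::setNames(out, conditions)
}

#' Write a cytosine report as TSV
#'
#' Bismark cytosine-report dialect: chrom, pos (1-based), strand,
#' count_methylated, count_unmethylated, context.
#' @param report A cytosine report data.frame.
#' @param path Output file.
#' @export
write_cytosine_report <- function(report, path) {
  out <- data.frame(chrom = report$chrom, pos = report$pos,
                    strand = report$strand,
                    count_methylated = report$meth,
                    count_unmethylated = report$total - report$meth,
                    context = report$context)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cytosine report TSV
#' @param path File written by [write_cytosine_report()] (or any TSV in
#'   the same dialect).
#' @return data.frame with chrom, pos, strand, context, meth, total.
#' @export
read_cytosine_report <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  data.frame(chrom = x$chrom, pos = x$pos, strand = x$strand,
             context = x$context, meth = x$count_methylated,
             total = x$count_methylated + x$count_unmethylated)
}
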