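#' Classify the sequence context of one cytosine
#'
#' Plant cytosine methylation is read 5'->3' on the cytosine's own
#' strand: `CG` if the next base is G, `CHG` if the next base is H
#' (A, T or C) and the one after is G, `CHH` if both downstream bases
#' are H. Sites with fewer than two downstream bases on their strand, or
#' with an N in the trinucleotide, are unclassifiable (`NA`).
#'
#' @param genome `DNAStringSet`.
#' @param chrom Chromosome name.
#' @param pos 1-based position of the cytosine on the plus-strand
#'   coordinate system (for a minus-strand site this is the position of
#'   the G on the plus strand).
#' @param strand `"+"` or `"-"`.
#' @return `"CG"`, `"CHG"`, `"CHH"` or `NA_character_`.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  L <- Biostrings::width(genome[chrom])
  if (pos < 1L || pos > L) stop("position out of bounds")
  s <- as.character(Biostrings::subseq(
    genome[[chrom]], max(1L, pos - 2L), min(L, pos + 2L)))
  off <- pos - max(1L, pos - 2L) + 1L  # index of focal base within s
  base <- substr(s, off, off)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  if (strand == "+") {
    if (base != "C") return(NA_character_)
    down <- c(substr(s, off + 1L, off + 1L), substr(s, off + 2L, off + 2L))
  } else {
    if (base != "G") return(NA_character_)
    down <- comp[c(substr(s, off - 1L, off - 1L), substr(s, off - 2L, off - 2L))]
  }
  if (any(down == "" | is.na(down) | down == "N")) return(NA_character_)
  h <- c("A", "T", "C")
  if (down[1] == "G") "CG"
  else if (down[1] %in% h && down[2] == "G") "CHG"
  else if (down[1] %in% h && down[2] %in% h) "CHH"
  else NA_character_
}

#' Enumerate all classifiable cytosines of a genome
#'
#' Vectorised scan of both strands. Positions are 1-based plus-strand
#' coordinates; minus-strand rows locate the G seen on the plus strand.
#'
#' @param genome `DNAStringSet`.
#' @return data.frame with columns chrom, pos, strand, context, ordered
#'   by (chrom, pos, strand).
#' @export
cytosine_map <- function(genome) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  h <- c("A", "T", "C")
  out <- lapply(names(genome), function(ch) {
    b <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1]]
    L <- length(b)
    ctx_of <- function(d1, d2) {
      ifelse(d1 == "G", "CG",
        ifelse(d1 %in% h & d2 == "G", "CHG",
          ifelse(d1 %in% h & d2 %in% h, "CHH", NA_character_)))
    }
    # plus strand: C at p, downstream p+1, p+2
    pp <- which(b == "C"); pp <- pp[pp <= L - 2L]
    plus <- data.frame(chrom = ch, pos = pp, strand = "+",
                       context = ctx_of(b[pp + 1L], b[pp + 2L]))
    # minus strand: G at p, downstream complements of p-1, p-2
    pm <- which(b == "G"); pm <- pm[pm >= 3L]
    minus <- data.frame(chrom = ch, pos = pm, strand = "-",
                        context = ctx_of(unname(comp[b[pm - 1L]]),
                                         unname(comp[b[pm - 2L]])))
    rbind(plus, minus)
  })
  out <- do.call(rbind, out)
  out <- out[!is.na(out$context), ]
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

#' Minimum methylated reads for a methylcytosine call
#'
#' A cytosine is called methylated only when its methylated-read count
#' exceeds what incomplete bisulfite conversion alone would produce: the
#' smallest k with upper binomial tail P(X >= k | n = coverage,
#' p = error_rate) < alpha, where error_rate = 1 - conversion rate.
#'
#' @param coverage Integer vector of total read counts.
#' @param error_rate Per-read false-methylation probability in `[0,1)`.
#' @param alpha Tail probability threshold in (0,1).
#' @return Integer vector; `NA` where no call is possible (zero coverage,
#'   or even k = coverage leaves tail mass >= alpha).
#' @examples
#' min_meth_reads(10, 0.01, 0.05)  # 2
#' @export
min_meth_reads <- function(coverage, error_rate, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must lie in [0,1)")
  if (any(coverage < 0)) stop("coverage must be non-negative")
  one <- function(n) {
    if (n == 0L) return(NA_integer_)
    k <- seq_len(n)
    tail <- pbinom(k - 1L, n, error_rate, lower.tail = FALSE)
    hit <- which(tail < alpha)
    if (!length(hit)) NA_integer_ else k[hit[1]]
  }
  u <- sort(unique(as.integer(coverage)))
  lut <- vapply(u, one, integer(1))
  lut[match(as.integer(coverage), u)]
}

#' Call methylcytosines on a cytosine report
#'
#' @param report data.frame with at least `meth` and `total` columns (as
#'   produced by [gen_methylome()] or [read_cytosine_report()]).
#' @param conversion_rate Bisulfite conversion rate in (0,1].
#' @param alpha Binomial tail threshold.
#' @return The report with added columns `min_required`, `p_binom`
#'   (upper tail at the observed count) and `is_mc`.
#' @export
call_mc <- function(report, conversion_rate = 0.99, alpha = 0.05) {
  if (conversion_rate <= 0 || conversion_rate > 1)
    stop("conversion_rate must lie in (0,1]")
  err <- 1 - conversion_rate
  report$min_required <- min_meth_reads(report$total, err, alpha)
  report$p_binom <- ifelse(report$total > 0,
                           pbinom(report$meth - 1L, report$total, err,
                                  lower.tail = FALSE),
                           NA_real_)
  report$is_mc <- !is.na(report$min_required) &
    report$meth >= report$min_required & report$total > 0L
  report
}

#' Methylation level of a site
#'
#' `meth / total`; `NA` (not 0) at zero coverage so uncovered sites drop
#' out of summaries instead of diluting them.
#' @param meth,total Read counts.
#' @return Numeric in `[0,1]` or `NA`.
#' @export
site_ml <- function(meth, total) {
  ifelse(total > 0L, meth / total, NA_real_)
}

#' Per-context methylome summary
#'
#' Mean methylation level over covered sites, methylcytosine counts and
#' the mC/C proportion, per context and overall.
#'
#' @param report A cytosine report (with `context`, `meth`, `total`).
#' @param conversion_rate,alpha Passed to [call_mc()] when the report
#'   does not already carry `is_mc`.
#' @return data.frame with one row per context plus an `all` row:
#'   context, n_covered, mean_ml, n_mc, mc_over_c. Contexts with no
#'   covered site get `NA` summaries.
#' @export
context_summary <- function(report, conversion_rate = 0.99, alpha = 0.05) {
  if (is.null(report$is_mc)) report <- call_mc(report, conversion_rate, alpha)
  report$ml <- site_ml(report$meth, report$total)
  grp <- function(sub, label) {
    cov <- sub$total > 0L
    data.frame(context = label, n_covered = sum(cov),
               mean_ml = if (any(cov)) mean(sub$ml[cov]) else NA_real_,
               n_mc = sum(sub$is_mc[cov]),
               mc_over_c = if (any(cov)) sum(sub$is_mc[cov]) / sum(cov) else NA_real_)
  }
  out <- do.call(rbind, lapply(CONTEXTS, function(cx)
    grp(report[report$context == cx, , drop = FALSE], cx)))
  rbind(out, grp(report, "all"))
}

#' Relative increment of a summary statistic
#'
#' `(treatment - control) / control`, the scale on which treatment-wise
#' changes in mean methylation level and mC/C proportion are reported.
#' @param treatment,control Numeric.
#' @export
increment_rate <- function(treatment, control) {
  (treatment - control) / control
}

# Vectorised two-sided Fisher exact p for 2x2 tables given as count
# vectors. Sums hypergeometric point probabilities <= the observed one,
# with the same 1 + 1e-7 relative tolerance stats::fisher.test uses.
fisher_test_2x2 <- function(a, b, c, d) {
  n <- length(a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m <- a[i] + b[i]; nn <- c[i] + d[i]; k <- a[i] + c[i]
    x <- max(0L, k - nn):min(k, m)
    dens <- dhyper(x, m, nn, k)
    obs <- dens[match(a[i], x)]
    p[i] <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }
  p
}

#' Call differentially methylated cytosines (DmCs)
#'
#' Fisher's exact test on the 2x2 methylated/unmethylated table per
#' site, condition B against condition A. A site is a DmC when the
#' two-sided p-value is below `alpha` and the absolute methylation-level
#' difference is at least `min_delta` (read as absolute difference, the
#' standard WGBS usage). No multiple-testing correction is applied to
#' the per-site p-values: the delta filter is the second gate. Sites
#' with coverage below `min_coverage` in either sample are excluded from
#' testing (Fisher on tiny counts is powerless; set to 1 to disable).
#'
#' @param report_a,report_b Cytosine reports sharing the same site keys
#'   (chrom, pos, strand, context).
#' @param alpha Fisher p threshold.
#' @param min_delta Minimum |ML(B) - ML(A)|.
#' @param min_coverage Coverage floor applied to both samples.
#' @return data.frame of DmCs: chrom, pos, strand, context, meth_a,
#'   total_a, meth_b, total_b, ml_a, ml_b, delta (= ml_b - ml_a), p,
#'   direction ("hyper" if B gained methylation, else "hypo").
#' @export
call_dmcs <- function(report_a, report_b, alpha = 0.05, min_delta = 0.2,
                      min_coverage = 4L) {
  key_cols <- c("chrom", "pos", "strand", "context")
  if (nrow(report_a) != nrow(report_b) ||
      !all(report_a[key_cols] == report_b[key_cols]))
    stop("cytosine reports must share identical site keys in order")
  keep <- report_a$total >= min_coverage & report_b$total >= min_coverage
  a <- report_a[keep, c(key_cols, "meth", "total")]
  b <- report_b[keep, c("meth", "total")]
  ml_a <- a$meth / a$total
  ml_b <- b$meth / b$total
  delta <- ml_b - ml_a
  cand <- which(abs(delta) >= min_delta)   # p and delta are conjunctive
  p <- fisher_test_2x2(a$meth[cand], a$total[cand] - a$meth[cand],
                       b$meth[cand], b$total[cand] - b$meth[cand])
  hit <- cand[p < alpha]
  out <- data.frame(a[hit, key_cols],
                    meth_a = a$meth[hit], total_a = a$total[hit],
                    meth_b = b$meth[hit], total_b = b$total[hit],
                    ml_a = ml_a[hit], ml_b = ml_b[hit], delta = delta[hit],
                    p = p[p < alpha],
                    direction = ifelse(delta[hit] > 0, "hyper", "hypo"),
                    row.names = NULL)
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

#' Fisher exact test for one 2x2 site comparison
#'
#' Scalar convenience wrapper around the vectorised test used by
#' [call_dmcs()].
#' @param meth_a,total_a,meth_b,total_b Counts for the two samples.
#' @return Two-sided p-value.
#' @export
dmc_fisher_p <- function(meth_a, total_a, meth_b, total_b) {
  fisher_test_2x2(meth_a, total_a - meth_a, meth_b, total_b - meth_b)
}
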