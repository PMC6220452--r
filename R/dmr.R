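#' Seed test for a differentially methylated region
#'
#' A window of five adjacent same-context cytosines seeds a DMR when at
#' least four of them are DmCs sharing one direction and the two-sided
#' Wilcoxon rank-sum test comparing the five per-site methylation levels
#' of the two samples is significant. By default an opposite-direction
#' DmC anywhere in the window vetoes the seed ("same response pattern"
#' read strictly); set `veto_opposite = FALSE` to allow 4-vs-1 windows.
#'
#' @param ml_a,ml_b Methylation levels of the five window sites in the
#'   two samples.
#' @param dmc Character vector of per-site DmC status: `"hyper"`,
#'   `"hypo"` or `"none"`.
#' @param alpha Wilcoxon significance threshold.
#' @param veto_opposite Veto windows containing an opposite-direction DmC.
#' @return List: `is_seed`, `direction` (`NA` when not a seed), `p`.
#' @export
seed_test <- function(ml_a, ml_b, dmc, alpha = 0.05, veto_opposite = TRUE) {
  if (length(ml_a) != 5L || length(ml_b) != 5L || length(dmc) != 5L)
    stop("seed windows hold exactly 5 sites")
  n_hyper <- sum(dmc == "hyper"); n_hypo <- sum(dmc == "hypo")
  direction <- if (n_hyper >= 4L && (!veto_opposite || n_hypo == 0L)) "hyper"
    else if (n_hypo >= 4L && (!veto_opposite || n_hyper == 0L)) "hypo"
    else NA_character_
  if (is.na(direction)) return(list(is_seed = FALSE, direction = NA, p = NA_real_))
  p <- wilcoxon_rank_sum_p(ml_a, ml_b)
  list(is_seed = p < alpha, direction = if (p < alpha) direction else NA, p = p)
}

# Extend a seed 3' (increasing coordinates) one site at a time: a site
# joins iff it keeps the response pattern (strictly, a DmC of the seed's
# direction; leniently, also a non-significant site whose ML difference
# has the seed's sign) and the rank-sum test over the enlarged set stays
# significant. Returns the index of the last member site.
extend_candidate <- function(series, start_i, end_i, direction,
                             alpha = 0.05, lenient = FALSE) {
  n <- nrow(series)
  j <- end_i
  sgn <- if (direction == "hyper") 1 else -1
  while (j < n) {
    k <- j + 1L
    pattern_ok <- series$dmc[k] == direction ||
      (lenient && series$dmc[k] == "none" &&
         sign(series$ml_b[k] - series$ml_a[k]) == sgn)
    if (!pattern_ok) break
    p <- wilcoxon_rank_sum_p(series$ml_a[start_i:k], series$ml_b[start_i:k])
    if (p >= alpha) break
    j <- k
  }
  j
}

# One chromosome x context series of testable sites: consecutive
# same-context cytosines (strands pooled in coordinate order by default)
# covered at >= min_coverage in both samples, with per-site MLs and DmC
# status.
build_series <- function(report_a, report_b, context, min_coverage,
                         alpha_dmc, min_delta_dmc) {
  keep <- report_a$context == context &
    report_a$total >= min_coverage & report_b$total >= min_coverage
  a <- report_a[keep, ]
  b <- report_b[keep, ]
  ml_a <- a$meth / a$total
  ml_b <- b$meth / b$total
  delta <- ml_b - ml_a
  dmc <- rep("none", nrow(a))
  cand <- which(abs(delta) >= min_delta_dmc)
  if (length(cand)) {
    p <- fisher_test_2x2(a$meth[cand], a$total[cand] - a$meth[cand],
                         b$meth[cand], b$total[cand] - b$meth[cand])
    hit <- cand[p < alpha_dmc]
    dmc[hit] <- ifelse(delta[hit] > 0, "hyper", "hypo")
  }
  data.frame(chrom = a$chrom, pos = a$pos, strand = a$strand,
             ml_a = ml_a, ml_b = ml_b, dmc = dmc, row.names = NULL)
}

#' Call differentially methylated regions (seed and extend)
#'
#' Scans 5-site sliding windows over the series of testable same-context
#' cytosines of each chromosome (strands pooled in coordinate order, so
#' "adjacent motifs" means adjacent along the chromosome), seeds windows
#' passing [seed_test()], extends each seed 3' site by site while the
#' rank-sum significance persists, merges overlapping same-direction
#' candidates (statistics recomputed over the union of member sites),
#' and discards candidates shorter than `min_len` bp or with a mean
#' methylation-level difference below `min_delta` (both thresholds
#' inclusive: a 50-bp, 0.10-delta region is kept).
#'
#' @param report_a,report_b Cytosine reports (A = control, B = treatment).
#' @param contexts Contexts to scan.
#' @param alpha_dmc,min_delta_dmc,min_coverage DmC-calling parameters
#'   (see [call_dmcs()]).
#' @param alpha_seed Wilcoxon threshold for seeding and extension.
#' @param min_len Minimum region span in bp (first to last member
#'   cytosine, inclusive).
#' @param min_delta Minimum |mean ML(B) - mean ML(A)| over member sites.
#' @param lenient Extension also admits non-significant sites whose ML
#'   difference has the seed's sign.
#' @param veto_opposite See [seed_test()].
#' @param strand_pooled If `FALSE`, scan each strand separately.
#' @return data.frame of DMRs sorted by (chrom, start): dmr_id, chrom,
#'   start, end (1-based inclusive), context, direction, n_sites, ml_a,
#'   ml_b (mean over member sites), delta, p.
#' @export
call_dmrs <- function(report_a, report_b, contexts = CONTEXTS,
                      alpha_dmc = 0.05, min_delta_dmc = 0.2,
                      min_coverage = 4L, alpha_seed = 0.05,
                      min_len = 50L, min_delta = 0.1,
                      lenient = FALSE, veto_opposite = TRUE,
                      strand_pooled = TRUE) {
  if (!all(contexts %in% CONTEXTS))
    stop("unknown context label: ", paste(setdiff(contexts, CONTEXTS), collapse = ","))
  out <- list()
  for (ctx in contexts) {
    series_all <- build_series(report_a, report_b, ctx, min_coverage,
                               alpha_dmc, min_delta_dmc)
    groups <- if (strand_pooled) split(series_all, series_all$chrom)
              else split(series_all, paste(series_all$chrom, series_all$strand))
    for (series in groups) {
      series <- series[order(series$pos, series$strand), ]
      cands <- scan_series(series, alpha_seed, lenient, veto_opposite)
      if (!nrow(cands)) next
      cands <- merge_candidates(cands)
      for (i in seq_len(nrow(cands))) {
        idx <- cands$start_i[i]:cands$end_i[i]
        p <- wilcoxon_rank_sum_p(series$ml_a[idx], series$ml_b[idx])
        if (p >= alpha_seed) next
        ml_a <- mean(series$ml_a[idx]); ml_b <- mean(series$ml_b[idx])
        out[[length(out) + 1L]] <- data.frame(
          chrom = series$chrom[1], start = series$pos[idx[1]],
          end = series$pos[idx[length(idx)]], context = ctx,
          direction = cands$direction[i], n_sites = length(idx),
          ml_a = ml_a, ml_b = ml_b, delta = ml_b - ml_a, p = p)
      }
    }
  }
  if (!length(out)) return(empty_dmr_frame())
  dmrs <- do.call(rbind, out)
  dmrs <- filter_dmrs(dmrs, min_len = min_len, min_delta = min_delta)
  dmrs <- dmrs[order(dmrs$chrom, dmrs$start), , drop = FALSE]
  dmrs <- cbind(dmr_id = sprintf("dmr%04d", seq_len(nrow(dmrs))), dmrs)
  rownames(dmrs) <- NULL
  dmrs
}

empty_dmr_frame <- function() {
  data.frame(dmr_id = character(), chrom = character(), start = integer(),
             end = integer(), context = character(), direction = character(),
             n_sites = integer(), ml_a = numeric(), ml_b = numeric(),
             delta = numeric(), p = numeric())
}

# Sliding-window scan over one series. Rolling DmC counts pick out the
# windows worth testing; each passing seed is extended immediately and
# later windows falling inside the grown candidate (same direction) are
# skipped.
scan_series <- function(series, alpha_seed, lenient, veto_opposite) {
  n <- nrow(series)
  none <- data.frame(start_i = integer(), end_i = integer(),
                     direction = character())
  if (n < 5L) return(none)
  ch <- cumsum(c(0L, series$dmc == "hyper"))
  cl <- cumsum(c(0L, series$dmc == "hypo"))
  i <- seq_len(n - 4L)
  nh <- ch[i + 5L] - ch[i]
  nl <- cl[i + 5L] - cl[i]
  seed_ok <- if (veto_opposite) (nh >= 4L & nl == 0L) | (nl >= 4L & nh == 0L)
             else nh >= 4L | nl >= 4L
  todo <- which(seed_ok)
  cands <- list()
  last_end <- 0L; last_dir <- ""
  for (i0 in todo) {
    direction <- if (nh[i0] >= 4L) "hyper" else "hypo"
    if (i0 + 4L <= last_end && direction == last_dir) next
    st <- seed_test(series$ml_a[i0:(i0 + 4L)], series$ml_b[i0:(i0 + 4L)],
                    series$dmc[i0:(i0 + 4L)], alpha_seed, veto_opposite)
    if (!st$is_seed) next
    e <- extend_candidate(series, i0, i0 + 4L, st$direction, alpha_seed,
                          lenient)
    cands[[length(cands) + 1L]] <- data.frame(
      start_i = i0, end_i = e, direction = st$direction)
    last_end <- e; last_dir <- st$direction
  }
  if (!length(cands)) none else do.call(rbind, cands)
}

# Merge overlapping same-direction candidates into index-range unions.
merge_candidates <- function(cands) {
  out <- list()
  for (dir in unique(cands$direction)) {
    x <- cands[cands$direction == dir, , drop = FALSE]
    x <- x[order(x$start_i), , drop = FALSE]
    cur <- x[1, ]
    for (i in seq_len(nrow(x))[-1]) {
      if (x$start_i[i] <= cur$end_i) {
        cur$end_i <- max(cur$end_i, x$end_i[i])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- x[i, ]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, out)
}

#' Filter DMR candidates on span and effect size
#'
#' Discards candidates spanning fewer than `min_len` bases or with
#' |delta| below `min_delta`; both thresholds are inclusive (the rule
#' discards regions strictly smaller). The counts of candidates
#' discarded per reason are attached as attribute `"discarded"`.
#'
#' @param candidates DMR data.frame (needs start, end, delta).
#' @param min_len,min_delta Inclusive thresholds.
#' @return The surviving rows.
#' @export
filter_dmrs <- function(candidates, min_len = 50L, min_delta = 0.1) {
  span <- candidates$end - candidates$start + 1L
  short <- span < min_len
  weak <- abs(candidates$delta) < min_delta
  out <- candidates[!short & !weak, , drop = FALSE]
  attr(out, "discarded") <- c(short = sum(short), small_delta = sum(weak))
  out
}

#' Write DMRs as BED6 plus a detail TSV
#'
#' BED is 0-based half-open; name = `context:direction`, score =
#' `round(1000 * |delta|)`. The companion TSV keeps the full 1-based
#' inclusive records.
#' @param dmrs DMR data.frame from [call_dmrs()].
#' @param prefix Path prefix (writes `<prefix>.bed`, `<prefix>.tsv`).
#' @export
write_dmrs <- function(dmrs, prefix) {
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L,
                    end = dmrs$end,
                    name = paste0(dmrs$context, ":", dmrs$direction),
                    score = round(1000 * abs(dmrs$delta)), strand = ".")
  write.table(bed, paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(dmrs, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}
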