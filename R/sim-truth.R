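#' Plant the recoverable truth for a simulated study
#'
#' Chooses, deterministically under the configured seed, everything the
#' downstream recovery tests need to know: differentially methylated
#' regions (background DMRs per context per treatment, a configurable
#' fraction planted identically in LL, HS and HL so they are shared
#' relative to the LS control), promoter methylation/expression
#' couplings (hypermethylated CG/CHG promoter DMRs paired with down- or
#' up-regulated genes), differentially expressed genes and TEs, the
#' phenotype variance components, and which accessions truly lose
#' femaleness in early autumn.
#'
#' Planted DMRs are placed only where at least `min_sites` same-context
#' cytosines fall within the requested span; placement retries are
#' bounded and failure is an error. Intervals are pairwise disjoint
#' (with a spacing buffer) so recovery is well posed.
#'
#' @param genome `DNAStringSet` from [gen_genome()].
#' @param annotation List from [gen_annotation()].
#' @param config A [sim_config()].
#' @param cmap Optional precomputed [cytosine_map()] of `genome`.
#' @return A truth table: list with `planted_dmrs`, `planted_degs`,
#'   `planted_epiregs`, `planted_dets`, `base_means`, `te_base_means`,
#'   `variance_components`, `seasonal`.
#' @export
gen_truth <- function(genome, annotation, config, cmap = NULL) {
  if (is.null(cmap)) cmap <- cytosine_map(genome)
  set.seed(stage_seed(config$seed, "truth"))
  ex <- config$expression

  base_means <- stats::setNames(
    rlnorm(nrow(annotation$genes), ex$meanlog, ex$sdlog),
    annotation$genes$gene_id)
  te_base_means <- stats::setNames(
    rlnorm(nrow(annotation$tes), ex$te_meanlog, ex$te_sdlog),
    annotation$tes$te_id)

  placed <- data.frame(chrom = character(), start = integer(), end = integer())
  gap <- config$dmr$gap

  clashes <- function(chrom, start, end) {
    p <- placed[placed$chrom == chrom, , drop = FALSE]
    any(start <= p$end + gap & end >= p$start - gap)
  }

  # Find a span-long window holding >= min_sites context cytosines inside
  # [lo, hi] on chrom; returns c(start, end, n_sites) or NULL.
  find_block <- function(chrom, lo, hi, context, span, min_sites) {
    s <- cmap[cmap$chrom == chrom & cmap$context == context &
              cmap$pos >= lo & cmap$pos <= hi, , drop = FALSE]
    if (nrow(s) < min_sites) return(NULL)
    starts <- s$pos[s$pos + span - 1L <= hi]
    ok <- vapply(starts, function(st)
      sum(s$pos >= st & s$pos <= st + span - 1L) >= min_sites, logical(1))
    starts <- starts[ok]
    starts <- starts[!vapply(starts, function(st)
      clashes(chrom, st, st + span - 1L), logical(1))]
    if (!length(starts)) return(NULL)
    st <- if (length(starts) == 1L) starts else sample(starts, 1L)
    n <- sum(s$pos >= st & s$pos <= st + span - 1L)
    c(st, st + span - 1L, n)
  }

  dmrs <- list(); epiregs <- list(); dmr_i <- 0L

  add_dmr <- function(chrom, blk, context, delta_abs, direction, conditions,
                      kind) {
    dmr_i <<- dmr_i + 1L
    id <- sprintf("pdmr%03d", dmr_i)
    placed <<- rbind(placed, data.frame(chrom = chrom, start = blk[1],
                                        end = blk[2]))
    dmrs[[length(dmrs) + 1L]] <<- data.frame(
      dmr_id = id, chrom = chrom, start = blk[1], end = blk[2],
      context = context, delta = if (direction == "hyper") delta_abs else -delta_abs,
      direction = direction, condition = conditions, n_sites = blk[3],
      kind = kind)
    id
  }

  # --- promoter couplings (epiregulation truth) -------------------------
  ep <- config$epireg
  genes <- annotation$genes
  bm <- base_means[genes$gene_id]
  eligible <- genes$gene_id[bm >= ex$min_base_count &
                            bm <= stats::quantile(bm, ex$max_base_quantile)]
  eligible <- sample(eligible)
  want <- c(rep("negative", ep$n_negative), rep("positive", ep$n_positive))
  gi <- 1L
  for (sg in want) {
    ok <- FALSE
    while (gi <= length(eligible)) {
      g <- genes[genes$gene_id == eligible[gi], ]
      gi <- gi + 1L
      tss <- if (g$strand == "+") g$start else g$end
      win <- if (g$strand == "+") c(tss - 2000L, tss - 1L) else c(tss + 1L, tss + 2000L)
      for (ctx in sample(c("CG", "CHG"))) {
        blk <- find_block(g$chrom, win[1], win[2], ctx, ep$span, ep$min_sites)
        if (!is.null(blk)) {
          id <- add_dmr(g$chrom, blk, ctx, ep$delta, "hyper", ep$condition,
                        "epireg")
          epiregs[[length(epiregs) + 1L]] <- data.frame(
            gene_id = g$gene_id, dmr_id = id, sign = sg,
            condition = ep$condition)
          ok <- TRUE
          break
        }
      }
      if (ok) break
    }
    if (!ok) stop("could not place a promoter DMR; genome too small or sparse")
  }
  epiregs <- if (length(epiregs)) do.call(rbind, epiregs) else
    data.frame(gene_id = character(), dmr_id = character(),
               sign = character(), condition = character())

  # keep background DMRs out of the coupling genes' association zones
  # (CDS / 2 kb of TSS-TES) so the planted coupling signs stay the only
  # methylation-expression couplings at those genes
  if (nrow(epiregs)) {
    zg <- genes[genes$gene_id %in% epiregs$gene_id, ]
    placed <- rbind(placed, data.frame(chrom = zg$chrom,
                                       start = pmax(1L, zg$start - 2000L),
                                       end = zg$end + 2000L))
  }

  # --- background DMRs per context per treatment ------------------------
  d <- config$dmr
  lens <- chrom_lengths(genome)
  treatments <- setdiff(CONDITIONS, "LS")
  n_shared <- round(d$shared_fraction * d$n_per_context)
  for (ctx in CONTEXTS) {
    specs <- c(rep(list(treatments), n_shared),
               lapply(seq_len(d$n_per_context - n_shared), function(i)
                 treatments[1L + (i - 1L) %% length(treatments)]))
    for (conds in specs) {
      direction <- if (runif(1) < d$p_hyper) "hyper" else "hypo"
      blk <- NULL
      for (try in 1:200) {
        ch <- sample(names(lens), 1L)
        lo <- sample.int(lens[[ch]] - d$span - 10L, 1L)
        blk <- find_block(ch, lo, min(lens[[ch]], lo + 20L * d$span), ctx,
                          d$span, d$min_sites)
        if (!is.null(blk)) break
      }
      if (is.null(blk)) stop("could not place a planted ", ctx, " DMR")
      add_dmr(ch, blk, ctx, d$delta, direction, conds, "background")
    }
  }
  planted_dmrs <- do.call(rbind, dmrs)
  row.names(planted_dmrs) <- NULL

  # --- expression truth -------------------------------------------------
  # planted DEGs come in baseline-matched up/down pairs so the planted
  # mass leaves per-condition library sizes comparable (in real
  # transcriptomes DEGs are a tiny mass fraction; a small panel would
  # otherwise couple every gene's FPKM to the planted shifts)
  deg_pool <- setdiff(eligible, epiregs$gene_id)
  deg_ids <- sample(deg_pool, min(ex$n_degs, length(deg_pool)))
  deg_ids <- deg_ids[order(base_means[deg_ids])]
  lfc <- rep(c(1, -1), length.out = length(deg_ids)) * ex$deg_log2fc
  planted_degs <- data.frame(
    gene_id = deg_ids, log2fc = lfc,
    direction = ifelse(lfc > 0, "up", "down"),
    condition = ex$deg_condition, kind = "deg")
  if (nrow(epiregs)) {
    epi_degs <- data.frame(
      gene_id = epiregs$gene_id,
      log2fc = ifelse(epiregs$sign == "negative", -ep$log2fc, ep$log2fc),
      direction = ifelse(epiregs$sign == "negative", "down", "up"),
      condition = epiregs$condition, kind = "epireg")
    planted_degs <- rbind(planted_degs, epi_degs)
  }

  # DETs planted only on TEs clear of gene bodies (gene-overlapping TEs
  # are discarded by the caller anyway) and with detectable baselines
  tes <- annotation$tes
  body_free <- !overlaps_any_feature(tes, genes)
  det_pool <- tes$te_id[body_free & te_base_means[tes$te_id] >= 20]
  det_ids <- sample(det_pool, min(ex$n_dets, length(det_pool)))
  det_lfc <- rep(c(1, -1), length.out = length(det_ids)) * ex$det_log2fc
  planted_dets <- data.frame(
    te_id = det_ids, log2fc = det_lfc,
    direction = ifelse(det_lfc > 0, "up", "down"),
    condition = ex$deg_condition)

  ph <- config$phenotype
  seasonal <- data.frame(
    accession = sprintf("acc%03d", seq_len(ph$varieties)),
    sensitive = runif(ph$varieties) < ph$decrease_fraction)

  truth <- list(planted_dmrs = planted_dmrs,
                planted_degs = planted_degs,
                planted_epiregs = epiregs,
                planted_dets = planted_dets,
                base_means = base_means,
                te_base_means = te_base_means,
                variance_components = ph$variance_components,
                seasonal = seasonal)
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  d <- truth$planted_dmrs
  for (ctx in unique(d$context)) {
    iv <- unique(d[d$context == ctx, c("chrom", "start", "end")])
    iv <- iv[order(iv$chrom, iv$start), ]
    by_chrom <- split(iv, iv$chrom)
    for (x in by_chrom) {
      if (nrow(x) > 1 && any(x$start[-1] <= x$end[-nrow(x)]))
        stop("planted DMR intervals overlap within context ", ctx)
    }
  }
  if (any(d$n_sites < 5L)) stop("planted DMR with fewer than 5 context sites")
  e <- truth$planted_epiregs
  if (!all(e$dmr_id %in% d$dmr_id)) stop("epireg coupling references unknown DMR")
  if (any(truth$variance_components < 0)) stop("negative variance component")
  invisible(truth)
}
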