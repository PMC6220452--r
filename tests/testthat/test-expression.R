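# A bare 2x2x(reps) FPKM matrix with chosen cell means, for the
# statistics that do not need a genome behind them.
toy_fpkm <- function(cell_means, n_genes = nrow(cell_means), reps = 3,
                     sd = 0.5, seed = 1) {
  set.seed(seed)
  samples <- data.frame(
    sample = paste0(rep(c("LS", "LL", "HS", "HL"), each = reps), "_r",
                    rep(seq_len(reps), 4)),
    condition = rep(c("LS", "LL", "HS", "HL"), each = reps),
    replicate = rep(seq_len(reps), 4))
  m <- matrix(NA_real_, n_genes, nrow(samples),
              dimnames = list(paste0("g", seq_len(n_genes)), samples$sample))
  for (cond in colnames(cell_means)) {
    cols <- samples$sample[samples$condition == cond]
    m[, cols] <- pmax(0, cell_means[, cond] +
                        rnorm(n_genes * length(cols), 0, sd))
  }
  list(fpkm = m, samples = samples)
}

test_that("DEG calling enforces both the probability and fold-change gates", {
  cm <- cbind(LS = c(10, 10, 50, 5), LL = c(10, 10, 50, 5),
              HS = c(10, 10, 50, 5), HL = c(40, 15, 50, 5))
  tf <- toy_fpkm(cm, sd = 0.3)
  degs <- call_degs(tf$fpkm, "LS", "HL", samples = tf$samples)
  expect_equal(degs$gene_id, "g1")          # clean 4-fold separation
  expect_equal(degs$direction, "up")
  expect_gte(degs$prob, 0.8)
  # g2: fold-change 1.5 < 2, never a DEG however divergent
  expect_false("g2" %in% degs$gene_id)

  # externally supplied probabilities override the built-in scheme
  probs <- data.frame(gene_id = rownames(tf$fpkm), prob = 0)
  expect_equal(nrow(call_degs(tf$fpkm, "LS", "HL", samples = tf$samples,
                              probs = probs)), 0L)
  expect_error(divergence_probability(tf$fpkm[, 1, drop = FALSE],
                                      tf$samples[1, ], "LS", "HL"),
               "replicates")
})

test_that("DEG screen has near-zero false positives and full recall on planted shifts", {
  sim <- get_study()
  degs <- call_degs(sim$expression, "LS", "HL")
  pd <- sim$truth$planted_degs
  pd <- pd[pd$condition == "HL", ]
  ev <- evaluate_deg_recovery(degs, pd, nrow(sim$expression$fpkm))
  expect_gte(ev$recall, 0.95)
  expect_lte(ev$fpr, 0.02)
  # planted at |log2FC| = 3 specifically
  strong <- pd[pd$kind == "deg", ]
  expect_gte(mean(strong$gene_id %in% degs$gene_id), 0.95)
  # emitted records satisfy the type invariants
  expect_true(all(abs(degs$log2fc) >= 1))
  expect_true(all(degs$prob >= 0.8))

  # a null condition pair (same planted state in LS and LL except
  # LL-planted truth) still respects the gates
  null_degs <- call_degs(sim$expression, "LS", "LL")
  expect_true(all(null_degs$prob >= 0.8 & abs(null_degs$log2fc) >= 1))
})

test_that("Venn region counts enumerate DEG set overlaps", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("c", "e"))
  v <- stats::setNames(deg_overlap(sets)$count, deg_overlap(sets)$region)
  expect_equal(unname(v[c("A", "B", "C", "A&B", "A&B&C")]),
               c(1L, 1L, 1L, 1L, 1L))
  idv <- deg_overlap(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(idv$region, "A&B")
  dis <- deg_overlap(list(A = "x", B = "y"))
  expect_true(!any(grepl("&", dis$region)))
})

test_that("per-gene two-factor ANOVA matches aov and recovers planted terms", {
  # pure temperature shift: only the temperature term fires
  cm <- cbind(LS = c(10, 10), LL = c(10, 10), HS = c(40, 10), HL = c(40, 10))
  tf <- toy_fpkm(cm, sd = 0.2, seed = 3)
  ga <- gene_anova(tf$fpkm, tf$samples)
  expect_lt(ga$per_gene$p_temperature[1], 1e-6)
  expect_gt(ga$per_gene$p_photoperiod[1], 0.05)

  # interaction-only pattern
  cmi <- cbind(LS = 10, LL = 30, HS = 30, HL = 10)
  tfi <- toy_fpkm(cmi, sd = 0.2, seed = 4)
  gi <- gene_anova(tfi$fpkm, tfi$samples)
  expect_lt(gi$per_gene$p_interaction[1], 1e-6)
  expect_gt(gi$per_gene$p_temperature[1], 0.05)

  # closed-form p-values equal aov's on random data
  set.seed(5)
  cmr <- matrix(runif(40, 5, 50), 10, 4,
                dimnames = list(NULL, c("LS", "LL", "HS", "HL")))
  tfr <- toy_fpkm(cmr, sd = 1, seed = 6)
  gr <- gene_anova(tfr$fpkm, tfr$samples)
  cond <- tfr$samples$condition
  tempf <- factor(substr(cond, 1, 1)); photof <- factor(substr(cond, 2, 2))
  for (i in c(1, 4, 7)) {
    y <- log2(tfr$fpkm[i, ] + 1)
    sm <- summary(aov(y ~ tempf * photof))[[1]]
    expect_equal(gr$per_gene$p_temperature[i], sm$`Pr(>F)`[1])
    expect_equal(gr$per_gene$p_photoperiod[i], sm$`Pr(>F)`[2])
    expect_equal(gr$per_gene$p_interaction[i], sm$`Pr(>F)`[3])
  }

  # type-I error under the global null, 2000 genes
  set.seed(7)
  cm0 <- matrix(rep(20, 2000 * 4), ncol = 4,
                dimnames = list(NULL, c("LS", "LL", "HS", "HL")))
  tf0 <- toy_fpkm(cm0, n_genes = 2000, sd = 2, seed = 8)
  g0 <- gene_anova(tf0$fpkm, tf0$samples)
  for (term in c("temperature", "photoperiod", "interaction")) {
    frac <- g0$n_significant[[term]] / 2000
    expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  }
})

test_that("TE FPKM normalisation follows the count/length/library formula", {
  cnt <- matrix(c(100, 0, 50, 200), 2, 2,
                dimnames = list(c("t1", "t2"), c("s1", "s2")))
  f <- te_expression(cnt, c(t1 = 1000, t2 = 500), c(s1 = 1e6, s2 = 2e6))
  expect_equal(f["t1", "s1"], 100)
  expect_equal(f["t2", "s1"], 0)
  # doubling the library halves FPKM
  expect_equal(f["t1", "s2"], 50 / 1 / 2)
  expect_error(te_expression(cnt, c(t1 = 0, t2 = 500), c(s1 = 1e6, s2 = 1e6)))
  expect_error(te_expression(cnt, c(t1 = 1000, t2 = 500), c(s1 = 0, s2 = 1e6)))
})

test_that("DET calling discards gene-overlapping TEs and recovers planted shifts", {
  sim <- get_study()
  ex <- sim$expression
  dets <- call_dets(ex$te_counts, ex$samples, "LS", "HL", sim$annotation,
                    ex$library_sizes)
  td <- sim$truth$planted_dets[sim$truth$planted_dets$condition == "HL", ]
  expect_gte(mean(td$te_id %in% dets$te_id), 0.9)
  expect_true(all(dets$padj < 0.05))

  # no emitted TE overlaps a protein-coding gene body
  tes <- sim$annotation$tes
  hit <- tes[tes$te_id %in% dets$te_id, ]
  gr_g <- GenomicRanges::GRanges(sim$annotation$genes$chrom,
    IRanges::IRanges(sim$annotation$genes$start, sim$annotation$genes$end))
  gr_t <- GenomicRanges::GRanges(hit$chrom, IRanges::IRanges(hit$start, hit$end))
  expect_equal(sum(IRanges::overlapsAny(gr_t, gr_g)), 0L)

  # identical counts across conditions are never DETs
  flat <- matrix(50, 4, nrow(ex$samples),
                 dimnames = list(tes$te_id[1:4], ex$samples$sample))
  libs <- stats::setNames(rep(1e6, nrow(ex$samples)), ex$samples$sample)
  d0 <- suppressWarnings(
    call_dets(flat, ex$samples, "LS", "HL", sim$annotation, libs))
  expect_equal(nrow(d0), 0L)
})

test_that("the epiregulation screen applies region, context and sign rules", {
  ann <- list(
    genes = data.frame(gene_id = c("gene1", "gene2"), chrom = "chr1",
                       start = c(10000L, 30000L), end = c(13000L, 33000L),
                       strand = c("+", "+")),
    cds = data.frame(gene_id = c("gene1", "gene2"),
                     start = c(10000L, 30000L), end = c(13000L, 33000L)),
    tes = data.frame(te_id = character(), chrom = character(),
                     start = integer(), end = integer(),
                     te_class = character()))
  degs <- data.frame(gene_id = c("gene1", "gene2"),
                     direction = c("down", "up"))
  dmrs <- data.frame(
    dmr_id = c("d1", "d2", "d3", "d4"),
    chrom = "chr1",
    start = c(9400, 30100, 9000, 16000),
    end = c(9600, 30200, 9200, 16400),
    context = c("CHG", "CG", "CHH", "CG"),
    direction = c("hyper", "hyper", "hyper", "hyper"))
  scr <- epireg_screen(dmrs, degs, ann)
  # d1: hyper 500 bp upstream of gene1 TSS + down DEG -> negative, kept
  # d2: hyper in gene2 CDS + up DEG -> positive, discarded
  # d3: CHH -> filtered silently; d4: > 2 kb from both genes -> no event
  expect_equal(nrow(scr$events), 2L)
  expect_equal(scr$events$sign[scr$events$dmr_id == "d1"], "negative")
  expect_equal(scr$events$region[scr$events$dmr_id == "d1"],
               "within-2kb-of-TSS")
  expect_equal(scr$events$sign[scr$events$dmr_id == "d2"], "positive")
  expect_equal(scr$putative_genes, "gene1")
  expect_equal(unname(scr$summary["n_events"]), 2)
  expect_equal(unname(scr$summary["frac_positive"]), 0.5)

  # one gene with two negative associations: two events, one putative gene
  dmrs2 <- dmrs[c(1, 1), ]; dmrs2$dmr_id <- c("d1", "d1b")
  dmrs2$start[2] <- 13500; dmrs2$end[2] <- 13700   # near TES
  scr2 <- epireg_screen(dmrs2, degs, ann)
  expect_equal(nrow(scr2$events), 2L)
  expect_equal(scr2$putative_genes, "gene1")
})

test_that("planted negative couplings are recovered and concordant couplings never emitted", {
  sim <- get_study()
  degs <- call_degs(sim$expression, "LS", "HL")
  dmrs <- call_dmrs(sim$methylomes$LS, sim$methylomes$HL,
                    contexts = c("CG", "CHG"))
  scr <- epireg_screen(dmrs, degs, sim$annotation)
  ev <- evaluate_epireg_recovery(scr, sim$truth$planted_epiregs)
  expect_gte(ev$recall, 0.9)
  expect_equal(ev$n_concordant_emitted, 0L)
  # events partition into positive and negative; putative <= negative
  expect_equal(sum(scr$events$sign == "positive") +
                 sum(scr$events$sign == "negative"), nrow(scr$events))
  expect_lte(length(scr$putative_genes), sum(scr$events$sign == "negative"))
})
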