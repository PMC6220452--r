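test_that("genome generation respects length, alphabet and GC fraction", {
  cfg <- sim_config(seed = 1, genome = list(n_chrom = 1L, length = 100000L))
  g <- gen_genome(cfg)
  expect_equal(unname(Biostrings::width(g)), 100000L)
  freq <- Biostrings::alphabetFrequency(g[[1]])
  expect_equal(sum(freq[c("A", "C", "G", "T")]), 100000L)

  cfg2 <- sim_config(seed = 2, genome = list(n_chrom = 1L, length = 1000000L,
                                             gc = 0.5))
  g2 <- gen_genome(cfg2)
  f2 <- Biostrings::alphabetFrequency(g2[[1]])
  gc <- sum(f2[c("C", "G")]) / 1000000
  expect_lt(abs(gc - 0.5), 0.01)

  expect_error(sim_config(seed = 1, genome = list(length = -5L)))
  expect_error(sim_config(seed = 1, genome = list(length = 5000L)),
               "10 kb")
})

test_that("identical configuration gives byte-identical outputs", {
  a <- simulate_study(small_config(seed = 11))
  b <- simulate_study(small_config(seed = 11))
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  expect_identical(a$methylomes, b$methylomes)
  expect_identical(a$expression, b$expression)
  expect_identical(a$phenotype_field, b$phenotype_field)
  c <- simulate_study(small_config(seed = 12))
  expect_false(identical(a$methylomes, c$methylomes))
})

test_that("annotations stay within bounds and honour the TE overlap fraction", {
  cfg <- sim_config(seed = 3)
  genome <- gen_genome(cfg)
  ann <- gen_annotation(genome, cfg)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  expect_equal(nrow(ann$genes), cfg$annotation$n_genes)
  expect_equal(nrow(ann$tes), cfg$annotation$n_tes)
  expect_true(all(ann$genes$start >= 1 & ann$genes$end <= lens[ann$genes$chrom]))
  expect_true(all(ann$tes$start >= 1 & ann$tes$end <= lens[ann$tes$chrom]))
  expect_true(all(ann$cds$start >= ann$genes$start[
    match(ann$cds$gene_id, ann$genes$gene_id)]))
  expect_true(all(ann$tes$te_class %in%
                    names(cfg$annotation$te_class_probs)))

  # overlap fraction: count TEs overlapping genic regions (body +/- 2 kb)
  genic <- genic_region(ann$genes, lengths = lens)
  gr_genic <- GenomicRanges::GRanges(genic$chrom,
    IRanges::IRanges(genic$region_start, genic$region_end))
  gr_te <- GenomicRanges::GRanges(ann$tes$chrom,
    IRanges::IRanges(ann$tes$start, ann$tes$end))
  n_over <- sum(IRanges::overlapsAny(gr_te, gr_genic))
  expect_equal(n_over,
               round(cfg$annotation$te_overlap_fraction * cfg$annotation$n_tes))

  cfg0 <- sim_config(seed = 4, annotation = list(te_overlap_fraction = 0))
  ann0 <- gen_annotation(gen_genome(cfg0), cfg0)
  gr_body0 <- GenomicRanges::GRanges(ann0$genes$chrom,
    IRanges::IRanges(ann0$genes$start, ann0$genes$end))
  gr_te0 <- GenomicRanges::GRanges(ann0$tes$chrom,
    IRanges::IRanges(ann0$tes$start, ann0$tes$end))
  expect_equal(sum(IRanges::overlapsAny(gr_te0, gr_body0)), 0L)
})

test_that("planted truth satisfies its structural invariants", {
  sim <- get_study()
  tr <- sim$truth
  expect_true(all(tr$planted_dmrs$n_sites >= 5))
  for (ctx in unique(tr$planted_dmrs$context)) {
    iv <- unique(tr$planted_dmrs[tr$planted_dmrs$context == ctx,
                                 c("chrom", "start", "end")])
    by_chr <- split(iv[order(iv$start), ], iv$chrom[order(iv$start)])
    for (x in by_chr) {
      if (nrow(x) > 1) expect_true(all(x$start[-1] > x$end[-nrow(x)]))
    }
  }
  expect_true(all(tr$planted_epiregs$dmr_id %in% tr$planted_dmrs$dmr_id))
  expect_true(all(tr$planted_epiregs$gene_id %in% sim$annotation$genes$gene_id))
  expect_true(all(tr$variance_components >= 0))
  # promoter DMRs carry only the eligible contexts
  epi <- tr$planted_dmrs[tr$planted_dmrs$kind == "epireg", ]
  expect_true(all(epi$context %in% c("CG", "CHG")))
})

test_that("methylome counts follow the planted signal and the conversion noise model", {
  # conversion 1, true ML 0 everywhere -> zero methylated reads
  cfg <- small_config(seed = 21,
                      methylome = list(baseline_ml = c(CG = 0, CHG = 0, CHH = 0),
                                       baseline_concentration = Inf,
                                       conversion_rate = 1),
                      dmr = list(n_per_context = 0L),
                      epireg = list(n_negative = 0L, n_positive = 0L))
  rep0 <- gen_methylome(gen_genome(cfg), NULL, cfg, conditions = "A")$A
  expect_equal(sum(rep0$meth), 0L)

  # conversion 0.99, true ML 0 -> methylated-read fraction ~ 0.01
  cfg2 <- small_config(seed = 22,
                       methylome = list(baseline_ml = c(CG = 0, CHG = 0, CHH = 0),
                                        baseline_concentration = Inf,
                                        conversion_rate = 0.99),
                       dmr = list(n_per_context = 0L),
                       epireg = list(n_negative = 0L, n_positive = 0L))
  rep2 <- gen_methylome(gen_genome(cfg2), NULL, cfg2, conditions = "A")$A
  expect_gt(sum(rep2$total), 1e5)   # enough reads for a tight frequency check
  expect_lt(abs(sum(rep2$meth) / sum(rep2$total) - 0.01), 0.002)

  # planted delta recovers as an observed ML difference
  sim <- get_study()
  pd <- sim$truth$planted_dmrs
  bg <- pd[pd$kind == "background" & pd$condition == "HS", ][1, ]
  a <- sim$methylomes$LS; b <- sim$methylomes$HS
  idx <- a$chrom == bg$chrom & a$pos >= bg$start & a$pos <= bg$end &
    a$context == bg$context & a$total > 0 & b$total > 0
  dml <- mean(b$meth[idx] / b$total[idx]) - mean(a$meth[idx] / a$total[idx])
  expect_lt(abs(dml - bg$delta), 0.1)

  # a planted delta that leaves [0,1] is rejected
  expect_error(sim_config(seed = 1, dmr = list(delta = 0.95, low_ml = 0.2)),
               "outside")
})

test_that("expression matrices carry the planted fold-changes and stay internally consistent", {
  sim <- get_study()
  ex <- sim$expression
  samples <- ex$samples
  cond_of <- function(m, cond) rowMeans(m[, samples$sample[samples$condition == cond]])

  pd <- sim$truth$planted_degs
  planted_hl <- pd[pd$condition == "HL", ]
  mr <- cond_of(ex$counts, "HL") / cond_of(ex$counts, "LS")
  for (i in seq_len(nrow(planted_hl))) {
    expect_lt(abs(log2(mr[planted_hl$gene_id[i]]) - planted_hl$log2fc[i]), 1)
  }
  # non-planted genes share means across conditions
  null_genes <- setdiff(rownames(ex$counts), planted_hl$gene_id)
  expect_lt(max(abs(log2(mr[null_genes]))), 1)

  # epireg genes with a hyper promoter DMR in HL are down in HL
  neg <- sim$truth$planted_epiregs
  neg <- neg$gene_id[neg$sign == "negative"]
  expect_true(all(cond_of(ex$fpkm, "HL")[neg] < cond_of(ex$fpkm, "LS")[neg]))

  # FPKM consistent with counts, lengths, library sizes
  recomputed <- ex$counts / (ex$gene_lengths / 1e3) /
    rep(ex$library_sizes / 1e6, each = nrow(ex$counts))
  expect_equal(ex$fpkm, recomputed)
})

test_that("phenotype tables are balanced, bounded and variance-faithful", {
  cfg <- sim_config(seed = 31, phenotype = list(varieties = 20L, years = 3L))
  g <- gen_genome(cfg); ann <- gen_annotation(g, cfg)
  tr <- gen_truth(g, ann, cfg)
  pf <- gen_phenotype(cfg, tr, "field")
  expect_equal(nrow(pf), 20 * 3 * 2 * 3)
  expect_true(all(pf$pnpf >= 0 & pf$pnpf <= 1))
  expect_equal(length(unique(table(pf$accession, pf$year, pf$season))), 1L)

  # all variance components zero and no seasonal decrease -> constant PNPF
  cfg0 <- sim_config(seed = 32, phenotype = list(
    varieties = 5L, years = 2L, decrease_fraction = 0,
    variance_components = c(year = 0, variety = 0, season_year = 0,
                            year_variety = 0, season_year_variety = 0,
                            residual = 0)))
  pf0 <- gen_phenotype(cfg0, NULL, "field")
  expect_equal(length(unique(pf0$pnpf)), 1L)

  # dominant variety variance dominates the SS decomposition
  cfgv <- sim_config(seed = 33, phenotype = list(
    varieties = 30L, years = 3L, decrease_fraction = 0,
    variance_components = c(year = 1e-4, variety = 0.3, season_year = 1e-4,
                            year_variety = 1e-4, season_year_variety = 1e-4,
                            residual = 1e-3)))
  gv <- gen_genome(cfgv); av <- gen_annotation(gv, cfgv)
  tv <- gen_truth(gv, av, cfgv)
  at <- nested_anova(gen_phenotype(cfgv, tv, "field"))
  comp <- at[at$source != "Total", ]
  expect_equal(comp$source[which.max(comp$ss)], "Variety")
})
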