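test_that("context classification follows the plant CG/CHG/CHH rules on both strands", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AACGTACAGTCATTCCANTA"))
  #                                  123456789012345678
  expect_equal(classify_context(g, "chr1", 3, "+"), "CG")   # C G
  expect_equal(classify_context(g, "chr1", 7, "+"), "CHG")  # C A G
  expect_equal(classify_context(g, "chr1", 11, "+"), "CHH") # C A T
  expect_equal(classify_context(g, "chr1", 15, "+"), "CHH") # C C A
  # non-C base on the requested strand
  expect_true(is.na(classify_context(g, "chr1", 2, "+")))
  # N in the trinucleotide
  expect_true(is.na(classify_context(g, "chr1", 16, "+")))
  # out of bounds
  expect_error(classify_context(g, "chr1", 0, "+"))
  expect_error(classify_context(g, "chr1", 99, "+"))
  expect_error(classify_context(g, "chrX", 3, "+"))

  # minus strand agrees with classifying the reverse complement, for
  # every possible downstream dinucleotide
  bases <- c("A", "C", "G", "T")
  for (d1 in bases) for (d2 in bases) {
    # minus-strand C at position 3; its 5'->3' downstream bases on the
    # minus strand (d1, d2) sit at plus positions 2 and 1, complemented
    s <- paste0(chartr("ACGT", "TGCA", d2), chartr("ACGT", "TGCA", d1),
                "G", "ATAT")
    fwd <- Biostrings::DNAStringSet(stats::setNames(s, "chr1"))
    rc <- Biostrings::DNAStringSet(stats::setNames(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
      "chr1"))
    got <- classify_context(fwd, "chr1", 3, "-")
    want <- classify_context(rc, "chr1", nchar(s) - 2, "+")
    expect_identical(got, want)
  }
})

test_that("cytosine_map agrees with per-site classification", {
  cfg <- sim_config(seed = 5, genome = list(n_chrom = 1L, length = 20000L))
  g <- gen_genome(cfg)
  cmap <- cytosine_map(g)
  expect_true(all(cmap$context %in% c("CG", "CHG", "CHH")))
  idx <- seq(1, nrow(cmap), length.out = 50)
  for (i in idx) {
    expect_identical(classify_context(g, cmap$chrom[i], cmap$pos[i],
                                      cmap$strand[i]),
                     cmap$context[i])
  }
})

test_that("min_meth_reads is the smallest count clearing the conversion-noise tail", {
  expect_equal(min_meth_reads(10, 0.01, 0.05), 2L)
  expect_equal(min_meth_reads(10, 0, 0.05), 1L)
  expect_true(is.na(min_meth_reads(0, 0.01, 0.05)))
  expect_error(min_meth_reads(10, 0.01, alpha = 1.5))
  expect_error(min_meth_reads(10, 1, 0.05))

  # brute-force tail sums over a coverage/error grid
  for (n in c(1, 5, 20, 60)) for (e in c(0.002, 0.01, 0.05)) {
    k <- min_meth_reads(n, e, 0.05)
    tail_at <- function(kk) sum(dbinom(kk:n, n, e))
    if (!is.na(k)) {
      expect_lt(tail_at(k), 0.05)
      if (k > 1) expect_gte(tail_at(k - 1), 0.05)
    }
  }
})

test_that("methylcytosine calls and levels follow the binomial gate", {
  rep <- toy_report(pos = c(10, 20, 30, 40), meth = c(2, 1, 0, 5),
                    total = c(10, 10, 12, 0))
  mc <- call_mc(rep, conversion_rate = 0.99, alpha = 0.05)
  expect_equal(mc$is_mc, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(site_ml(rep$meth, rep$total)[1:3], c(0.2, 0.1, 0))
  expect_true(is.na(site_ml(5, 0)))
  expect_error(call_mc(rep, conversion_rate = 0))

  # false-mC rate stays below alpha at every coverage when true ML is 0
  set.seed(42)
  for (cov in c(5, 15, 40)) {
    n <- 20000
    meth <- rbinom(n, cov, 0.01)
    r <- data.frame(meth = meth, total = cov)
    expect_lt(mean(call_mc(r, 0.99, 0.05)$is_mc), 0.05)
  }
})

test_that("context summaries and increment rates aggregate correctly", {
  rep <- toy_report(pos = c(1, 2, 3, 4, 5, 6),
                    meth = c(10, 0, 10, 0, 3, 0),
                    total = c(10, 10, 10, 10, 10, 0),
                    context = c("CG", "CG", "CG", "CG", "CHH", "CHG"))
  cs <- context_summary(rep, conversion_rate = 1)
  cg <- cs[cs$context == "CG", ]
  expect_equal(cg$mean_ml, 0.5)
  expect_equal(cg$n_mc, 2L)        # conversion 1: any methylated read
  expect_equal(cg$mc_over_c, 0.5)
  expect_true(is.na(cs$mean_ml[cs$context == "CHG"]))  # uncovered
  expect_equal(cs$n_covered[cs$context == "all"], 5L)

  expect_equal(increment_rate(0.275, 0.2), 0.375)

  empty <- context_summary(toy_report(1, 0, 10)[0, ])
  expect_true(all(is.na(empty$mean_ml)))
})

test_that("DmC calling applies the Fisher and delta gates with direction symmetry", {
  mk <- function(meth, total) toy_report(pos = seq_along(meth), meth = meth,
                                         total = total)
  # equal proportions: no call
  expect_equal(nrow(call_dmcs(mk(5, 10), mk(5, 10), min_coverage = 1)), 0L)
  # total separation: called, extreme p
  d <- call_dmcs(mk(20, 20), mk(0, 20), min_coverage = 1)
  expect_equal(nrow(d), 1L)
  expect_equal(d$delta, -1)
  expect_equal(d$direction, "hypo")
  expect_lt(d$p, 1e-10)
  # delta 0.2 but p = 0.58: rejected by the Fisher gate
  expect_equal(nrow(call_dmcs(mk(9, 10), mk(7, 10), min_coverage = 1)), 0L)
  # coverage floor removes sites (4/4 vs 0/4 is significant: p = 2/70)
  expect_equal(nrow(call_dmcs(mk(4, 4), mk(0, 4), min_coverage = 5)), 0L)
  expect_equal(nrow(call_dmcs(mk(4, 4), mk(0, 4), min_coverage = 4)), 1L)
  # key mismatch is an error
  a <- mk(5, 10); b <- mk(5, 10); b$pos <- b$pos + 1
  expect_error(call_dmcs(a, b), "keys")

  # symmetry: same p, opposite direction
  set.seed(9)
  for (i in 1:25) {
    ta <- sample(4:30, 1); tb <- sample(4:30, 1)
    ra <- mk(sample(0:ta, 1), ta); rb <- mk(sample(0:tb, 1), tb)
    ab <- call_dmcs(ra, rb); ba <- call_dmcs(rb, ra)
    expect_equal(nrow(ab), nrow(ba))
    if (nrow(ab)) {
      expect_equal(ab$p, ba$p)
      expect_equal(ab$delta, -ba$delta)
      expect_false(ab$direction == ba$direction)
    }
  }
})

test_that("report round trip preserves the cytosine table", {
  sim <- simulate_study(small_config(seed = 55))
  rep <- sim$methylomes$LS
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cytosine_report(rep, f)
  back <- read_cytosine_report(f)
  expect_equal(back, rep[, names(back)], ignore_attr = TRUE)
})

test_that("annotation GFF3 round trip preserves genes, CDS and TEs", {
  sim <- simulate_study(small_config(seed = 56))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(sim$annotation, f)
  back <- read_annotation_gff3(f)
  expect_equal(back$genes, sim$annotation$genes, ignore_attr = TRUE)
  expect_equal(back$tes, sim$annotation$tes, ignore_attr = TRUE)
  expect_equal(back$cds[order(back$cds$gene_id, back$cds$start), ],
               sim$annotation$cds[order(sim$annotation$cds$gene_id,
                                        sim$annotation$cds$start), ],
               ignore_attr = TRUE)
})
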