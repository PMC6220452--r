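#' Run the whole synthetic-data generator
#'
#' Generates genome, annotation, truth, the four-condition methylomes,
#' the expression matrices and both phenotype tables in one call, and
#' optionally writes everything to disk (FASTA, GFF3, cytosine-report
#' TSVs, expression TSVs, phenotype CSVs and one TSV per truth class).
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; created if missing.
#' @return List: `genome`, `annotation`, `truth`, `methylomes` (named
#'   list of cytosine reports), `expression`, `phenotype_field`,
#'   `phenotype_incubator`, `config`.
#' @examples
#' \donttest{
#' sim <- simulate_study(sim_config(seed = 1,
#'   genome = list(n_chrom = 1, length = 50000)))
#' }
#' @export
simulate_study <- function(config, outdir = NULL) {
  genome <- gen_genome(config)
  annotation <- gen_annotation(genome, config)
  cmap <- cytosine_map(genome)
  truth <- gen_truth(genome, annotation, config, cmap = cmap)
  methylomes <- gen_methylome(genome, truth, config, cmap = cmap)
  expression <- gen_expression(annotation, truth, config)
  pheno_field <- gen_phenotype(config, truth, "field")
  pheno_inc <- gen_phenotype(config, truth, "incubator")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_genome_fasta(genome, file.path(outdir, "genome.fa"))
    write_annotation_gff3(annotation, file.path(outdir, "annotation.gff3"))
    for (cond in names(methylomes)) {
      write_cytosine_report(methylomes[[cond]],
        file.path(outdir, paste0("cytosine_report_", cond, ".tsv")))
    }
    write_expression(expression, file.path(outdir, "expression"))
    write_phenotype_csv(pheno_field, file.path(outdir, "phenotype_field.csv"))
    write_phenotype_csv(pheno_inc, file.path(outdir, "phenotype_incubator.csv"))
    for (nm in c("planted_dmrs", "planted_degs", "planted_epiregs",
                 "planted_dets", "seasonal")) {
      write.table(truth[[nm]], file.path(outdir, paste0("truth_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  list(genome = genome, annotation = annotation, truth = truth,
       methylomes = methylomes, expression = expression,
       phenotype_field = pheno_field, phenotype_incubator = pheno_inc,
       config = config)
}
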