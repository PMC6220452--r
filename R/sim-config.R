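#' Simulation configuration
#'
#' Builds the configuration object that drives every synthetic-data
#' generator. The defaults describe the study conditions the pipeline is
#' exercised under: a small two-chromosome plant-like genome, plant-typical
#' context-specific baseline methylation (CG high, CHG intermediate, CHH
#' low), overdispersed whole-genome bisulfite coverage with imperfect
#' bisulfite conversion, a four-condition (LS/LL/HS/HL) expression design
#' with three replicates, and the balanced multi-year two-season germplasm
#' phenotype design whose degrees of freedom match the published field
#' survey (359 varieties x 5 years x 2 seasons x 3 replicates).
#'
#' @param seed Integer seed; fixes every downstream draw bit-for-bit.
#' @param ... Named overrides for any top-level section. Each section is a
#'   list; supplied elements are merged over the defaults with
#'   [utils::modifyList()].
#'
#' @return A classed list (`sim_config`) with sections `genome`,
#'   `annotation`, `methylome`, `dmr`, `epireg`, `expression`, `phenotype`.
#'
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$methylome$conversion_rate
#' cfg <- sim_config(seed = 1, genome = list(n_chrom = 1, length = 50000))
#' @export
sim_config <- function(seed = 1L, ...) {
  defaults <- list(
    genome = list(
      n_chrom = 2L,
      length = 400000L,      # per chromosome, bp
      gc = 0.37              # plant-like GC fraction
    ),
    annotation = list(
      n_genes = 100L,
      n_tes = 80L,
      gene_length = c(1500L, 3500L),
      te_length = c(300L, 2000L),
      n_exons = c(2L, 4L),
      # LTR-dominated class mix followed by unknown and LINE, as in
      # typical plant TE landscapes
      te_class_probs = c(LTR = 0.40, unknown = 0.25, LINE = 0.15,
                         DNA = 0.15, SINE = 0.05),
      te_overlap_fraction = 0.3  # fraction of TEs overlapping genic regions
    ),
    methylome = list(
      baseline_ml = c(CG = 0.80, CHG = 0.55, CHH = 0.10),
      baseline_concentration = 30, # Beta concentration of per-site true ML
      coverage_mean = 30,
      coverage_size = 10,          # negative-binomial size (overdispersion)
      conversion_rate = 0.99
    ),
    dmr = list(
      n_per_context = 6L,        # planted per context per treatment
      shared_fraction = 0.5,     # fraction planted identically in LL/HS/HL
      span = 150L,               # bp
      delta = 0.8,               # |ML difference|
      min_sites = 8L,
      p_hyper = 0.7,             # hypermethylation predominates
      low_ml = 0.1,              # baseline inside planted regions
      gap = 500L                 # minimum spacing between planted regions
    ),
    epireg = list(
      n_negative = 12L,          # promoter hyper + expression down
      n_positive = 6L,           # promoter hyper + expression up (control)
      delta = 0.5,
      log2fc = 2,
      span = 150L,
      min_sites = 8L,
      condition = "HL"           # treatment carrying the coupling (vs LS)
    ),
    expression = list(
      n_reps = 3L,
      meanlog = 4.3, sdlog = 1,  # log-normal baseline mean counts
      nb_size = 300,             # replicate dispersion (tight triplicates)
      n_degs = 16L,
      deg_log2fc = 3,
      deg_condition = "HL",      # planted DEGs shift in this condition
      min_base_count = 75,       # planted features must be expressed
      max_base_quantile = 0.9,   # ... but not extreme-abundance outliers
      # unmodelled remainder of the transcriptome entering the library
      # size (the gene/TE panel is a small mass fraction of a real
      # library, as DEGs are of a real transcriptome)
      background_mean = 1e6, background_size = 100,
      te_meanlog = 3, te_sdlog = 1,
      n_dets = 8L,
      det_log2fc = 3
    ),
    phenotype = list(
      varieties = 359L, years = 5L, seasons = 2L, reps = 3L,
      mu = asin(sqrt(0.35)),     # grand mean on the arcsine scale
      variance_components = c(year = 4e-4, variety = 0.09,
                              season_year = 2.5e-3, year_variety = 5e-3,
                              season_year_variety = 5e-3,
                              residual = 1e-3),
      decrease_fraction = 0.9,   # accessions with a true autumn decrease
      decrease_effect = 0.25,    # arcsine-scale autumn drop for those
      incubator = list(
        varieties = 4L, reps = 3L,
        variety_sd = 0.45, temp_effect = -0.14, photo_effect = -0.17,
        vt_sd = 0.08, vp_sd = 0.06, tp_effect = -0.06, vtp_sd = 0.02,
        resid_sd = 0.06
      )
    )
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (nm in names(overrides)) {
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], as.list(overrides[[nm]]))
  }
  cfg <- c(list(seed = as.integer(seed)), defaults)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  g <- cfg$genome
  if (g$n_chrom < 1L || any(g$length <= 0)) stop("genome lengths must be positive")
  if (any(g$length < 10000L)) stop("chromosome lengths must be at least 10 kb")
  if (g$gc <= 0 || g$gc >= 1) stop("GC fraction must lie in (0,1)")
  m <- cfg$methylome
  if (any(m$baseline_ml < 0 | m$baseline_ml > 1))
    stop("baseline methylation levels must lie in [0,1]")
  if (!all(CONTEXTS %in% names(m$baseline_ml)))
    stop("baseline_ml must name CG, CHG and CHH")
  if (m$conversion_rate <= 0 || m$conversion_rate > 1)
    stop("bisulfite conversion rate must lie in (0,1]")
  if (m$coverage_mean < 0 || m$coverage_size <= 0)
    stop("coverage distribution parameters out of range")
  for (side in c("dmr", "epireg")) {
    d <- cfg[[side]]
    if (d$delta <= 0 || d$delta > 1) stop(side, "$delta must lie in (0,1]")
  }
  if (cfg$dmr$low_ml + cfg$dmr$delta > 1)
    stop("planted delta pushes methylation level outside [0,1]")
  if (cfg$expression$n_reps < 2L) stop("need at least 2 replicates per condition")
  p <- cfg$phenotype
  if (any(p$variance_components < 0)) stop("variance components must be >= 0")
  if (p$seasons != 2L) stop("the phenotype design has two seasons (spring, early autumn)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed =", x$seed, "\n")
  cat("  genome:    ", x$genome$n_chrom, "chromosome(s) x", x$genome$length,
      "bp, GC", x$genome$gc, "\n")
  cat("  methylome:  coverage ~NB(mean", x$methylome$coverage_mean, ", size",
      x$methylome$coverage_size, "), conversion", x$methylome$conversion_rate, "\n")
  cat("  planted:   ", x$dmr$n_per_context, "DMRs/context/treatment,",
      x$expression$n_degs, "DEGs,", x$epireg$n_negative, "negative +",
      x$epireg$n_positive, "positive epiregulation couplings\n")
  cat("  phenotype: ", x$phenotype$varieties, "varieties x", x$phenotype$years,
      "years x 2 seasons x", x$phenotype$reps, "reps\n")
  invisible(x)
}
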