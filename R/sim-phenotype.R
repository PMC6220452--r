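#' Simulate PNPF phenotype tables
#'
#' PNPF (proportion of nodes with pistillate flowers among the first 25
#' main-stem nodes) is generated on the arcsine scale, where the
#' downstream ANOVA assumptions hold exactly: the response is the grand
#' mean plus independent normal effects drawn from the configured
#' variance components (year, variety, season-within-year, the two
#' interactions, residual), plus a fixed early-autumn decrease for the
#' accessions the truth table marks as season-sensitive. Values are
#' clamped to `[0, pi/2]` and back-transformed with `sin(x)^2`.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [gen_truth()] (uses `seasonal`); may be
#'   `NULL`, in which case no accession carries a seasonal decrease.
#' @param design `"field"` for the multi-year two-season germplasm
#'   survey, `"incubator"` for the 4-variety x temperature x photoperiod
#'   experiment.
#' @return data.frame. Field: accession, year, season
#'   (spring/early_autumn), rep, pnpf. Incubator: accession, condition
#'   (LS/LL/HS/HL), temperature, photoperiod, rep, pnpf.
#' @export
gen_phenotype <- function(config, truth = NULL,
                          design = c("field", "incubator")) {
  design <- match.arg(design)
  ph <- config$phenotype
  set.seed(stage_seed(config$seed, "phenotype") + (design == "incubator"))
  if (design == "field") gen_phenotype_field(ph, truth)
  else gen_phenotype_incubator(ph$incubator)
}

gen_phenotype_field <- function(ph, truth) {
  vc <- ph$variance_components
  years <- seq_len(ph$years) + 2009L
  seasons <- c("spring", "early_autumn")
  acc <- sprintf("acc%03d", seq_len(ph$varieties))
  tab <- expand.grid(rep = seq_len(ph$reps), season = seasons, year = years,
                     accession = acc, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  tab <- tab[, c("accession", "year", "season", "rep")]

  eff <- function(keys, sd) {
    keys <- as.character(keys)
    u <- unique(keys)
    unname(stats::setNames(rnorm(length(u), 0, sd), u)[keys])
  }
  z <- ph$mu +
    eff(tab$year, sqrt(vc[["year"]])) +
    eff(tab$accession, sqrt(vc[["variety"]])) +
    eff(paste(tab$year, tab$season), sqrt(vc[["season_year"]])) +
    eff(paste(tab$year, tab$accession), sqrt(vc[["year_variety"]])) +
    eff(paste(tab$year, tab$season, tab$accession),
        sqrt(vc[["season_year_variety"]])) +
    rnorm(nrow(tab), 0, sqrt(vc[["residual"]]))

  sensitive <- if (is.null(truth)) rep(FALSE, length(acc)) else
    stats::setNames(truth$seasonal$sensitive, truth$seasonal$accession)[tab$accession]
  z <- z - ifelse(tab$season == "early_autumn" & sensitive,
                  ph$decrease_effect, 0)
  tab$pnpf <- sin(pmin(pi / 2, pmax(0, z)))^2
  rownames(tab) <- NULL
  tab
}

gen_phenotype_incubator <- function(inc) {
  acc <- c("9930", sprintf("ST%d", 359:361))[seq_len(inc$varieties)]
  tab <- expand.grid(rep = seq_len(inc$reps), photoperiod = c("S", "L"),
                     temperature = c("L", "H"), accession = acc,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tab <- tab[, c("accession", "temperature", "photoperiod", "rep")]
  tab$condition <- paste0(tab$temperature, tab$photoperiod)

  v_eff <- stats::setNames(rnorm(length(acc), 0, inc$variety_sd), acc)
  vt <- stats::setNames(rnorm(2 * length(acc), 0, inc$vt_sd),
                        as.vector(outer(acc, c("L", "H"), paste)))
  vp <- stats::setNames(rnorm(2 * length(acc), 0, inc$vp_sd),
                        as.vector(outer(acc, c("S", "L"), paste)))
  vtp <- stats::setNames(rnorm(4 * length(acc), 0, inc$vtp_sd),
                         as.vector(outer(acc, c("LS", "LL", "HS", "HL"), paste)))
  z <- asin(sqrt(0.4)) + v_eff[tab$accession] +
    ifelse(tab$temperature == "H", inc$temp_effect, 0) +
    ifelse(tab$photoperiod == "L", inc$photo_effect, 0) +
    vt[paste(tab$accession, tab$temperature)] +
    vp[paste(tab$accession, tab$photoperiod)] +
    ifelse(tab$temperature == "H" & tab$photoperiod == "L", inc$tp_effect, 0) +
    vtp[paste(tab$accession, tab$condition)] +
    rnorm(nrow(tab), 0, inc$resid_sd)
  tab$pnpf <- sin(pmin(pi / 2, pmax(0, z)))^2
  rownames(tab) <- NULL
  tab
}

#' Write a phenotype table as CSV
#' @param table data.frame from [gen_phenotype()].
#' @param path Output file.
#' @export
write_phenotype_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
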