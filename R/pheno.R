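#' Proportion of nodes with pistillate flowers
#'
#' The femaleness measure: the number of nodes bearing pistillate
#' flowers among the first `max_node` (25) main-stem nodes, divided by
#' `max_node`.
#'
#' @param node Integer node indices observed.
#' @param pistillate Logical flags, same length.
#' @param max_node Denominator and node cutoff.
#' @return Proportion in `[0,1]`; `NA` with no node records.
#' @export
pnpf <- function(node, pistillate, max_node = 25L) {
  if (!length(node)) return(NA_real_)
  sum(pistillate[node <= max_node]) / max_node
}

#' Classify a cucumber sex type from spring PNPF
#'
#' Subandroecy below 25%, normal monoecy from 25% up to (excluding)
#' 75%, gynoecy/subgynoecy at 75% and above.
#' @param pnpf_spring Numeric in `[0,1]` (vectorised).
#' @return Character vector of sex types.
#' @export
classify_sex_type <- function(pnpf_spring) {
  if (any(pnpf_spring < 0 | pnpf_spring > 1, na.rm = TRUE))
    stop("PNPF must lie in [0,1]")
  ifelse(pnpf_spring < 0.25, "subandroecy",
    ifelse(pnpf_spring < 0.75, "normal monoecy", "gynoecy/subgynoecy"))
}

#' Arcsine square-root transformation
#'
#' `asin(sqrt(p))`: the variance-stabilising transform applied to PNPF
#' proportions before parametric testing.
#' @param p Proportions in `[0,1]`.
#' @return Values in `[0, pi/2]`.
#' @export
arcsine_transform <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("proportions must lie in [0,1]")
  asin(sqrt(p))
}

#' Per-accession seasonal change summary
#'
#' For every accession: mean spring and early-autumn PNPF, the relative
#' decrease, and a two-sample t-test (Welch by default) on the
#' arcsine-transformed values; plus germplasm-level counts of
#' accessions with a significant decrease and with a relative decrease
#' beyond `decrease_threshold`, and the linear fit of autumn on spring
#' means.
#'
#' @param table Field phenotype table (accession, season, pnpf; seasons
#'   `spring` / `early_autumn`).
#' @param alpha t-test significance threshold.
#' @param decrease_threshold Relative-decrease cutoff (0.4 = 40%).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return List: `per_accession` (accession, mean_spring, mean_autumn,
#'   relative_decrease, p, testable), `counts` (n_accessions,
#'   n_significant_decrease, n_large_decrease), `fit` (slope,
#'   intercept, r).
#' @export
seasonal_change_summary <- function(table, alpha = 0.05,
                                    decrease_threshold = 0.4,
                                    var_equal = FALSE) {
  per <- lapply(split(table, table$accession), function(x) {
    sp <- x$pnpf[x$season == "spring"]
    au <- x$pnpf[x$season == "early_autumn"]
    # accessions stuck at a constant PNPF (notably subandroecy lines
    # clamped near 0) cannot be tested
    testable <- length(sp) >= 2L && length(au) >= 2L &&
      (stats::var(arcsine_transform(sp)) + stats::var(arcsine_transform(au))) > 0
    p <- if (testable)
      t.test(arcsine_transform(sp), arcsine_transform(au),
             var.equal = var_equal)$p.value else NA_real_
    data.frame(accession = x$accession[1], mean_spring = mean(sp),
               mean_autumn = mean(au),
               relative_decrease = (mean(sp) - mean(au)) / mean(sp),
               p = p, testable = testable)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  sig_dec <- per$testable & per$p < alpha & per$mean_autumn < per$mean_spring
  fit <- lm(mean_autumn ~ mean_spring, data = per)
  list(per_accession = per,
       counts = c(n_accessions = nrow(per),
                  n_significant_decrease = sum(sig_dec, na.rm = TRUE),
                  n_large_decrease =
                    sum(per$relative_decrease > decrease_threshold, na.rm = TRUE)),
       fit = c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
               r = cor(per$mean_spring, per$mean_autumn)))
}

#' Nested ANOVA of the multi-year field survey
#'
#' Classical fixed-effects sums-of-squares decomposition of the
#' arcsine-transformed PNPF with season nested in year: Year, Variety,
#' Season(Year), Year x Variety, Season(Year) x Variety, Residual.
#' Computed directly from balanced group means (on a balanced design
#' all classical SS types coincide), so it handles the full
#' 359-variety x 5-year table that a dense model-matrix fit cannot.
#' F statistics test every term against the residual mean square.
#'
#' @param table Field table (accession, year, season, pnpf), balanced.
#' @param transform Apply [arcsine_transform()] to the response.
#' @return An ANOVA table data.frame: source, df, ss, ms, f, p,
#'   tss_pct; rows ordered as the classical field table plus Residual
#'   and Total.
#' @export
nested_anova <- function(table, transform = TRUE) {
  y <- if (transform) arcsine_transform(table$pnpf) else table$pnpf
  yr <- factor(table$year); se <- factor(table$season)
  va <- factor(table$accession)
  cell <- table(yr, se, va)
  if (length(unique(as.vector(cell))) != 1L || any(cell == 0))
    stop("nested_anova requires a balanced design ",
         "(every year x season x variety cell equally replicated)")
  n <- length(y)
  gm <- mean(y)
  mean_by <- function(...) tapply(y, list(...), mean)
  m_y <- mean_by(yr); m_v <- mean_by(va)
  m_ys <- mean_by(yr, se); m_yv <- mean_by(yr, va)
  m_ysv <- mean_by(yr, se, va)
  r <- unique(as.vector(cell))
  ny <- nlevels(yr); ns <- nlevels(se); nv <- nlevels(va)

  ss_year <- ns * nv * r * sum((m_y - gm)^2)
  ss_var <- ny * ns * r * sum((m_v - gm)^2)
  ss_sy <- nv * r * sum((m_ys - as.numeric(m_y[rownames(m_ys)]))^2)
  dev_yv <- sweep(sweep(m_yv, 1, m_y), 2, m_v) + gm
  ss_yv <- ns * r * sum(dev_yv^2)
  dev_ysv <- m_ysv
  for (i in seq_len(ny)) for (j in seq_len(ns))
    dev_ysv[i, j, ] <- m_ysv[i, j, ] - m_ys[i, j] - m_yv[i, ] + m_y[i]
  ss_syv <- r * sum(dev_ysv^2)
  fitted <- m_ysv[cbind(as.integer(yr), as.integer(se), as.integer(va))]
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - gm)^2)

  df <- c(ny - 1, nv - 1, ny * (ns - 1), (ny - 1) * (nv - 1),
          ny * (ns - 1) * (nv - 1))
  df_res <- n - 1 - sum(df)
  build_anova_table(
    sources = c("Year", "Variety", "Season (Year)", "Year x Variety",
                "Season (Year) x Variety"),
    ss = c(ss_year, ss_var, ss_sy, ss_yv, ss_syv),
    df = df, ss_res = ss_res, df_res = df_res, ss_tot = ss_tot, n = n)
}

#' Factorial ANOVA of the incubator experiment
#'
#' Full three-way fixed-effects decomposition (variety x temperature x
#' photoperiod with replicates) of the arcsine-transformed PNPF,
#' computed with [stats::aov()]; sequential SS coincide with all
#' classical types on the balanced design.
#'
#' @param table Incubator table (accession, temperature, photoperiod,
#'   pnpf), balanced with replicates.
#' @param transform Apply [arcsine_transform()].
#' @return ANOVA table data.frame as in [nested_anova()].
#' @export
factorial_anova <- function(table, transform = TRUE) {
  y <- if (transform) arcsine_transform(table$pnpf) else table$pnpf
  v <- factor(table$accession); t <- factor(table$temperature)
  p <- factor(table$photoperiod)
  cell <- table(v, t, p)
  if (any(cell == 0)) stop("missing cells in the factorial design")
  if (length(unique(as.vector(cell))) != 1L)
    stop("factorial_anova requires a balanced design")
  fit <- aov(y ~ v * t * p)
  sm <- summary(fit)[[1]]
  rn <- trimws(rownames(sm))
  pick <- function(term) which(rn == term)
  ord <- c("v", "t", "p", "v:t", "v:p", "t:p", "v:t:p")
  labels <- c("Variety", "Temperature", "Photoperiod", "Variety x Temp",
              "Variety x Photo", "Temp x Photo", "Variety x Temp x Photo")
  idx <- vapply(ord, pick, integer(1))
  res_i <- which(rn == "Residuals")
  build_anova_table(sources = labels, ss = sm$`Sum Sq`[idx],
                    df = sm$Df[idx], ss_res = sm$`Sum Sq`[res_i],
                    df_res = sm$Df[res_i],
                    ss_tot = sum(sm$`Sum Sq`), n = length(y))
}

build_anova_table <- function(sources, ss, df, ss_res, df_res, ss_tot, n) {
  ms <- ss / df
  ms_res <- ss_res / df_res
  f <- ms / ms_res
  p <- pf(f, df, df_res, lower.tail = FALSE)
  out <- data.frame(
    source = c(sources, "Residual", "Total"),
    df = c(df, df_res, n - 1),
    ss = c(ss, ss_res, ss_tot),
    ms = c(ms, ms_res, NA),
    f = c(f, NA, NA),
    p = c(p, NA, NA),
    tss_pct = 100 * c(ss, ss_res, ss_tot) / ss_tot)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Finish an ANOVA table from raw SS and df
#'
#' Fills MS = SS/df and TSS% = 100 SS / total SS at the printed
#' precision of the published tables (MS to 3 decimals; TSS% to 2
#' decimals for the field survey, 3 for the two-factor experiment).
#' Useful for recomputing the derived cells of a published ANOVA
#' skeleton.
#'
#' @param source Row names.
#' @param df,ss Degrees of freedom and sums of squares.
#' @param total_ss Total SS (defaults to `sum(ss)`).
#' @param ms_digits,tss_digits Rounding.
#' @return data.frame: source, df, ss, ms, tss_pct.
#' @examples
#' finalize_table("Variety", 358, 295.00, total_ss = 625.60)
#' @export
finalize_table <- function(source, df, ss, total_ss = sum(ss),
                           ms_digits = 3, tss_digits = 2) {
  if (any(df <= 0) || any(ss < 0)) stop("df must be positive and SS >= 0")
  if (total_ss <= 0) stop("total SS must be positive")
  data.frame(source = source, df = df, ss = ss,
             ms = round(ss / df, ms_digits),
             tss_pct = round(100 * ss / total_ss, tss_digits))
}

#' @export
print.anova_table <- function(x, ...) {
  y <- as.data.frame(x)
  for (cl in intersect(c("ss", "ms", "f"), names(y)))
    y[[cl]] <- signif(y[[cl]], 4)
  if ("p" %in% names(y)) y$p <- signif(y$p, 3)
  if ("tss_pct" %in% names(y)) y$tss_pct <- round(y$tss_pct, 2)
  print(y, row.names = FALSE)
  invisible(x)
}
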