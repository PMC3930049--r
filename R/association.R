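#' Linear-model test of MHC polymorphism against bacterial richness
#'
#' Ordinary least-squares simple regression of per-population percent
#' amino-acid polymorphism on per-population species richness, tested by
#' ANOVA: `F = MS_regression / MS_residual` with `(1, n - 2)` degrees of
#' freedom and a two-sided p-value. For simple regression `F` equals the
#' square of the slope t-statistic.
#'
#' @param polymorphism numeric vector of percent polymorphic codons, one
#'   value per population.
#' @param rich numeric vector of species richness, same populations.
#' @return list of class `assoc_result`: `slope`, `F`, `df_num`,
#'   `df_den`, `P`, `r2`, `n`.
#' @examples
#' fit_assoc(c(20, 24, 22, 30, 28, 26, 21, 25, 27), c(0:3, 1:3, 2, 1))
#' @export
fit_assoc <- function(polymorphism, rich) {
  stopifnot(length(polymorphism) == length(rich))
  ok <- is.finite(polymorphism) & is.finite(rich)
  y <- polymorphism[ok]; x <- rich[ok]
  n <- length(y)
  if (n < 4L) stop("need paired observations for >= 4 populations",
                   call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in richness", call. = FALSE)
  if (stats::var(y) == 0) {
    warning("zero variance in polymorphism; F = 0")
    return(structure(list(slope = 0, F = 0, df_num = 1L, df_den = n - 2L,
                          P = 1, r2 = 0, n = n), class = "assoc_result"))
  }
  fit <- stats::lm(y ~ x)
  an <- stats::anova(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 F = an$`F value`[1L], df_num = an$Df[1L],
                 df_den = an$Df[2L], P = an$`Pr(>F)`[1L],
                 r2 = summary(fit)$r.squared, n = n),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("Association: F(%d, %d) = %.3f, P = %.4g (slope %.4g, R2 %.3f, n = %d)\n",
              x$df_num, x$df_den, x$F, x$P, x$slope, x$r2, x$n))
  invisible(x)
}

#' Full locus x partition x richness association grid
#'
#' Fits [fit_assoc()] for every combination of locus, codon partition
#' (PBR, non-PBR) and richness partition (all, nonpathogen, pathogen),
#' mirroring the general-linear-model summary table of pooled MHC
#' surveys. No multiple-testing correction is applied across cells (the
#' customary presentation); a Bonferroni-adjusted column is emitted for
#' transparency.
#'
#' @param poly named list: locus -> data.frame from
#'   [percent_polymorphic_by_pop()].
#' @param tab a [flag_pathogens()] community table covering the same
#'   populations.
#' @return data.frame with one row per cell: locus, codon_partition,
#'   richness_partition, slope, F, df_num, df_den, P, P_bonferroni,
#'   significant.
#' @export
assoc_grid <- function(poly, tab) {
  stopifnot(is.list(poly), inherits(tab, "community_table"))
  rich <- list(all = richness(tab, "all"),
               nonpathogen = richness(tab, "nonpathogen"),
               pathogen = richness(tab, "pathogen"))
  rows <- list()
  for (locus in names(poly)) {
    pp <- poly[[locus]]
    for (cp in c("PBR", "non-PBR")) {
      y <- if (cp == "PBR") pp$pct_pbr else pp$pct_nonpbr
      names(y) <- pp$population
      for (rp in names(rich)) {
        x <- rich[[rp]][pp$population]
        res <- fit_assoc(y, x)
        rows[[length(rows) + 1L]] <- data.frame(
          locus = locus, codon_partition = cp, richness_partition = rp,
          slope = res$slope, F = res$F, df_num = res$df_num,
          df_den = res$df_den, P = res$P, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$P_bonferroni <- pmin(1, out$P * nrow(out))
  out$significant <- out$P < 0.05
  out
}
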