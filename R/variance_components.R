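# One-way CRD ANOVA and genetic-parameter estimators.
#
# Model: y_ij = mu + g_i + e_ij, i = 1..g genotypes, j = 1..k replicates.
# On the mean-square scale, E[QMg] = k*sigma2_g + sigma2_e and
# E[QMr] = sigma2_e, which gives the moment estimators below.

#' One-way ANOVA for a completely randomized design
#'
#' Fits the genotype model for one trait of a balanced [phenotype_table()]
#' and returns mean squares, the F test and significance stars
#' (`**` p <= 0.01, `*` 0.01 < p <= 0.05, `ns` otherwise). Cells with
#' missing values are dropped first; if that leaves the trait unbalanced,
#' an error is raised rather than silently approximating.
#'
#' @param tab a [phenotype_table()].
#' @param trait trait label to analyse.
#' @return An object of class `anova_crd`: list with `trait`, `QMg`,
#'   `QMr`, `df_g`, `df_r`, `F`, `p`, `signif`, `grand_mean`, `k`,
#'   `n_genotypes`.
#' @export
anova_crd <- function(tab, trait) {
  stopifnot(inherits(tab, "phenotype_table"))
  k <- replicates_per_genotype(tab, trait)
  sub <- tab[tab$trait == trait & !is.na(tab$value), , drop = FALSE]
  sub$genotype <- factor(sub$genotype)
  g <- nlevels(sub$genotype)
  if (g < 2) stop("need at least 2 genotypes for trait ", trait)
  if (g * (k - 1) < 1) stop("zero residual degrees of freedom for trait ", trait)
  fit <- stats::lm(value ~ genotype, data = sub)
  an <- stats::anova(fit)
  p <- an[["Pr(>F)"]][1]
  structure(list(trait = trait,
                 QMg = an[["Mean Sq"]][1], QMr = an[["Mean Sq"]][2],
                 df_g = an[["Df"]][1], df_r = an[["Df"]][2],
                 F = an[["F value"]][1], p = p,
                 signif = if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns",
                 grand_mean = mean(sub$value), k = k, n_genotypes = g),
            class = "anova_crd")
}

#' Genetic parameters from ANOVA mean squares
#'
#' Moment estimators for a balanced one-way design with k replicates:
#' phenotypic variance of genotype means `Vf = QMg/k`, environmental
#' variance `Ve = QMr/k`, genetic variance `Vg = (QMg - QMr)/k` truncated
#' at 0, broad-sense repeatability `h2 = 100 * Vg/Vf` (percent, in
#' \[0, 100\]), coefficient of genetic variation
#' `CVg = 100 * sqrt(Vg)/mean`, coefficient of environmental variation
#' `CVe = 100 * sqrt(QMr)/mean` (the residual SD of single observations,
#' which is also the experimental CV), and the ratio `CVg/CVe`
#' (equivalently `sqrt(Vg/QMr)`; the grand mean cancels).
#'
#' The untruncated genetic variance is kept in `Vg_raw` for diagnostics.
#' When the grand mean is 0 the CV terms are undefined and returned `NA`.
#'
#' @param QMg genotype mean square, or an `anova_crd` object (then `QMr`,
#'   `k` and `grand_mean` are taken from it).
#' @param QMr residual mean square.
#' @param k number of replicates, >= 2.
#' @param grand_mean trait grand mean (needed for the CV terms).
#' @param trait optional trait label carried through.
#' @return data.frame (one row) with columns `trait`, `Vf`, `Ve`, `Vg`,
#'   `Vg_raw`, `h2_pct`, `CVg_pct`, `CVe_pct`, `ratio`, `CV_pct`.
#' @export
#' @examples
#' # mean germination time of the reference trial: h2 = 96.20%
#' genetic_parameters(QMg = 2.37, QMr = 0.09, k = 4, grand_mean = 6)
genetic_parameters <- function(QMg, QMr = NULL, k = NULL, grand_mean = NA,
                               trait = NA_character_) {
  if (inherits(QMg, "anova_crd")) {
    a <- QMg
    QMg <- a$QMg; QMr <- a$QMr
    if (is.null(k)) k <- a$k
    grand_mean <- a$grand_mean; trait <- a$trait
  }
  if (is.null(k) || k < 2) stop("k must be >= 2")
  if (QMg < 0 || QMr < 0) stop("mean squares must be non-negative")
  vf <- QMg / k
  ve <- QMr / k
  vg_raw <- (QMg - QMr) / k
  vg <- max(0, vg_raw)
  h2 <- if (vf > 0) 100 * vg / vf else 0
  if (!is.na(grand_mean) && grand_mean == 0) {
    cvg <- cve <- NA_real_
  } else {
    cvg <- 100 * sqrt(vg) / grand_mean
    cve <- 100 * sqrt(QMr) / grand_mean
  }
  ratio <- if (QMr > 0) sqrt(vg / QMr) else if (vg == 0) 0 else Inf
  data.frame(trait = trait, Vf = vf, Ve = ve, Vg = vg, Vg_raw = vg_raw,
             h2_pct = h2, CVg_pct = cvg, CVe_pct = cve, ratio = ratio,
             CV_pct = cve, stringsAsFactors = FALSE)
}

#' Per-trait ANOVA and genetic parameters for a whole table
#'
#' Runs [anova_crd()] and [genetic_parameters()] for every trait of a
#' phenotype table and binds the results.
#'
#' @param tab a [phenotype_table()].
#' @return data.frame with one row per trait: mean squares, F, p,
#'   significance stars and all genetic parameters.
#' @export
genetic_parameters_table <- function(tab) {
  stopifnot(inherits(tab, "phenotype_table"))
  traits <- unique(tab$trait)
  rows <- lapply(traits, function(tr) {
    a <- anova_crd(tab, tr)
    gp <- genetic_parameters(a)
    cbind(data.frame(trait = tr, QMg = a$QMg, QMr = a$QMr, df_g = a$df_g,
                     df_r = a$df_r, F = a$F, p = a$p, signif = a$signif,
                     grand_mean = a$grand_mean, stringsAsFactors = FALSE),
          gp[, setdiff(names(gp), "trait"), drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.anova_crd <- function(x, ...) {
  cat("One-way CRD ANOVA:", x$trait, "\n")
  cat(sprintf("  genotypes: %d, replicates: %d\n", x$n_genotypes, x$k))
  cat(sprintf("  QMg = %.4f (df %d), QMr = %.4f (df %d)\n",
              x$QMg, x$df_g, x$QMr, x$df_r))
  cat(sprintf("  F = %.3f, p = %.4g %s\n", x$F, x$p, x$signif))
  invisible(x)
}
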