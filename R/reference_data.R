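#' Published mean squares for the beach mandacaru trial
#'
#' Per-trait genotype and residual mean squares, F-test significance codes
#' and experimental coefficients of variation from a published completely
#' randomized trial of 20 *Cereus fernambucensis* (beach mandacaru)
#' subpopulations with four replicates, covering 15 traits of plants,
#' fruits, seeds and seedlings. These summary statistics are the canonical
#' worked input for [genetic_parameters()] and the source of the default
#' trait panel of [default_simulation_config()].
#'
#' Trait codes: PH plant height (cm), CD cladode diameter (cm), NR number
#' of ribs, FL fruit length (mm), FD fruit diameter (mm), FFM fruit fresh
#' mass (g), NS seeds per fruit, TSM thousand-seed mass (g), G germination
#' percentage, GSI germination speed index, MGT mean germination time
#' (days), SL seedling length (cm), SDM seedling dry mass (mg), DEN
#' biomass density (mg/cm), SVI seed vigor index.
#'
#' @return A data.frame with columns `trait`, `QMg`, `QMr`, `signif`
#'   (`**`, `*` or `ns`) and `CV_pct`.
#' @export
#' @examples
#' ms <- cereus_mean_squares()
#' genetic_parameters(ms$QMg[ms$trait == "MGT"], ms$QMr[ms$trait == "MGT"], k = 4)
cereus_mean_squares <- function() {
  path <- system.file("extdata", "cereus_mean_squares.csv", package = "phenodiv",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
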