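# Validated long-format containers used throughout the pipeline.

#' Construct and validate a phenotype table
#'
#' Long-format balanced trial data: one row per genotype x replicate x
#' trait. The design must be balanced: every genotype carries the same
#' number of replicates `k` for every trait it was scored on. Missing
#' cells are permitted only as absent rows (they are excluded trait-wise,
#' with balance re-checked per trait at analysis time).
#'
#' @param df data.frame with columns `genotype`, `replicate`, `trait`,
#'   `value`.
#' @return `df` with class `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  need <- c("genotype", "replicate", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(df$value)) stop("value column must be numeric")
  key <- paste(df$genotype, df$replicate, df$trait)
  if (anyDuplicated(key)) stop("duplicated genotype x replicate x trait cells")
  df$genotype <- as.character(df$genotype)
  df$trait <- as.character(df$trait)
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Replicates per genotype of one trait, asserting balance
#'
#' @param tab a [phenotype_table()].
#' @param trait trait label.
#' @return the common replicate count k (>= 2).
#' @keywords internal
replicates_per_genotype <- function(tab, trait) {
  sub <- tab[tab$trait == trait & !is.na(tab$value), , drop = FALSE]
  if (!nrow(sub)) stop("no observations for trait ", trait)
  counts <- table(sub$genotype)
  if (length(unique(as.integer(counts))) != 1L)
    stop("unbalanced data for trait ", trait,
         ": replicate counts range ", min(counts), "-", max(counts))
  k <- as.integer(counts[1])
  if (k < 2) stop("trait ", trait, " has fewer than 2 replicates per genotype")
  k
}

#' Construct and validate a germination time course
#'
#' One row per genotype x replicate x day, with `count` the number of
#' seeds newly germinated on that day (incremental, not cumulative) and
#' `seeds_sown` the replicate's lot size. Counts must be non-negative and
#' sum to at most `seeds_sown` within each replicate.
#'
#' @param df data.frame with columns `genotype`, `replicate`, `day`,
#'   `count`, `seeds_sown`.
#' @return `df` with class `germination_course`.
#' @export
germination_course <- function(df) {
  need <- c("genotype", "replicate", "day", "count", "seeds_sown")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("germination course lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$day < 1) || any(df$day != as.integer(df$day)))
    stop("days must be positive integers")
  if (any(df$count < 0)) stop("negative germination counts")
  if (any(df$seeds_sown <= 0)) stop("seeds_sown must be positive")
  tot <- stats::aggregate(count ~ genotype + replicate + seeds_sown, df, sum)
  bad <- tot$count > tot$seeds_sown
  if (any(bad))
    stop("germinated counts exceed seeds sown for ",
         paste(tot$genotype[bad], tot$replicate[bad], sep = "/", collapse = ", "))
  df$genotype <- as.character(df$genotype)
  class(df) <- c("germination_course", "data.frame")
  df
}

#' Genotype x trait matrix of means from a phenotype table
#'
#' @param tab a [phenotype_table()].
#' @return numeric matrix, genotypes in rows (sorted labels), traits in
#'   columns.
#' @export
genotype_means <- function(tab) {
  stopifnot(inherits(tab, "phenotype_table"))
  ag <- stats::aggregate(value ~ genotype + trait, tab, mean)
  genos <- sort(unique(ag$genotype))
  traits <- unique(tab$trait)
  m <- matrix(NA_real_, length(genos), length(traits),
              dimnames = list(genos, traits))
  m[cbind(match(ag$genotype, genos), match(ag$trait, traits))] <- ag$value
  m
}
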