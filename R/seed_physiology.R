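# Physical and physiological seed/seedling indices.
#
# All per-replicate indices are computed from the daily germination counts
# (newly germinated seeds per day) or seedling measurements; replicate
# remains the analysis unit, so nothing is averaged across replicates here.

#' Thousand-seed weight
#'
#' `TSW = W * 1000 / N` for a weighed sample of N seeds.
#'
#' @param sample_weight_g total weight of the sample, g.
#' @param sample_count number of seeds in the sample.
#' @return weight of 1000 seeds, g.
#' @export
thousand_seed_weight <- function(sample_weight_g, sample_count) {
  if (any(sample_count <= 0)) stop("sample_count must be positive")
  if (any(sample_weight_g <= 0)) stop("sample_weight_g must be positive")
  sample_weight_g * 1000 / sample_count
}

#' Germination percentage
#'
#' `G% = 100 * Ng / Nt` with `Ng` the total germinated and `Nt` seeds sown.
#'
#' @param counts integer vector of daily counts of newly germinated seeds.
#' @param seeds_sown seeds placed to germinate, > 0.
#' @return percentage in \[0, 100\].
#' @export
germination_percentage <- function(counts, seeds_sown) {
  if (seeds_sown <= 0) stop("seeds_sown must be positive")
  ng <- sum(counts)
  if (ng > seeds_sown) stop("germinated count exceeds seeds sown")
  100 * ng / seeds_sown
}

#' Germination speed index (Maguire)
#'
#' `GSI = sum(G_i / N_i)` over daily counts, with `N_i` the day number
#' counted from sowing.
#'
#' @param counts daily counts of newly germinated seeds.
#' @param days day numbers (from sowing) matching `counts`; defaults to
#'   `seq_along(counts)`.
#' @return the index (seeds/day-weighted); 0 when nothing germinated.
#' @export
germination_speed_index <- function(counts, days = seq_along(counts)) {
  if (length(counts) != length(days)) stop("counts and days differ in length")
  if (any(days < 1)) stop("days must be >= 1")
  sum(counts / days)
}

#' Mean germination time
#'
#' `MGT = sum(G_i * N_i) / sum(G_i)`, in days. Undefined when no seed
#' germinated; `NA` is returned then (a 0 or Inf placeholder would bias
#' genotype means), and such cells are dropped from downstream ANOVA with
#' a warning.
#'
#' @inheritParams germination_speed_index
#' @return mean day of germination, or `NA_real_` if no germination.
#' @export
mean_germination_time <- function(counts, days = seq_along(counts)) {
  if (length(counts) != length(days)) stop("counts and days differ in length")
  ng <- sum(counts)
  if (ng == 0) return(NA_real_)
  sum(counts * days) / ng
}

#' Seedling biomass density
#'
#' `DEN = SDM / SL`, mg of dry mass per cm of seedling.
#'
#' @param sdm_mg seedling dry mass, mg.
#' @param sl_cm seedling length, cm, > 0.
#' @return density in mg/cm.
#' @export
biomass_density <- function(sdm_mg, sl_cm) {
  if (any(sl_cm <= 0)) stop("seedling length must be positive")
  sdm_mg / sl_cm
}

#' Seed vigor index
#'
#' `SVI = G% x SL`, combining germination percentage and seedling length.
#'
#' @param g_pct germination percentage.
#' @param sl_cm seedling length, cm.
#' @return the index.
#' @export
seed_vigor_index <- function(g_pct, sl_cm) g_pct * sl_cm

#' Per-replicate germination indices from a time course
#'
#' Computes G%, GSI and MGT for every genotype x replicate of a
#' [germination_course()] and returns them as a long [phenotype_table()]
#' ready for ANOVA — one value per genotype x replicate per index, never
#' averaged across replicates.
#'
#' @param course a [germination_course()].
#' @return a `phenotype_table` with traits `G`, `GSI`, `MGT`; MGT cells
#'   with zero germination are `NA` (warned about).
#' @export
germination_traits <- function(course) {
  stopifnot(inherits(course, "germination_course"))
  sp <- split(course, paste(course$genotype, course$replicate, sep = "\r"))
  rows <- lapply(sp, function(d) {
    data.frame(genotype = d$genotype[1], replicate = d$replicate[1],
               trait = c("G", "GSI", "MGT"),
               value = c(germination_percentage(d$count, d$seeds_sown[1]),
                         germination_speed_index(d$count, d$day),
                         mean_germination_time(d$count, d$day)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_na <- sum(is.na(out$value[out$trait == "MGT"]))
  if (n_na > 0)
    warning(n_na, " replicate(s) had no germination; their MGT is missing ",
            "and will be excluded from that trait's ANOVA")
  phenotype_table(out)
}
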