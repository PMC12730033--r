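# Synthetic balanced-trial generator with known ground truth.
#
# The generator emulates the structure of a germplasm characterization
# trial: a completely randomized design with g genotypes (subpopulations)
# and k replicates, an additive two-component model per trait
#   y_ij = mu + g_i + e_ij,   g_i ~ N(0, sigma2_g),  e_ij ~ N(0, sigma2_e),
# plus a germination time course per genotype x replicate (seeds sown,
# daily counts of newly germinated seeds up to a fixed window).

#' Specify one simulated trait
#'
#' @param name trait label.
#' @param mean grand mean, in trait units.
#' @param sigma2_g genotype (between-subpopulation) variance, >= 0.
#' @param sigma2_e residual variance, > 0.
#' @param direction `"higher_is_better"` or `"lower_is_better"`; used when
#'   building an ideotype from simulated data.
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, mean, sigma2_g, sigma2_e,
                       direction = c("higher_is_better", "lower_is_better")) {
  direction <- match.arg(direction)
  if (!is.numeric(sigma2_g) || sigma2_g < 0) stop("sigma2_g must be >= 0")
  if (!is.numeric(sigma2_e) || sigma2_e <= 0) stop("sigma2_e must be > 0")
  structure(list(name = as.character(name), mean = mean,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 direction = direction),
            class = "trait_spec")
}

#' Specify the germination-course model
#'
#' Each genotype draws a germination probability (varied on the logit
#' scale, so it stays in (0,1)) and a mean germination time; each seed of a
#' replicate then germinates independently with that probability, on a day
#' drawn from a rounded normal clamped below at day 1. Seeds whose drawn
#' day exceeds `n_days` are censored (never counted), as are non-germinating
#' seeds.
#'
#' @param seeds_per_replicate seeds sown per replicate (default 50).
#' @param n_days length of the daily-count window in days (default 21).
#' @param p_germ_mean mean germination probability across genotypes.
#' @param p_germ_genotype_sd genotype SD of germination probability, on the
#'   logit scale.
#' @param time_mean mean germination day across genotypes.
#' @param time_sd within-genotype SD of the germination day (days).
#' @param time_genotype_sd genotype SD of the mean germination day (days).
#' @return A `germination_model` list.
#' @export
germination_model <- function(seeds_per_replicate = 50, n_days = 21,
                              p_germ_mean = 0.95, p_germ_genotype_sd = 0.5,
                              time_mean = 6, time_sd = 1.5,
                              time_genotype_sd = 0.75) {
  if (p_germ_mean <= 0 || p_germ_mean >= 1) stop("p_germ_mean must lie in (0,1)")
  if (n_days < 1) stop("n_days must be >= 1")
  if (seeds_per_replicate < 1) stop("seeds_per_replicate must be >= 1")
  structure(list(seeds_per_replicate = as.integer(seeds_per_replicate),
                 n_days = as.integer(n_days),
                 p_germ_mean = p_germ_mean,
                 p_germ_genotype_sd = p_germ_genotype_sd,
                 time_mean = time_mean, time_sd = time_sd,
                 time_genotype_sd = time_genotype_sd),
            class = "germination_model")
}

#' Assemble a simulation configuration
#'
#' @param n_genotypes number of genotypes (subpopulations), >= 2.
#' @param n_replicates replicates per genotype (k), >= 2.
#' @param traits list of [trait_spec()] objects.
#' @param germination a [germination_model()].
#' @param rng_seed integer seed; the sole source of randomness.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genotypes, n_replicates, traits,
                              germination = germination_model(),
                              rng_seed = 1L) {
  if (n_genotypes < 2) stop("n_genotypes must be >= 2")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (!length(traits)) stop("at least one trait_spec is required")
  if (!all(vapply(traits, inherits, TRUE, "trait_spec")))
    stop("traits must be a list of trait_spec objects")
  nm <- vapply(traits, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("trait names must be unique")
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_replicates = as.integer(n_replicates),
                 traits = traits, germination = germination,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

#' Default simulation configuration mirroring the beach mandacaru trial
#'
#' The trait panel reproduces the study conditions of the reference trial:
#' 20 genotypes, 4 replicates, 15 traits whose genotype and residual
#' variances are back-solved from the published mean squares
#' ([cereus_mean_squares()]): `sigma2_e = QMr`,
#' `sigma2_g = max(0, (QMg - QMr)/k)`, and grand means from
#' `CV% = 100 * sqrt(QMr) / mean`. Mean germination time is the one
#' lower-is-better trait. The germination model uses 50 seeds per
#' replicate counted over 21 days with probability and timing centred on
#' the panel's G and MGT values.
#'
#' @param rng_seed integer seed.
#' @return A `simulation_config`.
#' @export
default_simulation_config <- function(rng_seed = 1L) {
  ms <- cereus_mean_squares()
  k <- 4
  traits <- lapply(seq_len(nrow(ms)), function(i) {
    trait_spec(name = ms$trait[i],
               mean = 100 * sqrt(ms$QMr[i]) / ms$CV_pct[i],
               sigma2_g = max(0, (ms$QMg[i] - ms$QMr[i]) / k),
               sigma2_e = ms$QMr[i],
               direction = if (ms$trait[i] == "MGT") "lower_is_better"
                           else "higher_is_better")
  })
  simulation_config(n_genotypes = 20, n_replicates = 4, traits = traits,
                    germination = germination_model(), rng_seed = rng_seed)
}

#' Simulate a balanced multi-trait phenotype table
#'
#' Draws `y_ij = mean + g_i + e_ij` per trait with independent normal
#' genotype and residual effects, balanced over replicates. Reproducible
#' for a fixed `rng_seed`; a single RNG stream is used per call.
#'
#' @param config a [simulation_config()].
#' @return A long-format data.frame (`genotype`, `replicate`, `trait`,
#'   `value`) of class `phenotype_table` — see [phenotype_table()].
#' @export
simulate_trait_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  g <- config$n_genotypes
  k <- config$n_replicates
  geno <- sprintf("G%02d", seq_len(g))
  out <- vector("list", length(config$traits))
  for (t in seq_along(config$traits)) {
    ts <- config$traits[[t]]
    gi <- stats::rnorm(g, 0, sqrt(ts$sigma2_g))
    e <- stats::rnorm(g * k, 0, sqrt(ts$sigma2_e))
    out[[t]] <- data.frame(
      genotype = rep(geno, each = k),
      replicate = rep(seq_len(k), times = g),
      trait = ts$name,
      value = ts$mean + rep(gi, each = k) + e,
      stringsAsFactors = FALSE)
  }
  phenotype_table(do.call(rbind, out))
}

#' Simulate germination time courses
#'
#' Per genotype, a germination probability (logit-normal around
#' `p_germ_mean`) and a mean germination day are drawn; per replicate each
#' seed germinates independently with that probability, on a day equal to
#' a normal draw rounded half-up and clamped below at 1. Seeds whose drawn
#' day exceeds the counting window are censored. Daily counts of newly
#' germinated seeds are returned.
#'
#' @param config a [simulation_config()].
#' @return A data.frame (`genotype`, `replicate`, `day`, `count`,
#'   `seeds_sown`) of class `germination_course`, one row per
#'   genotype x replicate x day with `day` in `1:n_days`.
#' @export
simulate_germination <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  gm <- config$germination
  # offset so trait-table and germination draws come from one seeded stream
  # but do not overlap run-to-run for the same seed
  set.seed(config$rng_seed + 1L)
  g <- config$n_genotypes
  k <- config$n_replicates
  geno <- sprintf("G%02d", seq_len(g))
  p_i <- stats::plogis(stats::qlogis(gm$p_germ_mean) +
                         stats::rnorm(g, 0, gm$p_germ_genotype_sd))
  t_i <- gm$time_mean + stats::rnorm(g, 0, gm$time_genotype_sd)
  rows <- vector("list", g * k)
  idx <- 0L
  for (i in seq_len(g)) {
    for (r in seq_len(k)) {
      n <- gm$seeds_per_replicate
      germ <- stats::runif(n) < p_i[i]
      day <- floor(stats::rnorm(n, t_i[i], gm$time_sd) + 0.5)  # round half-up
      day <- pmax(day, 1L)
      counted <- germ & day <= gm$n_days
      counts <- tabulate(day[counted], nbins = gm$n_days)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(genotype = geno[i], replicate = r,
                                day = seq_len(gm$n_days), count = counts,
                                seeds_sown = n, stringsAsFactors = FALSE)
    }
  }
  germination_course(do.call(rbind, rows))
}

#' Ground-truth genetic parameters of a simulation configuration
#'
#' Closed-form truths implied by the trait specifications: phenotypic
#' variance of genotype means `sigma2_g + sigma2_e/k`, broad-sense
#' repeatability `h2 = sigma2_g / (sigma2_g + sigma2_e/k)`, and the
#' coefficients of genetic and environmental variation.
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `trait`, `mean`, `sigma2_g`, `sigma2_e`,
#'   `h2_pct`, `CVg_pct`, `CVe_pct`, `ratio`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  k <- config$n_replicates
  do.call(rbind, lapply(config$traits, function(ts) {
    vf <- ts$sigma2_g + ts$sigma2_e / k
    cvg <- 100 * sqrt(ts$sigma2_g) / ts$mean
    cve <- 100 * sqrt(ts$sigma2_e) / ts$mean
    data.frame(trait = ts$name, mean = ts$mean,
               sigma2_g = ts$sigma2_g, sigma2_e = ts$sigma2_e,
               h2_pct = 100 * ts$sigma2_g / vf,
               CVg_pct = cvg, CVe_pct = cve,
               ratio = if (cve > 0) cvg / cve else 0,
               stringsAsFactors = FALSE)
  }))
}
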