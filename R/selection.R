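# Genotype-ideotype distance selection index.

#' Specify an ideotype
#'
#' Per trait: a desired direction (`"higher_is_better"` or
#' `"lower_is_better"`), an optional explicit target value on the raw
#' trait scale (overriding the observed optimum), and an optional
#' non-negative weight (default 1).
#'
#' @param directions named character vector, one entry per analysed trait.
#' @param targets optional named numeric vector of explicit raw-scale
#'   targets for a subset of traits.
#' @param weights optional named numeric vector of non-negative weights.
#' @return An `ideotype_spec` list.
#' @export
ideotype_spec <- function(directions, targets = NULL, weights = NULL) {
  ok <- directions %in% c("higher_is_better", "lower_is_better")
  if (!all(ok)) stop("directions must be higher_is_better or lower_is_better")
  if (is.null(names(directions))) stop("directions must be named by trait")
  if (!is.null(weights) && any(weights < 0)) stop("weights must be >= 0")
  structure(list(directions = directions, targets = targets,
                 weights = weights),
            class = "ideotype_spec")
}

#' Build the ideotype vector on the standardized scale
#'
#' Per trait, the best observed genotype mean in the desired direction
#' (the column maximum for higher-is-better traits, the minimum otherwise)
#' unless an explicit raw-scale target was supplied, which is standardized
#' with the trait's observed mean and SD.
#'
#' @param means genotype x trait matrix of raw means.
#' @param spec an [ideotype_spec()]; traits missing from it default to
#'   higher-is-better with weight 1.
#' @return named numeric vector (standardized scale), one entry per trait
#'   column of `means`.
#' @export
build_ideotype <- function(means, spec) {
  stopifnot(inherits(spec, "ideotype_spec"))
  means <- as.matrix(means)
  Z <- standardize_means(means)
  traits <- colnames(means)
  ideo <- vapply(traits, function(tr) {
    if (!is.null(spec$targets) && tr %in% names(spec$targets))
      return((spec$targets[[tr]] - mean(means[, tr])) / stats::sd(means[, tr]))
    dir <- if (tr %in% names(spec$directions)) spec$directions[[tr]]
           else "higher_is_better"
    if (dir == "higher_is_better") max(Z[, tr]) else min(Z[, tr])
  }, numeric(1))
  names(ideo) <- traits
  ideo
}

#' Genotype-ideotype distance index
#'
#' Ranks genotypes by their weighted Euclidean distance, on the
#' standardized trait scale, to the ideotype of [build_ideotype()]. Rank 1
#' is the genotype closest to the ideotype; the first `n_sel` ranks form
#' the selected set. Ties are broken by genotype label.
#'
#' @param means genotype x trait matrix of raw means.
#' @param spec an [ideotype_spec()].
#' @param n_sel number of genotypes to select; default 30% of the
#'   genotypes (rounded, at least 1).
#' @return An object of class `selection_result`: data.frame with columns
#'   `genotype`, `distance`, `rank`, `selected`, plus attributes
#'   `ideotype` and `n_sel`.
#' @export
genotype_ideotype_index <- function(means, spec,
                                    n_sel = max(1, round(0.3 * nrow(means)))) {
  means <- as.matrix(means)
  if (n_sel < 1 || n_sel > nrow(means)) stop("n_sel out of range")
  Z <- standardize_means(means)
  ideo <- build_ideotype(means, spec)
  w <- rep(1, ncol(means))
  names(w) <- colnames(means)
  if (!is.null(spec$weights)) w[names(spec$weights)] <- spec$weights
  dist2 <- colSums(w * (t(Z) - ideo)^2)
  ord <- order(dist2, rownames(means))
  out <- data.frame(genotype = rownames(means)[ord],
                    distance = sqrt(dist2[ord]),
                    rank = seq_len(nrow(means)),
                    selected = seq_len(nrow(means)) <= n_sel,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ideotype") <- ideo
  attr(out, "n_sel") <- n_sel
  class(out) <- c("selection_result", "data.frame")
  out
}
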