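# Genotype x genotype dissimilarity matrices: generalized Mahalanobis D2
# (genotype mean differences in the metric of the inverse pooled residual
# covariance) and standardized Euclidean distances.

#' Standardize a genotype x trait matrix of means
#'
#' Centers and scales every trait column to mean 0 and sample variance 1
#' (denominator n - 1), the usual preprocessing before multivariate
#' divergence procedures.
#'
#' @param means numeric matrix, genotypes x traits.
#' @return matrix of the same shape.
#' @export
standardize_means <- function(means) {
  means <- as.matrix(means)
  sds <- apply(means, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trait column(s): ",
         paste(colnames(means)[sds == 0], collapse = ", "))
  scale(means)[, , drop = FALSE]
}

#' Pooled residual covariance across traits
#'
#' Within-genotype centered cross-products summed over genotypes and
#' divided by the residual degrees of freedom g(k - 1). The diagonal
#' equals each trait's residual mean square QMr. Rows (genotype x
#' replicate) missing any trait are dropped with a message.
#'
#' @param tab a [phenotype_table()] covering >= 1 trait.
#' @return An object of class `pooled_covariance`: list with `Sigma`
#'   (trait x trait matrix), `df_r`, `k` (replicates of the balanced
#'   design), `n_dropped`.
#' @export
pooled_residual_covariance <- function(tab) {
  stopifnot(inherits(tab, "phenotype_table"))
  wide <- stats::reshape(as.data.frame(tab), idvar = c("genotype", "replicate"),
                         timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  traits <- setdiff(names(wide), c("genotype", "replicate"))
  cc <- stats::complete.cases(wide[, traits, drop = FALSE])
  n_dropped <- sum(!cc)
  if (n_dropped > 0)
    message(n_dropped, " genotype x replicate row(s) with missing traits ",
            "dropped from covariance estimation")
  wide <- wide[cc, , drop = FALSE]
  ks <- table(wide$genotype)
  if (any(ks < 2)) stop("every genotype needs >= 2 complete replicates")
  X <- as.matrix(wide[, traits, drop = FALSE])
  S <- matrix(0, length(traits), length(traits),
              dimnames = list(traits, traits))
  df_r <- 0L
  for (gname in names(ks)) {
    Xi <- X[wide$genotype == gname, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    S <- S + crossprod(Xi)
    df_r <- df_r + nrow(Xi) - 1L
  }
  structure(list(Sigma = S / df_r, df_r = df_r,
                 k = as.integer(ks[1]), n_dropped = n_dropped),
            class = "pooled_covariance")
}

# Invert a covariance matrix; pseudo-inverse (SVD) with a warning when the
# condition number exceeds 1e10.
safe_inverse <- function(W) {
  kap <- kappa(W, exact = TRUE)
  if (!is.finite(kap) || kap > 1e10) {
    warning("covariance matrix is near-singular (condition number ",
            format(kap, digits = 3), "); using the pseudo-inverse")
    s <- svd(W)
    pos <- s$d > max(s$d) * 1e-12
    return(s$v[, pos, drop = FALSE] %*%
             (t(s$u[, pos, drop = FALSE]) / s$d[pos]))
  }
  solve(W)
}

#' Generalized Mahalanobis distances between genotype means
#'
#' `D2(i, i') = d' W^-1 d` with `d` the trait-mean difference vector. By
#' default `W` is the pooled residual covariance divided by k — the
#' covariance of genotype means — so that the univariate D2 is on the same
#' scale as the ANOVA F statistic; set `scale_to_means = FALSE` to use the
#' raw residual covariance.
#'
#' @param means genotype x trait matrix of means.
#' @param pcov a [pooled_residual_covariance()] result, or a plain
#'   trait x trait covariance matrix (then used as `W` directly).
#' @param scale_to_means divide the pooled covariance by its k (default
#'   TRUE; ignored for a plain matrix).
#' @return symmetric genotype x genotype matrix of D2 values with
#'   attribute `metric = "mahalanobis_d2"`.
#' @export
mahalanobis_d2 <- function(means, pcov, scale_to_means = TRUE) {
  means <- as.matrix(means)
  if (inherits(pcov, "pooled_covariance")) {
    W <- pcov$Sigma
    if (scale_to_means) W <- W / pcov$k
  } else {
    W <- as.matrix(pcov)
  }
  if (ncol(means) != nrow(W)) stop("means and covariance dimensions disagree")
  Winv <- safe_inverse(W)
  n <- nrow(means)
  D <- matrix(0, n, n, dimnames = list(rownames(means), rownames(means)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- means[i, ] - means[j, ]
      D[i, j] <- D[j, i] <- drop(t(d) %*% Winv %*% d)
    }
  }
  attr(D, "metric") <- "mahalanobis_d2"
  D
}

#' Standardized Euclidean distances between genotype means
#'
#' Euclidean distance computed on trait columns standardized to mean 0 and
#' variance 1. The mean variant divides the squared distance by the number
#' of traits before the square root.
#'
#' @param means genotype x trait matrix of means.
#' @param mean_variant use the standardized *mean* Euclidean distance
#'   (default FALSE).
#' @return symmetric genotype x genotype distance matrix with attribute
#'   `metric` of `"std_euclidean"` or `"std_mean_euclidean"`.
#' @export
standardized_euclidean <- function(means, mean_variant = FALSE) {
  Z <- standardize_means(means)
  D <- as.matrix(stats::dist(Z))
  if (mean_variant) D <- D / sqrt(ncol(Z))
  attr(D, "metric") <- if (mean_variant) "std_mean_euclidean" else "std_euclidean"
  D
}
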