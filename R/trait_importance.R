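# Trait importance: Singh's relative contribution of each trait to the
# total Mahalanobis divergence, and canonical variate analysis.

#' Singh's relative trait contributions to total D2
#'
#' For every ordered genotype pair with mean-difference vector `d` and the
#' same `W^-1` used by [mahalanobis_d2()], the trait-j component of the
#' pair's D2 is `d_j * (W^-1 d)_j`; `S_j` accumulates this over all pairs,
#' so that `sum_j S_j` equals the sum of all pairwise D2 values exactly.
#' With correlated traits individual components can be negative; they are
#' reported signed (with a warning naming the traits), and percentages are
#' taken over the signed total. Flooring small negative components at zero
#' is a display concern left to the report layer.
#'
#' @inheritParams mahalanobis_d2
#' @return data.frame with columns `trait`, `S_j`, `percent` plus
#'   attribute `total_d2`.
#' @export
singh_contribution <- function(means, pcov, scale_to_means = TRUE) {
  means <- as.matrix(means)
  if (inherits(pcov, "pooled_covariance")) {
    W <- pcov$Sigma
    if (scale_to_means) W <- W / pcov$k
  } else {
    W <- as.matrix(pcov)
  }
  Winv <- safe_inverse(W)
  n <- nrow(means)
  p <- ncol(means)
  S <- numeric(p)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- means[i, ] - means[j, ]
      S <- S + d * drop(Winv %*% d)
    }
  }
  if (any(S < 0))
    warning("negative contribution component(s) for trait(s): ",
            paste(colnames(means)[S < 0], collapse = ", "))
  out <- data.frame(trait = colnames(means), S_j = S,
                    percent = 100 * S / sum(S), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "total_d2") <- sum(S)
  out
}

#' Canonical variate analysis of genotype means
#'
#' Solves the between/within eigenproblem `W^-1 B a = lambda a`, with `W`
#' the pooled within-genotype SSCP and `B` the between-genotype SSCP of
#' means scaled by the replicate count, through the symmetric Cholesky
#' reduction of `W` for numerical stability. Eigenvalues are sorted
#' descending; each variate's share of variation is its eigenvalue over
#' the eigenvalue sum. Genotype scores are the centered means projected on
#' the coefficient vectors, which are normalized so that `a' W a = 1`
#' (scores of distinct variates are uncorrelated in the within metric).
#' Signs follow the convention that each variate's largest-magnitude trait
#' coefficient is positive.
#'
#' @param tab a [phenotype_table()] with >= 2 traits scored on a balanced
#'   design.
#' @return An object of class `canonical_variates`: list with
#'   `eigenvalues`, `percent`, `cumulative`, `coefficients` (trait x
#'   variate), `scores` (genotype x variate).
#' @export
canonical_variates <- function(tab) {
  stopifnot(inherits(tab, "phenotype_table"))
  pcov <- pooled_residual_covariance(tab)
  M <- genotype_means(tab)
  M <- M[, colnames(pcov$Sigma), drop = FALSE]
  k <- pcov$k
  W <- pcov$Sigma * pcov$df_r          # within SSCP
  Mc <- sweep(M, 2, colMeans(M))
  B <- k * crossprod(Mc)               # between SSCP
  if (rcond(W) < 1e-12)
    stop("within-genotype covariance is singular (collinear traits); ",
         "canonical variates are undefined", call. = FALSE)
  R <- chol(W)
  Rinv <- backsolve(R, diag(ncol(W)))
  Msym <- t(Rinv) %*% B %*% Rinv
  Msym <- (Msym + t(Msym)) / 2
  eig <- eigen(Msym, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  A <- Rinv %*% eig$vectors            # a' W a = 1 by construction
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(A))) {
    i_max <- which.max(abs(A[, j]))
    if (A[i_max, j] < 0) A[, j] <- -A[, j]
  }
  dimnames(A) <- list(colnames(M), paste0("CV", seq_len(ncol(A))))
  scores <- Mc %*% A
  pct <- 100 * ev / sum(ev)
  structure(list(eigenvalues = ev, percent = pct, cumulative = cumsum(pct),
                 coefficients = A, scores = scores),
            class = "canonical_variates")
}

#' @export
print.canonical_variates <- function(x, ...) {
  cat("Canonical variates\n")
  print(data.frame(variate = seq_along(x$eigenvalues),
                   eigenvalue = round(x$eigenvalues, 4),
                   percent = round(x$percent, 2),
                   cumulative = round(x$cumulative, 2)), row.names = FALSE)
  invisible(x)
}
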