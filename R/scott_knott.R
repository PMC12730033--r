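# Scott-Knott partitioning of treatment means.
#
# The procedure sorts the genotype means and recursively looks for the
# contiguous split maximizing the between-group sum of squares B0. The
# split statistic
#   lambda = pi / (2*(pi - 2)) * B0 / sigma0^2,
#   sigma0^2 = (sum_i (m_i - mbar)^2 + df_r * s_m^2) / (g + df_r),
# with s_m^2 = QMr/k the variance of a treatment mean, is referred to a
# chi-square with nu = g/(pi - 2) degrees of freedom (fractional df used
# directly: rounding would flip decisions near the threshold). A node is
# split when lambda exceeds the (1 - alpha) quantile, and the procedure
# recurses into both halves; final contiguous runs get letters, 'a' for
# the highest-mean group.

#' Scott-Knott grouping of genotype means
#'
#' @param means named numeric vector of genotype means.
#' @param QMr residual mean square from the trait's ANOVA.
#' @param df_r residual degrees of freedom, >= 1.
#' @param k number of replicates each mean averages over.
#' @param alpha significance level of the chi-square test (default 0.05).
#' @param trait optional trait label carried through.
#' @return An object of class `scott_knott`: list with `groups` (data.frame
#'   `genotype`, `mean`, `group` sorted by descending mean), `splits`
#'   (per-tested-node data.frame of `B0`, `lambda`, `chisq_crit`, `nu`,
#'   `split`), `n_groups`, `alpha`, `trait`.
#' @export
scott_knott <- function(means, QMr, df_r, k, alpha = 0.05,
                        trait = NA_character_) {
  if (is.null(names(means))) names(means) <- paste0("G", seq_along(means))
  if (QMr < 0) stop("QMr must be >= 0")
  if (df_r < 1) stop("df_r must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  ord <- order(-means, names(means))  # descending, ties by label
  m <- means[ord]
  s2_mean <- QMr / k
  splits <- list()
  group_of <- integer(length(m))
  next_group <- 0L

  assign_groups <- function(idx) {
    g <- length(idx)
    if (g >= 2) {
      sp <- sk_split(m[idx], s2_mean, df_r, alpha)
      splits[[length(splits) + 1L]] <<- sp$record
      if (sp$split) {
        assign_groups(idx[seq_len(sp$left_size)])
        assign_groups(idx[(sp$left_size + 1L):g])
        return(invisible())
      }
    }
    next_group <<- next_group + 1L
    group_of[idx] <<- next_group
    invisible()
  }
  assign_groups(seq_along(m))

  lab <- group_letters(next_group)
  groups <- data.frame(genotype = names(m), mean = unname(m),
                       group = lab[group_of], stringsAsFactors = FALSE)
  structure(list(groups = groups,
                 splits = if (length(splits)) do.call(rbind, splits)
                          else data.frame(),
                 n_groups = next_group, alpha = alpha, trait = trait),
            class = "scott_knott")
}

# One Scott-Knott node test: find the argmax-B0 contiguous split of the
# (already descending-sorted) means y, and decide whether to split.
sk_split <- function(y, s2_mean, df_r, alpha) {
  g <- length(y)
  best_b0 <- -Inf
  best_left <- 1L
  ybar <- mean(y)
  for (j in seq_len(g - 1)) {      # left group = y[1..j]; ties -> smallest j
    m1 <- mean(y[seq_len(j)])
    m2 <- mean(y[(j + 1):g])
    b0 <- j * (m1 - ybar)^2 + (g - j) * (m2 - ybar)^2
    if (b0 > best_b0 + 1e-12) {
      best_b0 <- b0
      best_left <- j
    }
  }
  sigma0_sq <- (sum((y - ybar)^2) + df_r * s2_mean) / (g + df_r)
  lambda <- if (sigma0_sq > 0) pi / (2 * (pi - 2)) * best_b0 / sigma0_sq else 0
  nu <- g / (pi - 2)
  crit <- stats::qchisq(1 - alpha, df = nu)
  list(split = lambda > crit, left_size = best_left,
       record = data.frame(n = g, B0 = best_b0, sigma0_sq = sigma0_sq,
                           lambda = lambda, nu = nu, chisq_crit = crit,
                           split = lambda > crit))
}

# letter labels a, b, ..., z, aa, ab, ... for group indices
group_letters <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  c(letters, as.vector(outer(letters, letters, function(a, b) paste0(a, b))))[seq_len(n)]
}

#' @export
print.scott_knott <- function(x, ...) {
  cat("Scott-Knott grouping",
      if (!is.na(x$trait)) paste0("(", x$trait, ")"), "at alpha =",
      x$alpha, "\n")
  cat(" ", x$n_groups, "group(s)\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}
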