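# Genotype clustering: Tocher's optimization method, UPGMA agglomeration
# and Mojena's dendrogram cutoff.

#' Tocher's optimization grouping
#'
#' Greedy grouping that keeps within-group mean dissimilarity below the
#' inclusion limit theta = the largest nearest-neighbour distance over all
#' genotypes. The first group is seeded with the globally closest pair;
#' the unassigned genotype with the smallest mean distance to the current
#' group joins while that mean is <= theta; when no candidate qualifies the
#' group closes and a new one is seeded from the closest remaining pair (a
#' final lone genotype forms a singleton). Ties are broken by
#' lexicographic genotype label for reproducibility.
#'
#' @param d symmetric dissimilarity matrix with genotype labels.
#' @param criterion `"mean_vs_theta"` (the classic rule above) or
#'   `"increase"` — admit a candidate only while the *increase* in group
#'   mean distance it causes stays <= theta.
#' @return An object of class `tocher_groups`: list with `groups` (list of
#'   label vectors, in formation order), `theta`, `intra_mean` (per-group
#'   mean within-group distance; `NA` for singletons), `criterion`.
#' @export
tocher <- function(d, criterion = c("mean_vs_theta", "increase")) {
  criterion <- match.arg(criterion)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("G", seq_len(n))
  labels <- rownames(d)
  if (n == 1)
    return(structure(list(groups = list(labels), theta = NA_real_,
                          intra_mean = NA_real_, criterion = criterion),
                     class = "tocher_groups"))
  dd <- d
  diag(dd) <- Inf
  theta <- max(apply(dd, 1, min))
  remaining <- labels
  groups <- list()

  closest_pair <- function(members) {
    sub <- d[members, members, drop = FALSE]
    diag(sub) <- Inf
    best <- which(sub == min(sub), arr.ind = TRUE)
    # smallest-label pair among ties
    pairs <- cbind(members[best[, 1]], members[best[, 2]])
    pairs <- t(apply(pairs, 1, sort))
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    pairs[1, ]
  }

  while (length(remaining) > 0) {
    if (length(remaining) == 1) {
      groups[[length(groups) + 1L]] <- remaining
      remaining <- character(0)
      break
    }
    grp <- closest_pair(remaining)
    remaining <- setdiff(remaining, grp)
    repeat {
      if (!length(remaining)) break
      mean_to_grp <- vapply(remaining,
                            function(x) mean(d[x, grp]), numeric(1))
      o <- order(mean_to_grp, remaining)
      cand <- remaining[o[1]]
      admit <- if (criterion == "mean_vs_theta") {
        mean_to_grp[o[1]] <= theta
      } else {
        new_members <- c(grp, cand)
        sub <- d[new_members, new_members]
        new_mean <- mean(sub[upper.tri(sub)])
        old_sub <- d[grp, grp, drop = FALSE]
        old_mean <- if (length(grp) > 1) mean(old_sub[upper.tri(old_sub)]) else 0
        (new_mean - old_mean) <= theta
      }
      if (!admit) break
      grp <- c(grp, cand)
      remaining <- setdiff(remaining, cand)
    }
    groups[[length(groups) + 1L]] <- grp
  }
  intra <- vapply(groups, function(g) {
    if (length(g) < 2) return(NA_real_)
    sub <- d[g, g]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  structure(list(groups = groups, theta = theta, intra_mean = intra,
                 criterion = criterion),
            class = "tocher_groups")
}

#' @export
print.tocher_groups <- function(x, ...) {
  cat("Tocher grouping (theta =", format(x$theta, digits = 4), ")\n")
  for (i in seq_along(x$groups))
    cat(sprintf("  %s: %s\n", as.roman(i),
                paste(x$groups[[i]], collapse = ", ")))
  invisible(x)
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Standard unweighted pair-group agglomeration with arithmetic-mean,
#' size-weighted distance updates, via [stats::hclust()]. Fusion heights
#' are non-decreasing (the UPGMA ultrametric property).
#'
#' @param d symmetric dissimilarity matrix with genotype labels.
#' @return An object of class `merge_tree`: list with `merge` (hclust-style
#'   merge matrix), `height` (fusion heights), `labels`, and the underlying
#'   `hclust` object.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 genotypes")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("G", seq_len(n))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 hclust = hc),
            class = "merge_tree")
}

#' Mojena's dendrogram cutoff
#'
#' Cuts a merge tree at `mean(h) + c * sd(h)` over its fusion heights
#' (sample SD, denominator n - 1; zero for a single merge). Merges above
#' the cutoff are removed; the resulting connected components are the
#' groups.
#'
#' @param tree a [upgma()] merge tree.
#' @param c Mojena's constant (default 1.25, the value the method's
#'   follow-up literature recommends).
#' @return An object of class `mojena_cut`: list with `cutoff`, `c`,
#'   `height_mean`, `height_sd`, `membership` (named integer vector),
#'   `n_groups`.
#' @export
mojena_cut <- function(tree, c = 1.25) {
  stopifnot(inherits(tree, "merge_tree"))
  h <- tree$height
  h_sd <- if (length(h) > 1) stats::sd(h) else 0
  cutoff <- mean(h) + c * h_sd
  membership <- stats::cutree(tree$hclust, h = cutoff)
  structure(list(cutoff = cutoff, c = c, height_mean = mean(h),
                 height_sd = h_sd, membership = membership,
                 n_groups = max(membership)),
            class = "mojena_cut")
}

#' @export
print.mojena_cut <- function(x, ...) {
  cat(sprintf("Mojena cutoff = %.4f (mean %.4f + %.2f x sd %.4f): %d group(s)\n",
              x$cutoff, x$height_mean, x$c, x$height_sd, x$n_groups))
  invisible(x)
}

#' Cophenetic distance matrix of a merge tree
#'
#' Pairwise fusion heights — the height at which each pair of leaves first
#' joins. On an ultrametric input UPGMA's cophenetic distances reproduce
#' the input exactly.
#'
#' @param tree a [upgma()] merge tree.
#' @return symmetric matrix of cophenetic distances.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  as.matrix(stats::cophenetic(tree$hclust))
}

#' Export a merge tree as Newick
#'
#' Branch lengths derive from fusion heights (leaf-to-node spans of
#' height/2, the standard ultrametric layout).
#'
#' @param tree a [upgma()] merge tree.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to a file.
#' @export
as_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "merge_tree"))
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
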