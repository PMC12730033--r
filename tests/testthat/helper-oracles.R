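# Independent brute-force oracles used across the suite.

# Naive two-loop one-way ANOVA sums of squares.
naive_anova <- function(values, genotypes) {
  grand <- mean(values)
  ss_g <- 0
  ss_e <- 0
  for (g in unique(genotypes)) {
    y <- values[genotypes == g]
    ss_g <- ss_g + length(y) * (mean(y) - grand)^2
    for (v in y) ss_e <- ss_e + (v - mean(y))^2
  }
  g <- length(unique(genotypes))
  k <- length(values) / g
  list(SSg = ss_g, SSe = ss_e, SStot = sum((values - grand)^2),
       QMg = ss_g / (g - 1), QMr = ss_e / (g * (k - 1)))
}

# Exhaustive argmax-B0 over contiguous splits of descending-sorted means.
naive_best_split <- function(y) {
  g <- length(y)
  ybar <- mean(y)
  b0 <- vapply(seq_len(g - 1), function(j) {
    j * (mean(y[1:j]) - ybar)^2 + (g - j) * (mean(y[(j + 1):g]) - ybar)^2
  }, numeric(1))
  list(left = which.max(b0), B0 = max(b0))
}

# Random balanced long-format table.
random_phenotype_table <- function(g = 20, k = 4, traits = "y",
                                   mu = 10, sd_g = 1, sd_e = 1) {
  out <- do.call(rbind, lapply(traits, function(tr) {
    gi <- rnorm(g, 0, sd_g)
    data.frame(genotype = rep(sprintf("G%02d", 1:g), each = k),
               replicate = rep(1:k, g), trait = tr,
               value = mu + rep(gi, each = k) + rnorm(g * k, 0, sd_e))
  }))
  phenotype_table(out)
}

# Distance matrix helper.
as_dmat <- function(m, labels = NULL) {
  m <- as.matrix(m)
  if (is.null(labels)) labels <- LETTERS[seq_len(nrow(m))]
  dimnames(m) <- list(labels, labels)
  m
}
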