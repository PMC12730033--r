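# End-to-end orchestration: file readers and the full analysis pipeline.

#' Read a long-format phenotype CSV
#'
#' Expects columns `genotype`, `replicate`, `trait`, `value` (a wide
#' matrix with genotypes in the first column is also accepted and melted).
#' Validates types and duplicate cells.
#'
#' @param path CSV file path.
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  long <- all(c("genotype", "replicate", "trait", "value") %in% names(df))
  if (!long) {
    if (!all(c("genotype", "replicate") %in% names(df)))
      stop(path, ": need either long columns (genotype, replicate, trait, ",
           "value) or a wide layout with genotype and replicate columns")
    traits <- setdiff(names(df), c("genotype", "replicate"))
    df <- stats::reshape(df, direction = "long", varying = traits,
                         v.names = "value", timevar = "trait",
                         times = traits, idvar = c("genotype", "replicate"))
    rownames(df) <- NULL
  }
  if (!is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$value))) & !is.na(df$value))
    stop(path, ": non-numeric value(s) at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  phenotype_table(df[, c("genotype", "replicate", "trait", "value")])
}

#' Read a germination time-course CSV
#'
#' Expects columns `genotype`, `replicate`, `day`, `count`, `seeds_sown`,
#' with incremental daily counts.
#'
#' @param path CSV file path.
#' @return a [germination_course()].
#' @export
read_germination <- function(path) {
  if (!file.exists(path)) stop("germination file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  germination_course(df)
}

#' Run the full phenotypic-divergence pipeline
#'
#' Executes, in order: derivation of germination indices (when a course is
#' supplied), per-trait ANOVA and genetic parameters, Scott-Knott mean
#' grouping, genotype-mean divergence matrix, Tocher grouping, UPGMA with
#' Mojena's cutoff, Singh trait contributions, canonical variates, and
#' genotype-ideotype selection. All stage tables are written as CSV under
#' `output_dir`, the dendrogram as Newick, and a plain-text plus JSON
#' summary report. A stage failure aborts with a stage-named error;
#' outputs of completed stages are retained.
#'
#' @param phenotypes a [phenotype_table()] or path to a phenotype CSV; may
#'   be `NULL` when `sim_config` is given.
#' @param germination optional [germination_course()] or path to a
#'   germination CSV; its G/GSI/MGT indices are appended to the traits.
#' @param output_dir directory for the report bundle (created).
#' @param alpha Scott-Knott significance level.
#' @param mojena_c Mojena's constant.
#' @param distance `"mahalanobis_d2"`, `"std_euclidean"` or
#'   `"std_mean_euclidean"`.
#' @param ideotype optional [ideotype_spec()]; by default every trait is
#'   higher-is-better except MGT (lower-is-better), unweighted.
#' @param n_sel genotypes to select (default 30%, at least 1).
#' @param sim_config optional [simulation_config()] used to simulate the
#'   inputs when `phenotypes` is `NULL`.
#' @return (invisibly) a list with every stage result and the output paths.
#' @export
run_pipeline <- function(phenotypes = NULL, germination = NULL, output_dir,
                         alpha = 0.05, mojena_c = 1.25,
                         distance = c("mahalanobis_d2", "std_euclidean",
                                      "std_mean_euclidean"),
                         ideotype = NULL, n_sel = NULL, sim_config = NULL) {
  distance <- match.arg(distance)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  tab <- stage("input", {
    if (is.null(phenotypes)) {
      if (is.null(sim_config))
        stop("either phenotypes or sim_config must be supplied")
      simulate_trait_table(sim_config)
    } else if (is.character(phenotypes)) read_phenotypes(phenotypes)
    else phenotype_table(phenotypes)
  })
  if (!is.null(germination)) {
    course <- stage("germination", {
      if (is.character(germination)) read_germination(germination)
      else germination_course(germination)
    })
    gt <- stage("germination", germination_traits(course))
    gt <- gt[!gt$trait %in% unique(tab$trait), , drop = FALSE]
    if (nrow(gt)) tab <- phenotype_table(rbind(as.data.frame(tab),
                                               as.data.frame(gt)))
  }
  message("input: ", nrow(tab), " observations, ",
          length(unique(tab$genotype)), " genotypes, ",
          length(unique(tab$trait)), " traits")

  params <- stage("variance_components", genetic_parameters_table(tab))
  utils::write.csv(params, file.path(output_dir, "genetic_parameters.csv"),
                   row.names = FALSE)
  message("variance_components: ", nrow(params), " traits")

  sk_rows <- stage("scott_knott", {
    do.call(rbind, lapply(params$trait, function(tr) {
      a <- anova_crd(tab, tr)
      mns <- tapply(tab$value[tab$trait == tr & !is.na(tab$value)],
                    tab$genotype[tab$trait == tr & !is.na(tab$value)], mean)
      sk <- scott_knott(mns, a$QMr, a$df_r, a$k, alpha = alpha, trait = tr)
      cbind(trait = tr, sk$groups)
    }))
  })
  utils::write.csv(sk_rows, file.path(output_dir, "scott_knott_groups.csv"),
                   row.names = FALSE)
  message("mean_grouping: ", nrow(sk_rows), " genotype x trait labels")

  div <- stage("divergence", {
    M <- genotype_means(tab)
    # MGT cells can be missing when a replicate never germinated; divergence
    # needs complete genotype means
    M <- M[, colSums(is.na(M)) == 0, drop = FALSE]
    if (distance == "mahalanobis_d2") {
      pcov <- pooled_residual_covariance(
        tab[tab$trait %in% colnames(M), , drop = FALSE])
      list(means = M, pcov = pcov, D = mahalanobis_d2(M, pcov))
    } else {
      list(means = M, pcov = NULL,
           D = standardized_euclidean(M, mean_variant =
                                        distance == "std_mean_euclidean"))
    }
  })
  utils::write.csv(data.frame(genotype = rownames(div$D), div$D,
                              check.names = FALSE),
                   file.path(output_dir, "distance_matrix.csv"),
                   row.names = FALSE)
  message("divergence: ", distance, " on ", nrow(div$D), " genotypes")

  toc <- stage("tocher", tocher(div$D))
  utils::write.csv(
    data.frame(genotype = unlist(toc$groups),
               group = rep(seq_along(toc$groups),
                           lengths(toc$groups))),
    file.path(output_dir, "tocher_groups.csv"), row.names = FALSE)
  message("tocher: ", length(toc$groups), " groups, theta = ",
          format(toc$theta, digits = 4))

  tree <- stage("upgma", upgma(if (distance == "mahalanobis_d2")
    standardized_euclidean(div$means) else div$D))
  cut <- stage("mojena", mojena_cut(tree, c = mojena_c))
  as_newick(tree, file.path(output_dir, "dendrogram.newick"))
  utils::write.csv(data.frame(genotype = names(cut$membership),
                              group = unname(cut$membership)),
                   file.path(output_dir, "upgma_groups.csv"),
                   row.names = FALSE)
  message("upgma/mojena: cutoff = ", format(cut$cutoff, digits = 4), ", ",
          cut$n_groups, " groups")

  contrib <- stage("trait_importance", {
    pcov <- if (!is.null(div$pcov)) div$pcov else
      pooled_residual_covariance(tab[tab$trait %in% colnames(div$means), ,
                                     drop = FALSE])
    singh_contribution(div$means, pcov)
  })
  utils::write.csv(contrib, file.path(output_dir, "singh_contribution.csv"),
                   row.names = FALSE)
  cva <- stage("canonical_variates",
               canonical_variates(tab[tab$trait %in% colnames(div$means), ,
                                      drop = FALSE]))
  utils::write.csv(data.frame(variate = seq_along(cva$eigenvalues),
                              eigenvalue = cva$eigenvalues,
                              percent = cva$percent,
                              cumulative = cva$cumulative),
                   file.path(output_dir, "canonical_variates.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(genotype = rownames(cva$scores), cva$scores,
                              check.names = FALSE),
                   file.path(output_dir, "canonical_scores.csv"),
                   row.names = FALSE)
  message("trait_importance: top contribution ",
          contrib$trait[which.max(contrib$percent)], " (",
          round(max(contrib$percent), 2), "%)")

  sel <- stage("selection", {
    spec <- if (!is.null(ideotype)) ideotype else {
      dirs <- stats::setNames(
        ifelse(colnames(div$means) == "MGT", "lower_is_better",
               "higher_is_better"), colnames(div$means))
      ideotype_spec(dirs)
    }
    if (is.null(n_sel)) genotype_ideotype_index(div$means, spec)
    else genotype_ideotype_index(div$means, spec, n_sel = n_sel)
  })
  utils::write.csv(as.data.frame(sel), file.path(output_dir, "selection.csv"),
                   row.names = FALSE)
  message("selection: ", sum(sel$selected), " genotype(s) selected")

  summary_list <- list(
    n_genotypes = length(unique(tab$genotype)),
    n_traits = length(unique(tab$trait)),
    distance = distance,
    tocher_n_groups = length(toc$groups),
    tocher_theta = toc$theta,
    mojena_cutoff = cut$cutoff,
    mojena_n_groups = cut$n_groups,
    top_contribution_trait = contrib$trait[which.max(contrib$percent)],
    top_contribution_pct = max(contrib$percent),
    cumulative_pct_first3 = cva$cumulative[min(3, length(cva$cumulative))],
    selected = sel$genotype[sel$selected])
  jsonlite::write_json(summary_list, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    "Phenotypic divergence pipeline summary",
    sprintf("genotypes: %d  traits: %d  distance: %s",
            summary_list$n_genotypes, summary_list$n_traits, distance),
    sprintf("Tocher: %d groups (theta = %.2f)",
            summary_list$tocher_n_groups, summary_list$tocher_theta),
    sprintf("UPGMA/Mojena: cutoff %.2f -> %d groups",
            summary_list$mojena_cutoff, summary_list$mojena_n_groups),
    sprintf("Top Singh contribution: %s (%.2f%%)",
            summary_list$top_contribution_trait,
            summary_list$top_contribution_pct),
    sprintf("Canonical variates 1-3 cumulative: %.2f%%",
            summary_list$cumulative_pct_first3),
    sprintf("Selected genotypes: %s",
            paste(summary_list$selected, collapse = ", "))),
    file.path(output_dir, "summary.txt"))

  invisible(list(table = tab, parameters = params, scott_knott = sk_rows,
                 distance = div$D, tocher = toc, tree = tree, mojena = cut,
                 contribution = contrib, canonical = cva, selection = sel,
                 summary = summary_list, output_dir = output_dir))
}
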