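# Study-shaped orchestration: family scan -> paralogs/orthologs -> Ka/Ks +
# dating + window profiles -> NJ tree -> promoter census -> expression
# analytics, all governed by one pipeline_config.

#' Run the full gene-family pipeline
#'
#' Stages run in dependency order; any stage can be switched off, in which
#' case its outputs are omitted and the manifest records the omission.
#' Identical config + inputs yield an identical bundle (all randomized
#' stages are seeded from `config$rng_seed`).
#'
#' @param config A [pipeline_config()].
#' @param inputs Named list; recognized elements: `cds` (named list of dna
#'   records), `gene_models` (named list), `promoters` (named list of dna
#'   records), `motifs` (motif dictionary), `ct` (Ct table), `expression`
#'   (genes x samples matrix), `ortholog_sets` (list of two named record
#'   lists for cross-species BBH).
#' @param stages Character vector of stages to run, a subset of
#'   `c("family", "homology", "kaks", "tree", "promoter", "expression")`.
#' @return A `report_bundle` list: `family_table`, `homolog_table`,
#'   `kaks_table`, `window_profiles`, `tree`, `promoter_census`,
#'   `expression_order`, `fold_change_table`, `significance_table`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, inputs,
                         stages = c("family", "homology", "kaks", "tree",
                                    "promoter", "expression")) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("family", "homology", "kaks", "tree", "promoter",
                  "expression")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- function(stage, what) {
    for (w in what)
      if (is.null(inputs[[w]]))
        stop("stage '", stage, "' enabled but input '", w, "' is missing",
             call. = FALSE)
  }
  # validate all enabled stages before any computation
  if ("family" %in% stages) need("family", "cds")
  if ("homology" %in% stages) need("homology", "cds")
  if ("kaks" %in% stages) need("kaks", "cds")
  if ("tree" %in% stages) need("tree", "cds")
  if ("promoter" %in% stages) need("promoter", "promoters")
  if ("expression" %in% stages) need("expression", "ct")

  bundle <- list()
  proteins <- NULL
  if (any(c("family", "tree") %in% stages))
    proteins <- lapply(inputs$cds, translate_orf, strict_start = "silent")

  if ("family" %in% stages) {
    ft <- family_table(proteins, inputs$gene_models)
    membership <- vapply(proteins, function(p)
      classify_member(p)$member, TRUE)
    ft$table$member <- membership[ft$table$id]
    bundle$family_table <- ft$table
    bundle$family_means <- ft$means
  }

  pairs <- NULL
  if ("homology" %in% stages) {
    s <- scoring_scheme()
    para <- find_paralogs(inputs$cds, s, min_aln = config$bbh_min_aln,
                          min_identity = config$paralog_min_identity)
    orth <- NULL
    if (!is.null(inputs$ortholog_sets))
      orth <- bbh_orthologs(inputs$ortholog_sets[[1]],
                            inputs$ortholog_sets[[2]], s,
                            min_aln = config$bbh_min_aln)
    bundle$homolog_table <- rbind(para, orth)
    pairs <- bundle$homolog_table
  }

  if ("kaks" %in% stages) {
    if (is.null(pairs)) {
      pairs <- find_paralogs(inputs$cds, scoring_scheme(),
                             min_aln = config$bbh_min_aln,
                             min_identity = config$paralog_min_identity)
    }
    all_cds <- c(inputs$cds,
                 if (!is.null(inputs$ortholog_sets))
                   c(inputs$ortholog_sets[[1]], inputs$ortholog_sets[[2]]))
    kk <- list(); profiles <- list()
    for (i in seq_len(nrow(pairs))) {
      aln <- align_cds_pair(all_cds[[pairs$id_a[i]]],
                            all_cds[[pairs$id_b[i]]])
      res <- kaks(aln)
      kk[[i]] <- data.frame(id_a = res$id_a, id_b = res$id_b,
                            relation = pairs$relation[i],
                            ka = res$ka, ks = res$ks, ratio = res$ratio,
                            selection = classify_selection(res$ratio),
                            t_mya = divergence_time(
                              res$ks, config$lambda_rate)$t_mya)
      profiles[[paste(res$id_a, res$id_b, sep = "|")]] <-
        suppressWarnings(sliding_window_kaks(aln, config$window_len,
                                             config$window_step))
    }
    bundle$kaks_table <- if (length(kk)) do.call(rbind, kk) else NULL
    bundle$window_profiles <- profiles
  }

  if ("tree" %in% stages) {
    bundle$tree <- bootstrap_support(proteins,
                                     reps = config$bootstrap_reps,
                                     seed = config$rng_seed)
  }

  if ("promoter" %in% stages) {
    motifs <- if (is.null(inputs$motifs)) load_motif_dictionary()
              else inputs$motifs
    hits <- do.call(rbind, lapply(inputs$promoters, scan_promoter,
                                  motifs = motifs))
    rownames(hits) <- NULL
    bundle$promoter_census <- category_summary(hits, motifs)
    bundle$promoter_hits <- hits
  }

  if ("expression" %in% stages) {
    bundle$fold_change_table <- relative_expression(inputs$ct)
    bundle$significance_table <- significance(inputs$ct)
    if (!is.null(inputs$expression))
      bundle$expression_order <- cluster_expression(inputs$expression)
  }

  bundle$manifest <- list(
    config = unclass(config),
    stages_run = stages,
    stages_omitted = setdiff(all_stages, stages),
    n_inputs = vapply(inputs, function(x)
      if (is.data.frame(x) || is.matrix(x)) nrow(x) else length(x), 0L),
    package_version = as.character(utils::packageVersion("grfevol")))
  class(bundle) <- "report_bundle"
  bundle
}

#' Write a report bundle to a directory of plain-text files
#'
#' TSV for tables, Newick for the tree, YAML for the manifest — every stage
#' output independently re-usable.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(x, name) {
    p <- file.path(dir, name)
    write_tsv(x, p)
    paths <<- c(paths, p)
  }
  if (!is.null(bundle$family_table)) put(bundle$family_table,
                                         "family_table.tsv")
  if (!is.null(bundle$homolog_table)) put(bundle$homolog_table,
                                          "homolog_table.tsv")
  if (!is.null(bundle$kaks_table)) put(bundle$kaks_table, "kaks_table.tsv")
  if (!is.null(bundle$window_profiles))
    for (nm in names(bundle$window_profiles))
      put(bundle$window_profiles[[nm]],
          paste0("window_", gsub("[^A-Za-z0-9_]", "_", nm), ".tsv"))
  if (!is.null(bundle$promoter_census))
    put(bundle$promoter_census$per_motif, "promoter_census.tsv")
  if (!is.null(bundle$fold_change_table))
    put(bundle$fold_change_table, "fold_changes.tsv")
  if (!is.null(bundle$significance_table))
    put(bundle$significance_table, "significance.tsv")
  if (!is.null(bundle$tree)) {
    p <- file.path(dir, "tree.nwk")
    write_newick(bundle$tree, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(bundle$manifest, p)
  paths <- c(paths, p)
  invisible(paths)
}
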