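# End-to-end orchestration of the two-step pipeline with reproducible
# seeding, optional per-group (subtype-wise) execution and result export.

# Deterministic sub-seed derived from the master seed and a stage/group
# label, so adding a group or stage never perturbs the others' streams.
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647L)
}

#' Step 1: mutational pathway enrichment
#'
#' Builds the impact-scored mutation matrix from records and coverage, then
#' runs the ranking and weighted-KS enrichment stage over the pathway
#' collection.  Seeds the RNG deterministically from `cfg$rng_seed`.
#'
#' @param records Mutation record data frame (see [read_maf()]).
#' @param pathways List of [pathway_graph()] objects.
#' @param coverage Named covered-bases vector (see [read_coverage()]).
#' @param cfg A [run_config()].
#' @param samples Optional full cohort sample list (pass it when samples may
#'   carry no mutations).
#' @param verbose Log stage cardinalities via `message()`.
#' @return List with `matrix` (the `mutation_matrix`), `enrichment`
#'   (data frame sorted by p with FDR and rank) and `member_scores`.
#' @export
run_step1 <- function(records, pathways, coverage, cfg = run_config(),
                      samples = NULL, verbose = FALSE) {
  mat <- build_matrix(records, coverage, samples = samples)
  if (verbose)
    message("step1: ", nrow(records), " records -> matrix ",
            length(mat$genes), " genes x ", length(mat$samples), " samples")
  set.seed(derive_seed(cfg$rng_seed, "enrichment"))
  enr <- enrich_pathways(mat, pathways, cfg)
  if (verbose)
    message("step1: ", nrow(enr$results), " pathways tested")
  list(matrix = mat, enrichment = enr$results,
       member_scores = enr$member_scores, background = enr$background)
}

#' Step 2: collaborative driver-pathway selection
#'
#' Takes the top enriched pathways and runs the constrained greedy search.
#' Seeds the RNG deterministically from `cfg$rng_seed`.
#'
#' @param mat A `mutation_matrix` (from [run_step1()]).
#' @param enrichment Enrichment result data frame.
#' @param pathways The full pathway list (candidates are looked up by id).
#' @param cfg A [run_config()].
#' @param constrained Set `FALSE` for the unconstrained greedy variant.
#' @param verbose Log each greedy step.
#' @return A `collaborative_set` (see [greedy_select()]).
#' @export
run_step2 <- function(mat, enrichment, pathways, cfg = run_config(),
                      constrained = TRUE, verbose = FALSE) {
  stopifnot(nrow(enrichment) >= 1L)
  top_ids <- select_top_pathways(enrichment, cfg$top_k_pathways)
  ids <- vapply(pathways, `[[`, character(1), "pathway_id")
  candidates <- pathways[match(top_ids, ids)]
  set.seed(derive_seed(cfg$rng_seed, "collaboration"))
  res <- greedy_select(mat, candidates, cfg, constrained = constrained)
  if (verbose && nrow(res$steps) > 0L)
    for (i in seq_len(nrow(res$steps)))
      message(sprintf("step2 [%d]: %s MCR=%.3f max_gene=%.3f p=%s",
                      i, res$steps$pathway_id[i], res$steps$mcr_after[i],
                      res$steps$max_gene_rate[i],
                      format(res$steps$p[i])))
  res
}

#' Run the full two-step pipeline
#'
#' @inheritParams run_step1
#' @param constrained Set `FALSE` to drop the dominance and significance
#'   constraints in the greedy step.
#' @param out_dir Optional directory; when given, results and the resolved
#'   configuration are written there via [write_results()] and
#'   [write_config()].
#' @return List with `matrix`, `enrichment` and `collab`.
#' @export
run_pipeline <- function(records, pathways, coverage, cfg = run_config(),
                         samples = NULL, constrained = TRUE, out_dir = NULL,
                         verbose = FALSE) {
  s1 <- run_step1(records, pathways, coverage, cfg, samples = samples,
                  verbose = verbose)
  collab <- run_step2(s1$matrix, s1$enrichment, pathways, cfg,
                      constrained = constrained, verbose = verbose)
  if (!is.null(out_dir)) {
    write_results(s1$enrichment, collab, out_dir)
    write_config(cfg, file.path(out_dir, "config.tsv"))
  }
  list(matrix = s1$matrix, enrichment = s1$enrichment, collab = collab)
}

#' Run the pipeline independently per sample group
#'
#' Executes the full two-step pipeline on each group of samples (e.g. tumor
#' subtypes) with a per-group sub-seed derived from the master seed, and
#' tabulates which pathways were selected in which groups.
#'
#' @inheritParams run_pipeline
#' @param groups Named character vector mapping every sample to its group.
#' @return List with `per_group` (named list of pipeline results) and
#'   `comparison` (data frame pathway x group selection indicator with an
#'   `n_groups` column; shared pathways have `n_groups > 1`).
#' @export
run_per_group <- function(records, groups, pathways, coverage,
                          cfg = run_config(), samples = NULL,
                          constrained = TRUE, verbose = FALSE) {
  if (is.null(samples)) samples <- sort(unique(records$sample))
  missing <- setdiff(samples, names(groups))
  if (length(missing) > 0L)
    stop("data error: sample(s) with no group assignment: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)

  per_group <- list()
  for (g in sort(unique(unname(groups[samples])))) {
    g_samples <- samples[groups[samples] == g]
    g_records <- records[records$sample %in% g_samples, , drop = FALSE]
    g_cfg <- cfg
    g_cfg$rng_seed <- derive_seed(cfg$rng_seed, g)
    if (nrow(g_records) == 0L) {
      if (verbose) message("group ", g, ": no mutations, skipped")
      per_group[[g]] <- NULL
      next
    }
    per_group[[g]] <- run_pipeline(g_records, pathways, coverage, g_cfg,
                                   samples = g_samples,
                                   constrained = constrained,
                                   verbose = verbose)
  }

  all_selected <- lapply(per_group, function(r) r$collab$steps$pathway_id)
  pw_ids <- sort(unique(unlist(all_selected)))
  comparison <- data.frame(pathway_id = pw_ids, stringsAsFactors = FALSE)
  for (g in names(per_group))
    comparison[[g]] <- pw_ids %in% all_selected[[g]]
  comparison$n_groups <- if (length(per_group))
    rowSums(comparison[, names(per_group), drop = FALSE]) else integer(0)
  list(per_group = per_group, comparison = comparison)
}
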