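# Synthetic somatic-mutation cohort generator: background mutations, planted
# co-mutated pathway groups, single-gene-dominated pathways, random connected
# pathway topologies, coverage and impact tables -- all with known ground
# truth and full determinism under a seed.

#' Specification of a synthetic mutation cohort
#'
#' @param m_samples Number of samples (ignored when `groups` is given; then
#'   the group sizes define it).
#' @param n_genes Number of genes; pathways draw disjoint gene blocks from
#'   this pool and leftover genes are background-only.
#' @param n_pathways Number of pathways.
#' @param genes_per_pathway Length-2 integer range of pathway sizes.
#' @param background_nsy_rate Per-gene-per-sample probability of a background
#'   non-synonymous mutation.
#' @param background_sy_rate Per-gene-per-sample probability of a silent
#'   mutation.
#' @param planted_sets List of `list(pathways = <indices>, target = <rate>)`:
#'   each set plants a collaborative sample block of expected fraction
#'   `target` in which every member pathway receives at least one
#'   non-synonymous mutation, spread over randomly chosen member genes.
#' @param dominated_pathways List of `list(pathway = <index>,
#'   gene_coverage = <rate>)`: the pathway's first gene alone is mutated in
#'   the given expected fraction of samples.
#' @param groups Optional named list of `list(size = <n>, planted_sets =
#'   <as above>)` defining sample groups (e.g. tumor subtypes) with
#'   group-specific planted structure.
#' @param impact_range Range of scored missense impact values.
#' @param special_class_rate Fraction of non-synonymous events emitted as
#'   indel/nonsense/splice-site (exercising the max-score branch of the
#'   impact rule).
#' @param unscored_missense_rate Fraction of missense events left without an
#'   impact score (exercising the cohort-mean branch).
#' @param rng_seed Seed making generation fully deterministic.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(m_samples = 200, n_genes = 500, n_pathways = 20,
                        genes_per_pathway = c(8, 12),
                        background_nsy_rate = 0.01,
                        background_sy_rate = 0.005,
                        planted_sets = list(), dominated_pathways = list(),
                        groups = NULL,
                        impact_range = c(0.5, 4.5),
                        special_class_rate = 0.1,
                        unscored_missense_rate = 0.1,
                        rng_seed = 1L) {
  spec <- list(m_samples = as.integer(m_samples), n_genes = as.integer(n_genes),
               n_pathways = as.integer(n_pathways),
               genes_per_pathway = as.integer(genes_per_pathway),
               background_nsy_rate = background_nsy_rate,
               background_sy_rate = background_sy_rate,
               planted_sets = planted_sets,
               dominated_pathways = dominated_pathways,
               groups = groups,
               impact_range = impact_range,
               special_class_rate = special_class_rate,
               unscored_missense_rate = unscored_missense_rate,
               rng_seed = as.integer(rng_seed))
  if (!is.null(groups)) spec$m_samples <-
      sum(vapply(groups, `[[`, numeric(1), "size"))
  stopifnot(spec$m_samples >= 1L, spec$n_genes >= 1L, spec$n_pathways >= 1L,
            length(spec$genes_per_pathway) == 2L,
            spec$genes_per_pathway[1] >= 2L,
            diff(spec$genes_per_pathway) >= 0L,
            spec$background_nsy_rate >= 0, spec$background_nsy_rate <= 1,
            spec$background_sy_rate >= 0, spec$background_sy_rate <= 1,
            spec$special_class_rate >= 0, spec$special_class_rate <= 1,
            spec$unscored_missense_rate >= 0, spec$unscored_missense_rate <= 1)
  all_planted <- c(spec$planted_sets,
                   unlist(lapply(spec$groups, `[[`, "planted_sets"),
                          recursive = FALSE))
  for (ps in all_planted) {
    stopifnot(all(ps$pathways >= 1L), all(ps$pathways <= spec$n_pathways))
    if (ps$target > 1 || ps$target < 0)
      stop("infeasible spec: planted coverage target must lie in [0, 1]",
           call. = FALSE)
  }
  for (dp in spec$dominated_pathways)
    stopifnot(dp$pathway >= 1L, dp$pathway <= spec$n_pathways,
              dp$gene_coverage >= 0, dp$gene_coverage <= 1)
  structure(spec, class = "cohort_spec")
}

# Random connected topology: a random attachment tree plus extra edges.
.random_connected_edges <- function(genes, extra_frac = 0.3) {
  k <- length(genes)
  if (k < 2L) return(matrix(character(0), ncol = 2))
  perm <- sample(genes)
  parent <- vapply(2:k, function(i) perm[sample.int(i - 1L, 1L)], character(1))
  edges <- cbind(parent, perm[2:k])
  n_extra <- round(extra_frac * k)
  tried <- 0L
  while (n_extra > 0L && tried < 10L * k) {
    pair <- sort(sample(genes, 2L))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (!paste(pair[1], pair[2]) %in% key) {
      edges <- rbind(edges, pair)
      n_extra <- n_extra - 1L
    }
    tried <- tried + 1L
  }
  dimnames(edges) <- NULL
  edges
}

#' Generate a complete synthetic cohort
#'
#' Draws background non-synonymous and silent mutations independently per
#' gene and sample, plants collaborative sample blocks in which every member
#' pathway of a planted set is mutated (through randomly chosen member
#' genes, not a fixed one), drives dominated pathways through their single
#' designated gene, and emits coverage and impact tables plus random
#' connected pathway topologies.  Fully deterministic given the seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed override (defaults to `spec$rng_seed`).
#' @return An object of class `synthetic_cohort`: `records` (mutation
#'   records with impacts joined), `samples`, `coverage` (named vector),
#'   `impacts` (impact table rows for scored missense events), `pathways`
#'   (list of [pathway_graph()]), `groups` (named sample->group vector or
#'   `NULL`) and `truth` (planted collaborative pathway ids per set,
#'   dominated pathway/gene pairs, per-sample planted-block membership).
#' @export
generate_cohort <- function(spec, seed = spec$rng_seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  m <- spec$m_samples
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  samples <- sprintf("S%04d", seq_len(m))

  sizes <- sample(seq(spec$genes_per_pathway[1], spec$genes_per_pathway[2]),
                  spec$n_pathways, replace = TRUE)
  if (sum(sizes) > spec$n_genes)
    stop("infeasible spec: pathway gene blocks exceed the gene pool ",
         "(need ", sum(sizes), ", have ", spec$n_genes, ")", call. = FALSE)
  ends <- cumsum(sizes)
  pathways <- lapply(seq_len(spec$n_pathways), function(i) {
    block <- genes[(ends[i] - sizes[i] + 1L):ends[i]]
    pathway_graph(sprintf("PW%03d", i), sprintf("synthetic pathway %d", i),
                  block, .random_connected_edges(block))
  })

  group_of <- NULL
  if (!is.null(spec$groups)) {
    group_of <- rep(names(spec$groups),
                    vapply(spec$groups, `[[`, numeric(1), "size"))
    names(group_of) <- samples
  }

  ev_gene <- character(0); ev_sample <- character(0); ev_class <- character(0)

  add_bernoulli_events <- function(gene_set, sample_set, rate, class) {
    if (rate <= 0 || length(gene_set) == 0L || length(sample_set) == 0L)
      return(invisible(NULL))
    hits <- which(stats::runif(length(gene_set) * length(sample_set)) < rate)
    if (length(hits) == 0L) return(invisible(NULL))
    gi <- ((hits - 1L) %% length(gene_set)) + 1L
    sj <- ((hits - 1L) %/% length(gene_set)) + 1L
    ev_gene <<- c(ev_gene, gene_set[gi])
    ev_sample <<- c(ev_sample, sample_set[sj])
    ev_class <<- c(ev_class, rep(class, length(hits)))
    invisible(NULL)
  }

  add_bernoulli_events(genes, samples, spec$background_nsy_rate, "nsy")
  add_bernoulli_events(genes, samples, spec$background_sy_rate, "silent")

  truth_sets <- list()
  plant <- function(ps, sample_pool, label) {
    block <- sample_pool[stats::runif(length(sample_pool)) < ps$target]
    for (pw_i in ps$pathways) {
      pw_genes <- pathways[[pw_i]]$genes
      if (length(block) > 0L) {
        picked <- pw_genes[sample.int(length(pw_genes), length(block),
                                      replace = TRUE)]
        ev_gene <<- c(ev_gene, picked)
        ev_sample <<- c(ev_sample, block)
        ev_class <<- c(ev_class, rep("nsy", length(block)))
      }
    }
    truth_sets[[length(truth_sets) + 1L]] <<- list(
      label = label,
      pathway_ids = vapply(pathways[ps$pathways], `[[`, character(1),
                           "pathway_id"),
      target = ps$target, collab_samples = block)
    invisible(NULL)
  }

  for (ps in spec$planted_sets) plant(ps, samples, "cohort")
  if (!is.null(spec$groups))
    for (gname in names(spec$groups))
      for (ps in spec$groups[[gname]]$planted_sets)
        plant(ps, samples[group_of == gname], gname)

  dominated <- list()
  for (dp in spec$dominated_pathways) {
    gene <- pathways[[dp$pathway]]$genes[1]
    block <- samples[stats::runif(m) < dp$gene_coverage]
    if (length(block) > 0L) {
      ev_gene <- c(ev_gene, rep(gene, length(block)))
      ev_sample <- c(ev_sample, block)
      ev_class <- c(ev_class, rep("nsy", length(block)))
    }
    dominated[[length(dominated) + 1L]] <- list(
      pathway_id = pathways[[dp$pathway]]$pathway_id, gene = gene)
  }

  n_ev <- length(ev_gene)
  variant_class <- character(n_ev)
  impact <- rep(NA_real_, n_ev)
  is_nsy <- ev_class == "nsy"
  variant_class[!is_nsy] <- "silent"
  if (any(is_nsy)) {
    u <- stats::runif(sum(is_nsy))
    special <- u < spec$special_class_rate
    cls <- rep("missense", sum(is_nsy))
    cls[special] <- sample(c("indel", "nonsense", "splice_site"),
                           sum(special), replace = TRUE)
    variant_class[is_nsy] <- cls
    mis <- which(is_nsy)[cls == "missense"]
    scored <- stats::runif(length(mis)) >= spec$unscored_missense_rate
    impact[mis[scored]] <- stats::runif(sum(scored), spec$impact_range[1],
                                        spec$impact_range[2])
  }

  records <- data.frame(gene = ev_gene, sample = ev_sample,
                        variant_class = variant_class,
                        position = as.character(seq_len(n_ev)),
                        impact = impact, bases = rep(1, n_ev),
                        stringsAsFactors = FALSE)
  scored_rows <- records$variant_class == "missense" & !is.na(records$impact)
  impacts <- data.frame(gene = records$gene[scored_rows],
                        sample = records$sample[scored_rows],
                        position = records$position[scored_rows],
                        score = records$impact[scored_rows],
                        stringsAsFactors = FALSE)
  coverage <- stats::setNames(
    sample(50000:200000, spec$n_genes, replace = TRUE), genes)

  structure(list(records = records, samples = samples, coverage = coverage,
                 impacts = impacts, pathways = pathways, groups = group_of,
                 truth = list(planted_sets = truth_sets,
                              dominated = dominated)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$records), " mutations, ",
      length(x$samples), " samples, ", length(x$pathways), " pathways",
      if (!is.null(x$groups)) paste0(", ", length(unique(x$groups)),
                                     " sample groups"),
      "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk in the package's file dialects
#'
#' Emits `mutations.maf`, `pathways.txt`, `coverage.tsv`, `impacts.tsv` and
#' `samples.tsv` (sample list with group assignment, `NA` when ungrouped);
#' all parse back through the companion readers.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_maf(cohort$records, file.path(dir, "mutations.maf"))
  write_pathways(cohort$pathways, file.path(dir, "pathways.txt"))
  write_coverage(cohort$coverage, file.path(dir, "coverage.tsv"))
  write_impact_table(cohort$impacts, file.path(dir, "impacts.tsv"))
  grp <- if (is.null(cohort$groups)) rep(NA_character_, length(cohort$samples))
         else unname(cohort$groups[cohort$samples])
  utils::write.table(data.frame(sample = cohort$samples, group = grp),
                     file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' Named cohort presets used throughout validation
#'
#' \describe{
#'   \item{null}{200 pathways over 200 samples with independent background
#'     mutations only; used for enrichment p-value calibration.}
#'   \item{planted_trio}{Three pathways co-mutated in an expected 60% of 500
#'     samples plus seven independent decoy pathways; used for greedy
#'     recovery.}
#'   \item{dominated}{A pathway whose coverage comes entirely from one gene
#'     mutated in 70% of samples over a near-silent background; used for the
#'     dominance filter.}
#'   \item{breast_like}{Four sample groups sized 93/57/224/124 (a
#'     four-subtype tumor cohort layout) with group-specific planted
#'     collaborative sets all sharing pathway PW001.}
#' }
#'
#' @return Named list of [cohort_spec()] objects.
#' @export
cohort_presets <- function() {
  list(
    null = cohort_spec(m_samples = 200, n_genes = 2600, n_pathways = 200,
                       genes_per_pathway = c(8, 12),
                       background_nsy_rate = 0.01,
                       background_sy_rate = 0.005),
    planted_trio = cohort_spec(m_samples = 500, n_genes = 120,
                               n_pathways = 10,
                               genes_per_pathway = c(8, 12),
                               background_nsy_rate = 0.02,
                               background_sy_rate = 0.01,
                               planted_sets = list(
                                 list(pathways = 1:3, target = 0.6))),
    dominated = cohort_spec(m_samples = 200, n_genes = 60, n_pathways = 5,
                            genes_per_pathway = c(8, 12),
                            background_nsy_rate = 0.002,
                            background_sy_rate = 0.001,
                            dominated_pathways = list(
                              list(pathway = 1, gene_coverage = 0.7))),
    breast_like = cohort_spec(n_genes = 240, n_pathways = 20,
                              genes_per_pathway = c(8, 12),
                              background_nsy_rate = 0.01,
                              background_sy_rate = 0.005,
                              groups = list(
                                "Basal-like" = list(size = 93, planted_sets =
                                  list(list(pathways = c(1, 2), target = 0.85))),
                                "HER2+" = list(size = 57, planted_sets =
                                  list(list(pathways = c(1, 3, 4), target = 0.5))),
                                "Luminal-A" = list(size = 224, planted_sets =
                                  list(list(pathways = c(1, 5, 6), target = 0.55))),
                                "Luminal-B" = list(size = 124, planted_sets =
                                  list(list(pathways = c(1, 7, 8), target = 0.45)))))
  )
}
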