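# Readers and writers for the external file formats: MAF mutation calls,
# pathway topology blocks, per-gene coverage, per-mutation impact scores,
# the run configuration, and the result tables.

variant_class_levels <- c("missense", "nonsense", "indel", "splice_site",
                          "silent", "other")

# TCGA MAF Variant_Classification vocabulary -> canonical classes.  Canonical
# names themselves are accepted so that minimal toy files round-trip.
.maf_class_map <- c(
  silent             = "silent",
  missense_mutation  = "missense",
  nonsense_mutation  = "nonsense",
  frame_shift_ins    = "indel",
  frame_shift_del    = "indel",
  in_frame_ins       = "indel",
  in_frame_del       = "indel",
  splice_site        = "splice_site",
  missense           = "missense",
  nonsense           = "nonsense",
  indel              = "indel",
  splice_site        = "splice_site"
)

.canonical_columns <- list(
  gene     = c("hugo_symbol", "gene", "gene_symbol"),
  sample   = c("tumor_sample_barcode", "sample", "sample_id", "sample_barcode"),
  class    = c("variant_classification", "variant_class", "class"),
  position = c("start_position", "position", "pos")
)

.match_column <- function(header, field, required = TRUE) {
  idx <- match(.canonical_columns[[field]], tolower(header))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    if (required)
      stop("MAF format error: no column matching '", field, "' (accepted: ",
           paste(.canonical_columns[[field]], collapse = ", "), ")",
           call. = FALSE)
    return(NA_integer_)
  }
  idx[1L]
}

#' Read somatic mutation calls from a MAF file
#'
#' Accepts standard tab-separated Mutation Annotation Format (TCGA-style
#' headers, matched case-insensitively) as well as a minimal toy dialect with
#' `gene`, `sample` and `variant_class` columns.  Variant classifications are
#' mapped onto the canonical classes `missense`, `nonsense`, `indel`,
#' `splice_site`, `silent`; anything unrecognized becomes `other` and is
#' reported via a message (such rows are kept but excluded from impact
#' scoring downstream).
#'
#' @param path Path to a tab-separated MAF file with a header line.
#' @param impact_table Optional data frame with columns `gene`, `sample`,
#'   `position`, `score` (as from [read_impact_table()]); functional impact
#'   scores are joined onto records by the `(gene, sample, position)` key.
#' @return A data frame of mutation records with columns `gene`, `sample`,
#'   `variant_class`, `position`, `impact` and `bases` (mutated base count,
#'   1 unless the file carries a usable length), one row per MAF data row in
#'   file order.
#' @seealso [read_impact_table()], [write_maf()]
#' @export
read_maf <- function(path, impact_table = NULL) {
  if (!file.exists(path)) stop("MAF file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (nrow(tab) == 0L) stop("MAF format error: file has no data rows",
                            call. = FALSE)
  header <- names(tab)
  gi <- .match_column(header, "gene")
  si <- .match_column(header, "sample")
  ci <- .match_column(header, "class")
  pi <- .match_column(header, "position", required = FALSE)

  gene   <- trimws(tab[[gi]])
  sample <- trimws(tab[[si]])
  if (any(!nzchar(gene)) || any(!nzchar(sample)))
    stop("MAF format error: empty gene symbol or sample barcode", call. = FALSE)

  raw_class <- tolower(trimws(tab[[ci]]))
  variant_class <- unname(.maf_class_map[raw_class])
  n_other <- sum(is.na(variant_class))
  variant_class[is.na(variant_class)] <- "other"
  if (n_other > 0L)
    message(n_other, " mutation record(s) with unmapped variant class kept as 'other'")

  unknown <- grepl("^unknown$|^\\?+$|^\\.$", gene, ignore.case = TRUE)
  if (any(unknown))
    message(sum(unknown), " mutation record(s) with unresolved gene symbol kept")

  position <- if (is.na(pi)) as.character(seq_len(nrow(tab))) else trimws(tab[[pi]])

  rec <- data.frame(gene = gene, sample = sample,
                    variant_class = variant_class, position = position,
                    impact = NA_real_, bases = 1,
                    stringsAsFactors = FALSE)
  if (!is.null(impact_table)) {
    key <- paste(rec$gene, rec$sample, rec$position, sep = "\r")
    tkey <- paste(impact_table$gene, impact_table$sample,
                  impact_table$position, sep = "\r")
    rec$impact <- as.numeric(impact_table$score)[match(key, tkey)]
  }
  rec
}

#' Write mutation records as a minimal MAF file
#'
#' @param records Data frame of mutation records as returned by [read_maf()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_maf <- function(records, path) {
  class_out <- c(missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
                 indel = "Frame_Shift_Del", splice_site = "Splice_Site",
                 silent = "Silent", other = "Other")
  out <- data.frame(Hugo_Symbol = records$gene,
                    Tumor_Sample_Barcode = records$sample,
                    Variant_Classification = class_out[records$variant_class],
                    Start_Position = records$position,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a pathway graph
#'
#' A named gene set with undirected topology.  Edges must join declared genes
#' and self-edges are rejected; isolated genes (no incident edge) are allowed.
#'
#' @param pathway_id Pathway identifier string.
#' @param name Human-readable pathway name.
#' @param genes Character vector of member gene symbols (at least one).
#' @param edges Two-column character matrix of undirected gene pairs
#'   (may have zero rows).
#' @return An object of class `pathway_graph`.
#' @export
pathway_graph <- function(pathway_id, name, genes, edges = NULL) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L,
            nzchar(pathway_id))
  genes <- unique(as.character(genes))
  if (length(genes) < 1L)
    stop("pathway '", pathway_id, "' declares no genes", call. = FALSE)
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2)
  edges <- matrix(as.character(edges), ncol = 2)
  if (nrow(edges) > 0L) {
    bad <- setdiff(as.vector(edges), genes)
    if (length(bad) > 0L)
      stop("pathway '", pathway_id, "' format error: edge endpoint(s) not in ",
           "gene list: ", paste(bad, collapse = ", "), call. = FALSE)
    if (any(edges[, 1] == edges[, 2]))
      stop("pathway '", pathway_id, "' format error: self-edge", call. = FALSE)
  }
  structure(list(pathway_id = pathway_id, name = as.character(name),
                 genes = genes, edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", x$pathway_id, " (", x$name, "): ",
      length(x$genes), " genes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Read pathway topologies from a plain-text block file
#'
#' The dialect is line-oriented: each pathway is a block starting with
#' `PATHWAY <id> <name...>`, followed by one or more `GENES g1 g2 ...` lines
#' and zero or more `EDGE gA gB` lines.  Blocks are separated by the next
#' `PATHWAY` line (blank lines are ignored).
#'
#' @param path Path to the pathway file.
#' @return A list of [pathway_graph()] objects in file order.
#' @export
read_pathways <- function(path) {
  if (!file.exists(path)) stop("pathway file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^PATHWAY\\b", lines)
  if (length(starts) == 0L)
    stop("pathway format error: no PATHWAY blocks found", call. = FALSE)
  if (starts[1] != 1L)
    stop("pathway format error: content before first PATHWAY line",
         call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  mapply(function(a, b) {
    head_tok <- strsplit(lines[a], "[ \t]+")[[1]]
    if (length(head_tok) < 2L)
      stop("pathway format error: PATHWAY line lacks an id", call. = FALSE)
    id <- head_tok[2]
    nm <- if (length(head_tok) > 2L) paste(head_tok[-(1:2)], collapse = " ") else id
    body <- if (b >= a + 1L) lines[(a + 1L):b] else character(0)
    toks <- strsplit(body, "[ \t]+")
    genes <- character(0); edges <- list()
    for (tk in toks) {
      if (tk[1] == "GENES") {
        genes <- c(genes, tk[-1])
      } else if (tk[1] == "EDGE") {
        if (length(tk) != 3L)
          stop("pathway '", id, "' format error: EDGE line needs two genes",
               call. = FALSE)
        edges[[length(edges) + 1L]] <- tk[2:3]
      } else {
        stop("pathway '", id, "' format error: unrecognized line '",
             paste(tk, collapse = " "), "'", call. = FALSE)
      }
    }
    edges <- if (length(edges)) do.call(rbind, edges) else NULL
    pathway_graph(id, nm, genes, edges)
  }, starts, ends, SIMPLIFY = FALSE)
}

#' Write pathway topologies in the block dialect read by [read_pathways()]
#'
#' @param pathways List of [pathway_graph()] objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pathways <- function(pathways, path) {
  blocks <- vapply(pathways, function(pw) {
    lines <- c(paste("PATHWAY", pw$pathway_id, pw$name),
               paste("GENES", paste(pw$genes, collapse = " ")))
    if (nrow(pw$edges) > 0L)
      lines <- c(lines, paste("EDGE", pw$edges[, 1], pw$edges[, 2]))
    paste(lines, collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Read a per-gene covered-base table
#'
#' Two-column tab-separated file `gene<TAB>covered_bases`; the counts are the
#' number of bases per gene with sufficient read depth (computed upstream,
#' e.g. by a coverage pipeline over alignment wiggle tracks).
#'
#' @param path Path to the coverage TSV.
#' @return A named numeric vector mapping gene symbol to covered bases.
#' @export
read_coverage <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("coverage format error: expected columns gene, covered_bases",
         call. = FALSE)
  cov <- as.numeric(tab[[2]])
  if (any(is.na(cov)) || any(cov <= 0))
    stop("coverage format error: covered_bases must be positive", call. = FALSE)
  names(cov) <- as.character(tab[[1]])
  cov
}

#' Write a per-gene covered-base table
#' @param coverage Named numeric vector (gene -> covered bases).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_coverage <- function(coverage, path) {
  utils::write.table(
    data.frame(gene = names(coverage),
               covered_bases = sprintf("%.17g", unname(coverage))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-mutation functional-impact score table
#'
#' Tab-separated with columns `gene`, `sample`, `position`, `score`; scores
#' are keyed on `(gene, sample, position)` when joined to MAF records.
#'
#' @param path Path to the impact TSV.
#' @return Data frame with columns `gene`, `sample`, `position`, `score`.
#' @export
read_impact_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "character", "numeric"))
  need <- c("gene", "sample", "position", "score")
  if (!all(need %in% tolower(names(tab))))
    stop("impact table format error: need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  names(tab) <- tolower(names(tab))
  if (any(tab$score < 0, na.rm = TRUE))
    stop("impact table format error: negative score", call. = FALSE)
  tab[, need]
}

#' Write a per-mutation functional-impact score table
#' @param impacts Data frame with columns `gene`, `sample`, `position`, `score`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_impact_table <- function(impacts, path) {
  out <- impacts[, c("gene", "sample", "position", "score")]
  out$score <- sprintf("%.17g", out$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the tunable parameters of the two-step pipeline.
#'
#' @param alpha Interaction-strength pass threshold gating contributions to
#'   the Interaction Factor (default 0.005).
#' @param n_perm_enrichment Number of membership permutations for the weighted
#'   KS enrichment p-value (default 5000).
#' @param n_perm_collab Number of mutation-redistribution permutations for the
#'   collaboration test (default 5000).
#' @param top_k_pathways Size of the candidate pool passed from the enrichment
#'   step to the greedy search (default 60).
#' @param dominance_delta Required margin of the collaborative coverage rate
#'   over the best single-gene mutation rate (default 0.05).
#' @param collab_p_threshold Strict upper bound on the collaboration
#'   permutation p-value (default 0.01).
#' @param rng_seed Master seed; all stage and group sub-seeds derive from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(alpha = 0.005, n_perm_enrichment = 5000,
                       n_perm_collab = 5000, top_k_pathways = 60,
                       dominance_delta = 0.05, collab_p_threshold = 0.01,
                       rng_seed = 1L) {
  cfg <- list(alpha = as.numeric(alpha),
              n_perm_enrichment = as.integer(n_perm_enrichment),
              n_perm_collab = as.integer(n_perm_collab),
              top_k_pathways = as.integer(top_k_pathways),
              dominance_delta = as.numeric(dominance_delta),
              collab_p_threshold = as.numeric(collab_p_threshold),
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$alpha > 0, cfg$alpha < 1,
            cfg$n_perm_enrichment >= 1L, cfg$n_perm_collab >= 1L,
            cfg$top_k_pathways >= 1L,
            cfg$dominance_delta > 0, cfg$dominance_delta < 1,
            cfg$collab_p_threshold > 0, cfg$collab_p_threshold < 1)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a flat key-value file
#'
#' One `key<TAB>value` (or `key=value`) pair per line, keys mirroring the
#' arguments of [run_config()]; missing keys take their defaults.
#'
#' @param path Path to the configuration file.
#' @return A [run_config()] object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[=\t]+")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  known <- names(formals(run_config))
  bad <- setdiff(keys, known)
  if (length(bad) > 0L)
    stop("config format error: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- as.list(as.numeric(vals))
  names(args) <- keys
  do.call(run_config, args)
}

#' Write a run configuration as a flat key-value file
#' @param cfg A [run_config()] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  writeLines(paste(names(cfg), vapply(cfg, function(v) sprintf("%.17g", v),
                                      character(1)), sep = "\t"), path)
  invisible(path)
}

#' Write pipeline results to a directory
#'
#' Emits `enrichment.tsv` (pathway_id, md, p, fdr, rank), `collaboration.tsv`
#' (step, pathway_id, mcr_after, p, max_gene_rate) and a machine-readable
#' `summary.json`.  Numeric fields are written at full double precision so
#' that [read_results()] round-trips exactly.
#'
#' @param enrichment Data frame of enrichment results (columns `pathway_id`,
#'   `md`, `p`, `fdr`, `rank`).
#' @param collab A `collaborative_set` object from [greedy_select()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, `out_dir`.
#' @export
write_results <- function(enrichment, collab, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create output directory ", out_dir, call. = FALSE)

  enr <- enrichment[, c("pathway_id", "md", "p", "fdr", "rank")]
  for (col in c("md", "p", "fdr")) enr[[col]] <- sprintf("%.17g", enr[[col]])
  utils::write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  steps <- collab$steps
  co <- data.frame(step = seq_len(nrow(steps)),
                   pathway_id = steps$pathway_id,
                   mcr_after = sprintf("%.17g", steps$mcr_after),
                   p = sprintf("%.17g", steps$p),
                   max_gene_rate = sprintf("%.17g", steps$max_gene_rate),
                   stringsAsFactors = FALSE)
  utils::write.table(co, file.path(out_dir, "collaboration.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  summary <- list(n_pathways_tested = nrow(enrichment),
                  n_selected = nrow(steps),
                  mcr = collab$mcr,
                  selected_pathways = steps$pathway_id,
                  n_covered_samples = length(collab$covered_samples),
                  m_samples = collab$m)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Read back results written by [write_results()]
#'
#' @param out_dir Directory previously populated by [write_results()].
#' @return List with elements `enrichment` (data frame), `collab` (data frame
#'   of greedy steps) and `summary` (parsed JSON list).
#' @export
read_results <- function(out_dir) {
  enr <- utils::read.delim(file.path(out_dir, "enrichment.tsv"), sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric", "integer"))
  co <- utils::read.delim(file.path(out_dir, "collaboration.tsv"), sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "character", "numeric",
                                         "numeric", "numeric"))
  summary <- jsonlite::read_json(file.path(out_dir, "summary.json"),
                                 simplifyVector = TRUE)
  list(enrichment = enr, collab = co, summary = summary)
}
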