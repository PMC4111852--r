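# Greedy construction of the collaborative driver-pathway set: coverage
# profiles, intersection coverage (MCR), single-gene-dominance filter, and
# the mutation-redistribution permutation test.

#' Coverage profile of a pathway
#'
#' A pathway covers a sample when at least one of its member genes carries a
#' non-synonymous mutation in that sample.
#'
#' @param mat A `mutation_matrix`.
#' @param pw A [pathway_graph()] sharing at least one gene with the matrix.
#' @return List with `pathway_id`, `covered_samples` (character vector) and
#'   `rate` (fraction of samples covered).
#' @export
pathway_coverage <- function(mat, pw) {
  members <- intersect(pw$genes, mat$genes)
  if (length(members) == 0L)
    stop("pathway '", pw$pathway_id, "' shares no gene with the mutation ",
         "matrix", call. = FALSE)
  hits <- colSums(mat$nsy_counts[members, , drop = FALSE]) > 0
  covered <- mat$samples[hits]
  list(pathway_id = pw$pathway_id, covered_samples = covered,
       rate = length(covered) / length(mat$samples))
}

#' Joint (intersection) coverage of a set of pathways
#'
#' The Maximal Coverage Rate of a collaborative set: the fraction of samples
#' in which every member pathway is mutated.
#'
#' @param profiles Non-empty list of coverage profiles from
#'   [pathway_coverage()].
#' @param m Total number of samples.
#' @return Intersection coverage rate in \[0, 1\].
#' @export
joint_coverage <- function(profiles, m) {
  if (length(profiles) == 0L)
    stop("joint coverage of an empty pathway set is undefined", call. = FALSE)
  inter <- Reduce(intersect, lapply(profiles, `[[`, "covered_samples"))
  length(inter) / m
}

#' Highest single-gene mutation rate within a pathway
#'
#' @inheritParams pathway_coverage
#' @return List with `gene` (ties broken alphabetically) and `rate`.
#' @export
max_single_gene_rate <- function(mat, pw) {
  members <- intersect(pw$genes, mat$genes)
  if (length(members) == 0L)
    stop("pathway '", pw$pathway_id, "' shares no gene with the mutation ",
         "matrix", call. = FALSE)
  rates <- stats::setNames(rep(0, length(pw$genes)), pw$genes)
  rates[members] <- rowSums(mat$nsy_counts[members, , drop = FALSE] > 0) /
    length(mat$samples)
  rates <- rates[order(names(rates))]
  best <- which.max(rates)
  list(gene = names(rates)[best], rate = unname(rates[best]))
}

#' Single-gene dominance check
#'
#' A candidate's collaborative coverage must exceed the mutation rate of its
#' most-mutated gene by at least `delta`, ensuring the pathway's disruption
#' is not attributable to a single gene.  The boundary passes.
#'
#' @param mcr_candidate Joint coverage rate the candidate would produce.
#' @param max_gene_rate Highest single-gene mutation rate in the candidate.
#' @param delta Required margin (default 0.05).
#' @return `TRUE` iff `mcr_candidate >= max_gene_rate + delta`.
#' @export
dominance_ok <- function(mcr_candidate, max_gene_rate, delta = 0.05) {
  stopifnot(mcr_candidate >= 0, mcr_candidate <= 1,
            max_gene_rate >= 0, max_gene_rate <= 1, delta >= 0, delta <= 1)
  mcr_candidate >= max_gene_rate + delta
}

#' Mutation-redistribution permutation test for pathway collaboration
#'
#' Tests whether the candidate pathway's joint coverage with the already
#' selected set exceeds chance: every non-synonymous mutation event of the
#' candidate's genes is independently reassigned to a uniformly random
#' sample (with replacement, preserving the total event count), the
#' background MCR is the fraction of samples covered by the permuted
#' candidate and by every already-selected pathway (selected coverages fixed
#' at their observed values), and
#' \deqn{p = \#\{MCR_{bg} \ge MCR_{obs}\} / n_{perm}}
#' Coverage comparisons are made on integer covered-sample counts.  When the
#' full assignment space \eqn{m^K} (K = candidate event count) is small the
#' p-value is computed by exact enumeration instead of sampling.
#'
#' @param mat A `mutation_matrix`.
#' @param candidate A [pathway_graph()], the pathway under test.
#' @param selected_profiles List of coverage profiles of the already
#'   selected pathways (may be empty, in which case the base set is all
#'   samples).
#' @param n_perm Number of redistribution permutations.
#' @param exact `TRUE`, `FALSE`, or `"auto"` (exact when \eqn{m^K \le 10^4}).
#' @return Permutation p-value; 1 by convention for a candidate with no
#'   mutations.  Monte-Carlo mode consumes the current RNG stream.
#' @export
collab_pvalue <- function(mat, candidate, selected_profiles, n_perm = 5000,
                          exact = "auto") {
  stopifnot(n_perm >= 1)
  m <- length(mat$samples)
  members <- intersect(candidate$genes, mat$genes)
  k_events <- if (length(members) == 0L) 0L
              else sum(mat$nsy_counts[members, , drop = FALSE])
  if (k_events == 0L) return(1)

  base <- if (length(selected_profiles) == 0L) mat$samples
          else Reduce(intersect, lapply(selected_profiles,
                                        `[[`, "covered_samples"))
  base_idx <- mat$samples %in% base
  cand <- pathway_coverage(mat, candidate)
  obs_cnt <- sum(cand$covered_samples %in% base)

  do_exact <- if (identical(exact, "auto")) m^k_events <= 1e4 else isTRUE(exact)
  if (do_exact) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(m)), k_events)))
    bg_cnt <- apply(grid, 1L, function(a) sum(base_idx[unique.default(a)]))
    return(mean(bg_cnt >= obs_cnt))
  }
  draws <- matrix(sample.int(m, k_events * n_perm, replace = TRUE),
                  nrow = k_events)
  bg_cnt <- vapply(seq_len(n_perm), function(i)
    sum(base_idx[unique.default(draws[, i])]), numeric(1))
  mean(bg_cnt >= obs_cnt)
}

#' Greedy selection of a collaborative driver-pathway set
#'
#' Starts from the candidate with the highest coverage rate that passes the
#' dominance filter (the first pathway is exempt from the collaboration
#' test, having no partners).  At each subsequent step the unselected
#' candidates are ordered by the joint coverage they would produce with the
#' current set (ties by candidate-pool order); the best one passing both the
#' dominance filter and the redistribution permutation test
#' (`p < collab_p_threshold`, strict) is added.  The search stops when no
#' candidate qualifies.  In unconstrained mode both filters are dropped and
#' pathways are added by decreasing joint coverage until it reaches zero.
#'
#' @param mat A `mutation_matrix`.
#' @param candidates Ordered list of [pathway_graph()] objects (e.g. the top
#'   enriched pathways); the order is the tie-break.
#' @param cfg A [run_config()]; uses `dominance_delta`,
#'   `collab_p_threshold`, `n_perm_collab` and the current RNG stream.
#' @param constrained Set `FALSE` for the unconstrained greedy variant.
#' @return An object of class `collaborative_set`: `steps` (data frame
#'   `pathway_id`, `mcr_after`, `p`, `max_gene_rate`), `covered_samples`
#'   (intersection of the selected coverages), `mcr` and `m`.  Zero steps is
#'   a legal result.
#' @export
greedy_select <- function(mat, candidates, cfg = run_config(),
                          constrained = TRUE) {
  stopifnot(length(candidates) >= 1L)
  m <- length(mat$samples)
  ids <- vapply(candidates, `[[`, character(1), "pathway_id")

  profiles <- vector("list", length(candidates))
  gene_rate <- numeric(length(candidates))
  usable <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    prof <- tryCatch(pathway_coverage(mat, candidates[[i]]),
                     error = function(e) NULL)
    if (is.null(prof)) next
    usable[i] <- TRUE
    profiles[[i]] <- prof
    gene_rate[i] <- max_single_gene_rate(mat, candidates[[i]])$rate
  }

  selected <- integer(0)
  steps <- list()
  base <- mat$samples

  repeat {
    remaining <- setdiff(which(usable), selected)
    if (length(remaining) == 0L) break
    joint_cnt <- vapply(remaining, function(i)
      sum(profiles[[i]]$covered_samples %in% base), numeric(1))
    ord <- remaining[order(-joint_cnt, match(remaining, seq_along(ids)))]

    picked <- NA_integer_
    for (i in ord) {
      mcr_cand <- sum(profiles[[i]]$covered_samples %in% base) / m
      if (constrained) {
        if (!dominance_ok(mcr_cand, gene_rate[i], cfg$dominance_delta)) next
        if (length(selected) > 0L) {
          p <- collab_pvalue(mat, candidates[[i]], profiles[selected],
                             cfg$n_perm_collab)
          if (!(p < cfg$collab_p_threshold)) next
        } else p <- NA_real_
      } else {
        if (mcr_cand <= 0) next
        p <- NA_real_
      }
      picked <- i
      steps[[length(steps) + 1L]] <- data.frame(
        pathway_id = ids[i], mcr_after = mcr_cand, p = p,
        max_gene_rate = gene_rate[i], stringsAsFactors = FALSE)
      break
    }
    if (is.na(picked)) break
    selected <- c(selected, picked)
    base <- intersect(base, profiles[[picked]]$covered_samples)
  }

  steps <- if (length(steps)) do.call(rbind, steps)
           else data.frame(pathway_id = character(0), mcr_after = numeric(0),
                           p = numeric(0), max_gene_rate = numeric(0),
                           stringsAsFactors = FALSE)
  covered <- if (length(selected)) base else character(0)
  mcr <- if (length(selected)) length(covered) / m else NA_real_
  if (nrow(steps) > 1L)
    stopifnot(all(diff(steps$mcr_after) <= 1e-12))  # MCR never increases
  structure(list(steps = steps, covered_samples = covered, mcr = mcr, m = m),
            class = "collaborative_set")
}

#' @export
print.collaborative_set <- function(x, ...) {
  if (nrow(x$steps) == 0L) {
    cat("<collaborative_set> empty (no qualifying pathway)\n")
    return(invisible(x))
  }
  cat("<collaborative_set> ", nrow(x$steps), " pathway(s), MCR = ",
      sprintf("%.3f", x$mcr), " (", length(x$covered_samples), "/", x$m,
      " samples)\n", sep = "")
  print(x$steps, row.names = FALSE)
  invisible(x)
}
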