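# Gene ranking (MF x IF), score imputation for out-of-pathway genes, the
# weighted Kolmogorov-Smirnov enrichment statistic with a membership
# permutation null, and rank-based FDR.

#' Combined gene ranking score
#'
#' \deqn{score = e^{MF} \cdot IF}
#' The exponential maps the (possibly negative) Mutation Factor to a positive
#' multiplier so that the score is strictly positive and strictly increasing
#' in both factors.
#'
#' @param mf Mutation factor (any real); vectorized.
#' @param if_value Interaction factor, strictly inside (0, 1); vectorized.
#' @return Positive ranking score(s).
#' @export
ranking_score <- function(mf, if_value) {
  if (any(if_value <= 0 | if_value >= 1))
    stop("interaction factor must lie strictly in (0, 1)", call. = FALSE)
  exp(mf) * if_value
}

#' Impute ranking scores for genes outside a pathway
#'
#' Out-of-pathway genes have no topology, so their interaction contribution
#' is imputed: with probability `pass_rate` (the fraction of in-pathway genes
#' whose interaction factor had at least one passing partner) a score is
#' drawn from the cohort-wide background Normal(`background_mean`,
#' `background_sd`) truncated below at a small positive floor; otherwise the
#' gene receives the non-passing fallback \eqn{e^{MF} \cdot \alpha}.  Keeping
#' the passing fraction equal inside and outside the pathway avoids an
#' artificial ranking bias toward pathway members.
#'
#' @param mf Numeric vector of mutation factors for the outside genes.
#' @param background_mean,background_sd Mean and standard deviation of all
#'   non-imputed gene scores across all pathways.
#' @param pass_rate Probability of a passing event, in \[0, 1\].
#' @param alpha Interaction pass threshold (the non-passing fallback scale).
#' @param floor Lower truncation for the Gaussian draws (default `1e-12`).
#' @return Data frame with columns `score` (positive) and `imputed`
#'   (`TRUE` throughout), one row per element of `mf`.  Draws consume the
#'   current RNG stream.
#' @export
impute_outside_scores <- function(mf, background_mean, background_sd,
                                  pass_rate, alpha = 0.005, floor = 1e-12) {
  stopifnot(background_sd >= 0, pass_rate >= 0, pass_rate <= 1)
  n <- length(mf)
  passing <- if (pass_rate == 0) rep(FALSE, n)
             else if (pass_rate == 1) rep(TRUE, n)
             else stats::runif(n) < pass_rate
  score <- exp(mf) * alpha
  if (any(passing))
    score[passing] <- pmax(stats::rnorm(sum(passing), background_mean,
                                        background_sd), floor)
  data.frame(score = score, imputed = TRUE)
}

#' Construct a ranked gene list for one pathway
#'
#' @param pathway_id Pathway identifier.
#' @param genes Gene symbols.
#' @param scores Positive ranking scores aligned to `genes`.
#' @param member Logical membership flags aligned to `genes`.
#' @return A `ranked_list` object: genes sorted by decreasing score (ties
#'   broken by gene symbol for determinism) with aligned membership flags.
#' @export
ranked_list <- function(pathway_id, genes, scores, member) {
  stopifnot(length(genes) == length(scores), length(genes) == length(member))
  if (any(scores <= 0)) stop("ranking scores must be positive", call. = FALSE)
  if (!any(member) || all(member))
    stop("ranked list needs at least one member and one non-member",
         call. = FALSE)
  o <- order(-scores, genes)
  structure(list(pathway_id = pathway_id, genes = genes[o],
                 scores = scores[o], member = member[o]),
            class = "ranked_list")
}

#' Weighted Kolmogorov-Smirnov maximum deviation
#'
#' Walking the ranked list from the top, the member (hit) CDF accumulates
#' member scores normalized by their total, while the non-member (miss) CDF
#' takes uniform steps of \eqn{1/N_{\notin P}}.  The statistic is the maximum
#' absolute deviation (MD) between the two running CDFs.
#'
#' @param rl A [ranked_list()].
#' @return MD in \[0, 1\].
#' @export
wks_statistic <- function(rl) {
  w <- rl$scores * rl$member
  tot <- sum(w)
  if (tot <= 0) stop("zero total member score: corrupted ranked list",
                     call. = FALSE)
  hit <- cumsum(w) / tot
  miss <- cumsum(!rl$member) / sum(!rl$member)
  max(abs(hit - miss))
}

# MD for permuted member positions, evaluated only at the deviation's
# corner points (just after each member and just before the next), which is
# exact because the deviation is piecewise decreasing between members.
.wks_perm_md <- function(w, p, n_perm) {
  N <- length(w)
  n_miss <- N - p
  ks <- seq_len(p)
  vapply(seq_len(n_perm), function(i) {
    q <- sort.int(sample.int(N, p))
    s <- cumsum(w[q])
    s <- s / s[p]
    a <- s - (q - ks) / n_miss
    qn <- c(q[-1L], N + 1L)
    b <- s - (qn - 1L - ks) / n_miss
    max(abs(c(a, b, (q[1L] - 1L) / n_miss)))
  }, numeric(1))
}

#' Membership-permutation p-value for a ranked list
#'
#' Fast label-shuffle approximation applicable to any ranked list:
#' membership flags are shuffled uniformly over the ranked positions while
#' scores stay fixed (the null that membership is unrelated to score), the
#' MD recomputed for each permutation, and
#' \deqn{p = \frac{\#\{MD_{perm} \ge MD_{obs}\} + 1}{n_{perm} + 1}}
#' The +1 smoothing keeps p strictly positive so the FDR ordering is
#' well defined.  Member count is conserved in every permutation.  Note
#' this scheme assumes member scores carry no pathway-level common factor;
#' the pipeline itself uses the calibrated [wks_gene_perm_test()].
#'
#' @param rl A [ranked_list()].
#' @param n_perm Number of permutations (>= 1).
#' @return List with `pathway_id`, `md` (observed) and `p`.  Consumes the
#'   current RNG stream.
#' @export
enrichment_pvalue <- function(rl, n_perm = 5000) {
  stopifnot(n_perm >= 1)
  md_obs <- wks_statistic(rl)
  perm <- .wks_perm_md(rl$scores, sum(rl$member), n_perm)
  list(pathway_id = rl$pathway_id, md = md_obs,
       p = (sum(perm >= md_obs - 1e-12) + 1) / (n_perm + 1))
}

# MD from member scores placed into the fixed, descending-sorted outside
# list.  `s_desc` are member scores sorted decreasing, `c_before[i]` the
# number of outside genes ranked above member i (members are placed after
# equal-scoring outside genes), `n_out` the outside-list length.  Corner
# evaluation is exact: the deviation only jumps up at member positions and
# decays linearly between them.
.wks_md_placed <- function(s_desc, c_before, n_out) {
  h <- cumsum(s_desc)
  h <- h / h[length(h)]
  c_next <- c(c_before[-1L], n_out)
  max(abs(c(h - c_before / n_out, h - c_next / n_out)), c_before[1L] / n_out)
}

#' Gene-set permutation test for pathway enrichment
#'
#' The calibrated permutation scheme used by the pipeline: each permutation
#' draws a random gene set of the pathway's size from the cohort, places it
#' on the pathway's own topology, recomputes the Interaction Factors and
#' ranking scores from those genes' mutation profiles, and re-evaluates the
#' weighted KS maximum deviation against the fixed list of imputed
#' outside-gene scores.  On a cohort with no pathway-linked mutational
#' structure the pathway's member genes are exchangeable with a random draw,
#' so observed and permuted statistics share one distribution and the
#' p-value is calibrated; a pathway whose genes carry elevated or mutually
#' exclusive non-synonymous mutations beats the permutations.  Members are
#' placed after equal-scoring outside genes in both the observed and
#' permuted walks.
#'
#' The permutation distribution of MD has atoms in sparse cohorts (many
#' draws consist of unmutated or non-overlapping genes and give identical
#' statistics), so exact ties with the observed MD are broken uniformly at
#' random:
#' \deqn{p = \frac{\#\{MD_{perm} > MD_{obs}\} + U \cdot \#\{MD_{perm} =
#'   MD_{obs}\} + 1}{n_{perm} + 1}, \quad U \sim \mathrm{Unif}(0,1)}
#' which is valid and uniform up to the +1 smoothing.
#'
#' @param pw A [pathway_graph()] with at least two genes.
#' @param mat A `mutation_matrix`.
#' @param mf_all Named mutation-factor vector over `mat$genes` (from
#'   [mutation_factors()]).
#' @param outside_scores Positive scores of the non-member genes (imputed;
#'   fixed across permutations).
#' @param n_perm Number of permutations (>= 1).
#' @param alpha Interaction pass threshold.
#' @return List with `pathway_id`, `md` (observed maximum deviation) and
#'   `p`.  Consumes the current RNG stream.
#' @export
wks_gene_perm_test <- function(pw, mat, mf_all, outside_scores,
                               n_perm = 5000, alpha = 0.005) {
  stopifnot(n_perm >= 1, all(outside_scores > 0))
  inv_d <- 1 / (1 + pathway_distances(pw))
  x_obs <- .nsy_indicator(mat, pw$genes)
  members <- intersect(pw$genes, mat$genes)
  if (length(members) == 0L)
    stop("pathway '", pw$pathway_id, "' shares no gene with the matrix",
         call. = FALSE)
  member_rows <- match(members, pw$genes)
  k <- nrow(x_obs)
  m <- ncol(x_obs)
  n_out <- length(outside_scores)
  a_sorted <- sort.int(outside_scores, method = "radix")
  ind_all <- unname(mat$nsy_counts > 0) * 1
  exp_mf_all <- exp(unname(mf_all))
  km1 <- k - 1

  md_of <- function(x_num, r, exp_mf, rows) {
    rsum <- outer(r, r, "+")
    both <- tcrossprod(x_num)
    uni <- rsum - both
    excl <- rsum - 2 * both
    memat <- excl / uni
    memat[uni == 0] <- 0
    f <- (excl / m) * memat * inv_d
    diag(f) <- 0
    pass <- f >= alpha
    if_val <- rowSums(f * pass) / km1
    if_val[rowSums(pass) == 0] <- alpha
    s <- sort.int(exp_mf * if_val[rows], decreasing = TRUE, method = "radix")
    c_before <- n_out - findInterval(s, a_sorted, left.open = TRUE)
    .wks_md_placed(s, c_before, n_out)
  }

  x_num <- x_obs * 1
  md_obs <- md_of(x_num, rowSums(x_num), exp(unname(mf_all[members])),
                  member_rows)
  n_univ <- nrow(ind_all)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n_univ, k)
    x <- ind_all[idx, , drop = FALSE]
    md_of(x, rowSums(x), exp_mf_all[idx], seq_len(k))
  }, numeric(1))
  gt <- sum(perm > md_obs + 1e-12)
  eq <- sum(abs(perm - md_obs) <= 1e-12)
  list(pathway_id = pw$pathway_id, md = md_obs,
       p = (gt + stats::runif(1) * eq + 1) / (n_perm + 1))
}

#' Rank-based FDR correction
#'
#' Pathways are sorted by increasing p (ties by pathway id) and assigned
#' ranks \eqn{k = 1, 2, \ldots}; the false discovery rate is
#' \eqn{FDR = p \cdot m_{total} / k}, capped at one, with a running maximum
#' down the list so the reported FDR is non-decreasing in p.
#'
#' @param results Data frame with columns `pathway_id`, `md`, `p`.
#' @param m_total Total number of pathways tested (defaults to
#'   `nrow(results)`).
#' @return The data frame sorted by p with `rank` and `fdr` columns added.
#' @export
fdr_correct <- function(results, m_total = nrow(results)) {
  stopifnot(m_total >= nrow(results))
  o <- order(results$p, results$pathway_id)
  res <- results[o, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res$fdr <- cummax(pmin(res$p * m_total / res$rank, 1))
  rownames(res) <- NULL
  res
}

#' Select the top pathways for the collaboration step
#'
#' @param results Enrichment result data frame (`pathway_id`, `md`, `p`).
#' @param k Pool size; fewer are returned if fewer exist.
#' @return Character vector of pathway ids ordered by increasing p, ties
#'   broken by larger MD then pathway id.
#' @export
select_top_pathways <- function(results, k = 60) {
  stopifnot(k >= 1)
  o <- order(results$p, -results$md, results$pathway_id)
  utils::head(results$pathway_id[o], k)
}

#' Mutational enrichment analysis over a pathway collection
#'
#' Runs the full ranking-and-testing stage: per-pathway Interaction Factors,
#' combined ranking scores for member genes, cohort-wide background
#' parameterization, score imputation for outside genes, the weighted KS
#' statistic with mutation-status permutation p-values
#' (see [wks_gene_perm_test()]) and FDR.
#'
#' @param mat A `mutation_matrix` over the gene universe.
#' @param pathways List of [pathway_graph()] objects.
#' @param cfg A [run_config()]; uses `alpha`, `n_perm_enrichment` and the
#'   current RNG stream (seed it from `cfg$rng_seed` upstream for
#'   reproducibility).
#' @param m_total Total pathways for the FDR denominator (defaults to the
#'   number actually tested).
#' @param keep_ranked_lists Keep the per-pathway ranked gene lists in the
#'   result (for inspection or debugging).
#' @return List with `results` (data frame `pathway_id`, `md`, `p`, `fdr`,
#'   `rank`), `member_scores` (per-pathway member gene score tables) and
#'   optionally `ranked_lists`.
#' @export
enrich_pathways <- function(mat, pathways, cfg = run_config(),
                            m_total = NULL, keep_ranked_lists = FALSE) {
  mf_all <- mutation_factors(mat)
  universe <- mat$genes

  member_scores <- list()
  for (pw in pathways) {
    members <- intersect(pw$genes, universe)
    if (length(members) == 0L || length(members) == length(universe)) {
      warning("pathway '", pw$pathway_id,
              "' skipped: no usable member/non-member split", call. = FALSE)
      next
    }
    if (length(pw$genes) < 2L) {
      warning("pathway '", pw$pathway_id, "' skipped: single gene",
              call. = FALSE)
      next
    }
    ifs <- pathway_interaction_factors(pw, mat, cfg$alpha)
    member_scores[[pw$pathway_id]] <- data.frame(
      gene = members,
      mf = unname(mf_all[members]),
      if_value = ifs[members, "value"],
      n_passing = ifs[members, "n_passing"],
      score = ranking_score(mf_all[members], ifs[members, "value"]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(member_scores) == 0L)
    stop("no testable pathway (need >= 2 genes with a member/non-member split)",
         call. = FALSE)

  all_scores <- unlist(lapply(member_scores, `[[`, "score"), use.names = FALSE)
  bg_mean <- mean(all_scores)
  bg_sd <- if (length(all_scores) > 1L) stats::sd(all_scores) else 0

  rows <- vector("list", length(member_scores))
  rls <- if (keep_ranked_lists) vector("list", length(member_scores)) else NULL
  for (i in seq_along(member_scores)) {
    pid <- names(member_scores)[i]
    ms <- member_scores[[i]]
    outside <- setdiff(universe, ms$gene)
    pass_rate <- mean(ms$n_passing > 0)
    imp <- impute_outside_scores(mf_all[outside], bg_mean, bg_sd, pass_rate,
                                 cfg$alpha)
    pw <- pathways[[match(pid, vapply(pathways, `[[`, character(1),
                                      "pathway_id"))]]
    pv <- wks_gene_perm_test(pw, mat, mf_all, imp$score,
                             cfg$n_perm_enrichment, cfg$alpha)
    rows[[i]] <- data.frame(pathway_id = pid, md = pv$md, p = pv$p,
                            stringsAsFactors = FALSE)
    if (keep_ranked_lists)
      rls[[i]] <- ranked_list(pid,
                              genes = c(ms$gene, outside),
                              scores = c(ms$score, imp$score),
                              member = c(rep(TRUE, nrow(ms)),
                                         rep(FALSE, length(outside))))
  }
  results <- do.call(rbind, rows)
  if (is.null(m_total)) m_total <- nrow(results)
  out <- list(results = fdr_correct(results, m_total),
              member_scores = member_scores,
              background = c(mean = bg_mean, sd = bg_sd))
  if (keep_ranked_lists) {
    names(rls) <- names(member_scores)
    out$ranked_lists <- rls
  }
  out
}
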