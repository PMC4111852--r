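# Topology-aware Interaction Factor (IF): shortest-path distance, pairwise
# sample coverage and mutual exclusivity combined into a per-gene,
# per-pathway interaction score.

.pathway_igraph <- function(pw) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(pw$genes), name = pw$genes)
  if (nrow(pw$edges) > 0L)
    g <- igraph::add_edges(g, t(pw$edges))
  g
}

#' All-pairs shortest-path distances within a pathway
#'
#' Unweighted hop counts over the pathway's undirected topology; `Inf` for
#' gene pairs in different connected components.
#'
#' @param pw A [pathway_graph()].
#' @return Symmetric numeric matrix over `pw$genes`.
#' @export
pathway_distances <- function(pw) {
  d <- igraph::distances(.pathway_igraph(pw))
  d[pw$genes, pw$genes, drop = FALSE]
}

#' Shortest-path distance between two pathway genes
#'
#' @param pw A [pathway_graph()].
#' @param gi,gj Gene symbols, both members of `pw`.
#' @return Non-negative hop count, or `Inf` if disconnected.
#' @export
shortest_distance <- function(pw, gi, gj) {
  for (g in c(gi, gj))
    if (!g %in% pw$genes)
      stop("gene not in pathway '", pw$pathway_id, "': ", g, call. = FALSE)
  pathway_distances(pw)[gi, gj]
}

# Logical gene x sample indicator of non-synonymous mutation; genes absent
# from the matrix are treated as unmutated rows.
.nsy_indicator <- function(mat, genes) {
  ind <- matrix(FALSE, length(genes), length(mat$samples),
                dimnames = list(genes, mat$samples))
  present <- intersect(genes, mat$genes)
  ind[present, ] <- mat$nsy_counts[present, , drop = FALSE] > 0
  ind
}

#' Pairwise covered-sample fraction
#'
#' Fraction of samples in which exactly one of the two genes carries a
#' non-synonymous mutation.
#'
#' @param mat A `mutation_matrix`.
#' @param gi,gj Gene symbols present in the matrix.
#' @return Value in \[0, 1\].
#' @export
pairwise_coverage <- function(mat, gi, gj) {
  .check_gene(mat, gi); .check_gene(mat, gj)
  ind <- .nsy_indicator(mat, c(gi, gj))
  mean(xor(ind[1, ], ind[2, ]))
}

#' Pairwise mutual exclusivity
#'
#' Number of samples in which exactly one of the two genes is
#' non-synonymously mutated, divided by the number of samples in which at
#' least one is; zero when neither gene is mutated anywhere.
#'
#' @inheritParams pairwise_coverage
#' @return Value in \[0, 1\].
#' @export
mutual_exclusivity <- function(mat, gi, gj) {
  .check_gene(mat, gi); .check_gene(mat, gj)
  ind <- .nsy_indicator(mat, c(gi, gj))
  excl <- sum(xor(ind[1, ], ind[2, ]))
  uni <- sum(ind[1, ] | ind[2, ])
  if (uni == 0L) 0 else excl / uni
}

#' Pairwise interaction strength
#'
#' Combines co-coverage, mutual exclusivity and topological distance:
#' \deqn{f_{ij} = \frac{C_{ij} \cdot ME_{ij}}{1 + d_{ij}}}
#' increasing with co-coverage and exclusivity and decaying with hop
#' distance; zero for disconnected pairs (no functional route, no
#' influence).  Bounded in \[0, 1) so that averaging keeps the Interaction
#' Factor inside (0, 1).
#'
#' @param d Shortest-path distance (non-negative, possibly `Inf`).
#' @param c Pairwise covered-sample fraction in \[0, 1\].
#' @param me Mutual exclusivity in \[0, 1\].
#' @return Interaction strength in \[0, 1). Vectorized over its arguments.
#' @export
interaction_strength <- function(d, c, me) {
  f <- (c * me) / (1 + d)
  f[is.infinite(d)] <- 0
  f
}

#' Interaction Factor of a gene within a pathway
#'
#' The average mutational influence the gene imposes on the rest of the
#' pathway: pairwise strengths \eqn{f_{ij}} are summed over partners passing
#' the threshold \eqn{\alpha} and divided by the number of partners
#' (\eqn{|genes| - 1}); failing partners contribute zero but stay in the
#' denominator.  When no partner passes, the factor is floored at
#' \eqn{\alpha} so that it remains strictly positive.
#'
#' @param pw A [pathway_graph()] with at least two genes.
#' @param mat A `mutation_matrix`; pathway genes absent from it are treated
#'   as unmutated.
#' @param gene Gene symbol, a member of `pw`.
#' @param alpha Pass threshold in (0, 1).
#' @return List with `gene`, `pathway_id`, `value` (in (0, 1)) and
#'   `n_passing` (partners with \eqn{f_{ij} \ge \alpha}).
#' @export
interaction_factor <- function(pw, mat, gene, alpha = 0.005) {
  res <- pathway_interaction_factors(pw, mat, alpha)
  if (!gene %in% rownames(res))
    stop("gene not in pathway '", pw$pathway_id, "': ", gene, call. = FALSE)
  list(gene = gene, pathway_id = pw$pathway_id,
       value = res[gene, "value"], n_passing = res[gene, "n_passing"])
}

#' Interaction Factors for every gene of a pathway
#'
#' Vectorized form of [interaction_factor()]; computes the distance matrix
#' and pairwise statistics once for the whole pathway.
#'
#' @inheritParams interaction_factor
#' @return Numeric matrix over `pw$genes` with columns `value` and
#'   `n_passing`.
#' @export
pathway_interaction_factors <- function(pw, mat, alpha = 0.005) {
  k <- length(pw$genes)
  if (k < 2L)
    stop("pathway '", pw$pathway_id,
         "' has a single gene; interaction factor undefined", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  inv_d <- 1 / (1 + pathway_distances(pw))   # 0 for disconnected pairs
  x <- .nsy_indicator(mat, pw$genes)
  .if_from_indicator(x, inv_d, alpha)
}

# Core IF computation from a gene x sample mutation indicator and the
# precomputed 1/(1+d) matrix; shared by the public accessor and the
# mutation-status permutation test.
.if_from_indicator <- function(x, inv_d, alpha) {
  k <- nrow(x); m <- ncol(x)
  r <- rowSums(x)
  both <- tcrossprod(x * 1)                # co-mutated sample counts
  rsum <- outer(r, r, "+")
  uni <- rsum - both
  excl <- rsum - 2 * both
  memat <- excl / uni
  memat[uni == 0] <- 0
  f <- (excl / m) * memat * inv_d
  diag(f) <- 0
  pass <- f >= alpha
  value <- rowSums(f * pass) / (k - 1)
  n_passing <- rowSums(pass)
  value[n_passing == 0] <- alpha
  cbind(value = value, n_passing = n_passing)
}
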