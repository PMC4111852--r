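# Fixture builders and independent brute-force oracles used across tests.
# Oracles are deliberately written as plain loops/enumerations, independent
# of the package's vectorized code paths.

# Assemble a mutation_matrix directly from count/impact matrices.
make_matrix <- function(nsy_counts, sy_counts = NULL, nsy = NULL, sy = NULL) {
  if (is.null(rownames(nsy_counts)))
    rownames(nsy_counts) <- paste0("g", seq_len(nrow(nsy_counts)))
  if (is.null(colnames(nsy_counts)))
    colnames(nsy_counts) <- paste0("s", seq_len(ncol(nsy_counts)))
  zero <- array(0, dim(nsy_counts), dimnames(nsy_counts))
  if (is.null(sy_counts)) sy_counts <- zero
  if (is.null(nsy)) nsy <- nsy_counts
  if (is.null(sy)) sy <- sy_counts
  dimnames(sy_counts) <- dimnames(nsy) <- dimnames(sy) <- dimnames(nsy_counts)
  structure(list(genes = rownames(nsy_counts), samples = colnames(nsy_counts),
                 nsy = nsy, sy = sy, nsy_counts = nsy_counts,
                 sy_counts = sy_counts,
                 bounds = impact_bounds(5, 0, 2.5)),
            class = "mutation_matrix")
}

# Indicator matrix (genes x samples) from a list of per-gene mutated-sample
# index vectors.
indicator_matrix <- function(sample_sets, m, genes = names(sample_sets)) {
  x <- matrix(0L, length(sample_sets), m,
              dimnames = list(genes, paste0("s", seq_len(m))))
  for (i in seq_along(sample_sets)) x[i, sample_sets[[i]]] <- 1L
  x
}

# Exhaustive position-by-position walk of the weighted KS deviation on an
# already-ranked list.
wks_scan_oracle <- function(scores, member) {
  total <- 0
  for (i in seq_along(scores)) if (member[i]) total <- total + scores[i]
  n_miss <- sum(!member)
  best <- 0; hit <- 0; miss <- 0
  for (i in seq_along(scores)) {
    if (member[i]) hit <- hit + scores[i] / total else miss <- miss + 1 / n_miss
    dev <- abs(hit - miss)
    if (dev > best) best <- dev
  }
  best
}

random_ranked_list <- function(n, id = "pw") {
  repeat {
    member <- runif(n) < runif(1, 0.1, 0.9)
    if (any(member) && !all(member)) break
  }
  ranked_list(id, genes = sprintf("g%03d", seq_len(n)),
              scores = rexp(n) + 1e-6, member = member)
}

# Set-based oracles for the pairwise statistics.
c_oracle <- function(si, sj, m) {
  excl <- 0
  for (s in seq_len(m))
    if (xor(s %in% si, s %in% sj)) excl <- excl + 1
  excl / m
}

me_oracle <- function(si, sj, m) {
  excl <- 0; uni <- 0
  for (s in seq_len(m)) {
    in_i <- s %in% si; in_j <- s %in% sj
    if (in_i || in_j) uni <- uni + 1
    if (xor(in_i, in_j)) excl <- excl + 1
  }
  if (uni == 0) 0 else excl / uni
}

# Independent Monte-Carlo mutation-redistribution p-value (plain loop).
collab_p_oracle <- function(k_events, base_idx, obs_cnt, m, n_perm) {
  hits <- 0
  for (r in seq_len(n_perm)) {
    assigned <- sample.int(m, k_events, replace = TRUE)
    cnt <- sum(base_idx[unique(assigned)])
    if (cnt >= obs_cnt) hits <- hits + 1
  }
  hits / n_perm
}

# Exhaustive subset search for the best collaborative set: maximize
# (size, joint MCR) over subsets whose every member passes dominance, and,
# for subsets of size >= 2, whose every member passes an independent
# redistribution significance test against the rest of the subset.
greedy_oracle <- function(mat, pathways, delta, p_threshold, n_perm) {
  n <- length(pathways)
  m <- length(mat$samples)
  cov <- matrix(FALSE, n, m)
  gene_rate <- numeric(n)
  events <- numeric(n)
  for (i in seq_len(n)) {
    prof <- pathway_coverage(mat, pathways[[i]])
    cov[i, ] <- mat$samples %in% prof$covered_samples
    gene_rate[i] <- max_single_gene_rate(mat, pathways[[i]])$rate
    members <- intersect(pathways[[i]]$genes, mat$genes)
    events[i] <- sum(mat$nsy_counts[members, , drop = FALSE])
  }
  best <- list(size = 0, mcr = -1, subset = integer(0))
  for (mask in seq_len(2^n - 1)) {
    subset <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    joint <- rep(TRUE, m)
    for (i in subset) joint <- joint & cov[i, ]
    mcr <- sum(joint) / m
    if (!all(mcr >= gene_rate[subset] + delta)) next
    if (length(subset) >= 2) {
      ok <- TRUE
      for (i in subset) {
        others <- setdiff(subset, i)
        base_idx <- rep(TRUE, m)
        for (j in others) base_idx <- base_idx & cov[j, ]
        obs_cnt <- sum(base_idx & cov[i, ])
        p <- collab_p_oracle(events[i], base_idx, obs_cnt, m, n_perm)
        if (!(p < p_threshold)) { ok <- FALSE; break }
      }
      if (!ok) next
    }
    if (length(subset) > best$size ||
        (length(subset) == best$size && mcr > best$mcr))
      best <- list(size = length(subset), mcr = mcr, subset = subset)
  }
  best
}
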