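path_abc <- pathway_graph("p", "path A-B-C", c("A", "B", "C"),
                          rbind(c("A", "B"), c("B", "C")))

test_that("shortest distances are hop counts, Inf across components", {
  expect_equal(shortest_distance(path_abc, "A", "C"), 2)
  expect_equal(shortest_distance(path_abc, "A", "A"), 0)
  pw <- pathway_graph("q", "q", c("A", "B", "C"), rbind(c("A", "B")))
  expect_equal(shortest_distance(pw, "A", "C"), Inf)
  expect_error(shortest_distance(pw, "A", "Z"), "not in pathway")
})

test_that("pairwise coverage counts exclusively mutated samples", {
  x <- indicator_matrix(list(gi = c(1, 2), gj = c(2, 3)), m = 4)
  mat <- make_matrix(x)
  expect_equal(pairwise_coverage(mat, "gi", "gj"), 0.5)

  same <- make_matrix(indicator_matrix(list(a = c(1, 3), b = c(1, 3)), m = 4))
  expect_equal(pairwise_coverage(same, "a", "b"), 0)

  disj <- make_matrix(indicator_matrix(list(a = 1, b = 2), m = 2))
  expect_equal(pairwise_coverage(disj, "a", "b"), 1)
})

test_that("mutual exclusivity is exclusive over union, 0 on empty union", {
  mat <- make_matrix(indicator_matrix(list(gi = c(1, 2), gj = c(2, 3)), m = 4))
  expect_equal(mutual_exclusivity(mat, "gi", "gj"), 2 / 3)

  same <- make_matrix(indicator_matrix(list(a = c(1, 3), b = c(1, 3)), m = 4))
  expect_equal(mutual_exclusivity(same, "a", "b"), 0)

  disj <- make_matrix(indicator_matrix(list(a = 1, b = 2), m = 3))
  expect_equal(mutual_exclusivity(disj, "a", "b"), 1)

  none <- make_matrix(indicator_matrix(list(a = integer(0), b = integer(0)),
                                       m = 3))
  expect_equal(mutual_exclusivity(none, "a", "b"), 0)
})

test_that("interaction strength combines C, ME and distance", {
  expect_equal(interaction_strength(2, 0.5, 2 / 3), (0.5 * 2 / 3) / 3)
  expect_equal(interaction_strength(5, 0.9, 0), 0)
  expect_equal(interaction_strength(Inf, 0.9, 0.9), 0)
  d <- c(1, 2, Inf); f <- interaction_strength(d, c(0.5, 0.5, 0.5),
                                               c(1, 1, 1))
  expect_equal(f, c(0.25, 0.5 / 3, 0))
})

test_that("interaction factor averages passing partners over |genes|-1", {
  # both partners at f = 0.2: A-B and A-C adjacent, engineered profiles
  # d(A,B)=d(A,C)=1, C=ME such that C*ME/2 = 0.2 -> C=ME: use C=ME=0.6325?
  # use direct construction instead: star graph, identical pair stats
  pw <- pathway_graph("p", "star", c("A", "B", "C"),
                      rbind(c("A", "B"), c("A", "C")))
  # A in {1..4}, B in {5..10}, C in {5..10}: A vs B exclusive in all 10
  x <- indicator_matrix(list(A = 1:4, B = 5:10, C = 5:10), m = 10)
  mat <- make_matrix(x)
  # f(A,B) = f(A,C) = (1 * 1)/2 = 0.5 -> IF(A) = (0.5+0.5)/2 = 0.5
  res <- interaction_factor(pw, mat, "A", alpha = 0.005)
  expect_equal(res$value, 0.5)
  expect_equal(res$n_passing, 2)

  # all pairs below alpha -> floored at alpha with n_passing 0
  quiet <- make_matrix(indicator_matrix(list(A = integer(0), B = integer(0),
                                             C = integer(0)), m = 10))
  res0 <- interaction_factor(pw, quiet, "A", alpha = 0.005)
  expect_equal(res0$value, 0.005)
  expect_equal(res0$n_passing, 0)

  # one passing partner at f=0.5, one failing: failing contributes zero but
  # stays in the denominator
  x2 <- indicator_matrix(list(A = 1:4, B = 5:10, C = 1:4), m = 10)
  res1 <- interaction_factor(pw, mat = make_matrix(x2), "A", alpha = 0.005)
  expect_equal(res1$value, 0.5 / 2)
  expect_equal(res1$n_passing, 1)

  single <- pathway_graph("s", "s", "A")
  expect_error(interaction_factor(single, mat, "A"), "single gene")
})

test_that("C and ME are symmetric and match set enumeration", {
  set.seed(5)
  for (r in 1:30) {
    m <- sample(2:4, 1)
    si <- which(runif(m) < 0.5); sj <- which(runif(m) < 0.5)
    mat <- make_matrix(indicator_matrix(list(a = si, b = sj), m = m))
    expect_equal(pairwise_coverage(mat, "a", "b"), c_oracle(si, sj, m))
    expect_equal(pairwise_coverage(mat, "b", "a"),
                 pairwise_coverage(mat, "a", "b"))
    expect_equal(mutual_exclusivity(mat, "a", "b"), me_oracle(si, sj, m))
    expect_equal(mutual_exclusivity(mat, "b", "a"),
                 mutual_exclusivity(mat, "a", "b"))
  }
})

test_that("adding an edge never increases distances nor decreases strengths", {
  set.seed(9)
  for (r in 1:10) {
    genes <- paste0("g", 1:6)
    edges <- rbind(cbind(genes[1:5], genes[2:6]))  # path graph
    pw <- pathway_graph("p", "p", genes, edges)
    extra <- sort(sample(genes, 2))
    pw2 <- pathway_graph("p", "p", genes, rbind(edges, extra))
    d1 <- pathway_distances(pw); d2 <- pathway_distances(pw2)
    expect_true(all(d2 <= d1))
    x <- indicator_matrix(setNames(lapply(genes, function(g)
      which(runif(8) < 0.4)), genes), m = 8)
    mat <- make_matrix(x)
    for (i in 1:5) for (j in (i + 1):6) {
      cij <- pairwise_coverage(mat, genes[i], genes[j])
      meij <- mutual_exclusivity(mat, genes[i], genes[j])
      expect_gte(interaction_strength(d2[i, j], cij, meij),
                 interaction_strength(d1[i, j], cij, meij))
    }
  }
})

test_that("interaction factors stay strictly inside (0, 1)", {
  set.seed(21)
  co <- generate_cohort(cohort_spec(m_samples = 40, n_genes = 60,
                                    n_pathways = 5, rng_seed = 21))
  mat <- build_matrix(co$records, co$coverage, samples = co$samples)
  for (pw in co$pathways) {
    vals <- pathway_interaction_factors(pw, mat)[, "value"]
    expect_true(all(vals > 0 & vals < 1))
  }
})
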