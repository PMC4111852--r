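pw2 <- pathway_graph("pw", "two genes", c("A", "B"), rbind(c("A", "B")))

test_that("pathway coverage is the union of member-gene mutated samples", {
  mat <- make_matrix(indicator_matrix(list(A = 1, B = 2, C = integer(0),
                                           D = 1:4), m = 4))
  expect_equal(pathway_coverage(mat, pw2)$rate, 0.5)
  expect_setequal(pathway_coverage(mat, pw2)$covered_samples, c("s1", "s2"))

  empty_pw <- pathway_graph("e", "e", "C")
  expect_equal(pathway_coverage(mat, empty_pw)$rate, 0)

  full <- pathway_graph("f", "f", "D")
  expect_equal(pathway_coverage(mat, full)$rate, 1)

  absent <- pathway_graph("x", "x", "ZZZ")
  expect_error(pathway_coverage(mat, absent), "no gene")
})

test_that("joint coverage is intersection coverage", {
  p1 <- list(pathway_id = "a", covered_samples = c("s1", "s2"), rate = 0.5)
  p2 <- list(pathway_id = "b", covered_samples = c("s2", "s3"), rate = 0.5)
  expect_equal(joint_coverage(list(p1), 4), 0.5)
  expect_equal(joint_coverage(list(p1, p2), 4), 0.25)
  p3 <- list(pathway_id = "c", covered_samples = "s4", rate = 0.25)
  expect_equal(joint_coverage(list(p1, p3), 4), 0)
  expect_error(joint_coverage(list(), 4), "empty")
})

test_that("max single-gene rate counts mutated samples, ties alphabetical", {
  mat <- make_matrix(indicator_matrix(list(A = 1:3, B = 1, C = integer(0)),
                                      m = 10))
  pw <- pathway_graph("p", "p", c("A", "B", "C"))
  res <- max_single_gene_rate(mat, pw)
  expect_equal(res$gene, "A"); expect_equal(res$rate, 0.3)

  tie <- make_matrix(indicator_matrix(list(B = 1:2, A = 1:2), m = 10))
  res2 <- max_single_gene_rate(tie, pathway_graph("p", "p", c("A", "B")))
  expect_equal(res2$gene, "A")

  none <- make_matrix(indicator_matrix(list(A = integer(0), B = integer(0)),
                                       m = 10))
  expect_equal(max_single_gene_rate(none, pw2)$rate, 0)
})

test_that("dominance filter mirrors the coverage-vs-top-gene rule", {
  expect_true(dominance_ok(0.70, 0.44, 0.05))   # clears the margin
  expect_false(dominance_ok(0.72, 0.72, 0.05))  # equal rates cannot clear
  expect_true(dominance_ok(0.5, 0.25, 0.25))    # boundary passes (>=)
})

test_that("collaboration p-value enumerates the toy space exactly", {
  # 3 samples, candidate with one event in each of two genes
  mat <- make_matrix(indicator_matrix(list(A = 1, B = 2, Z = 1:3), m = 3))
  base <- list(list(pathway_id = "z", covered_samples = c("s1", "s2", "s3"),
                    rate = 1))
  # independent enumeration of all 3^2 assignments
  cnts <- integer(0)
  for (a in 1:3) for (b in 1:3) cnts <- c(cnts, length(unique(c(a, b))))
  obs <- 2  # A covers s1, B covers s2
  p_expected <- mean(cnts >= obs)
  cand <- pathway_graph("c", "c", c("A", "B"))
  expect_equal(collab_pvalue(mat, cand, base, n_perm = 100), p_expected)
  expect_equal(p_expected, 2 / 3)

  # Monte-Carlo mode converges to the exact value
  set.seed(1)
  p_mc <- collab_pvalue(mat, cand, base, n_perm = 20000, exact = FALSE)
  expect_lt(abs(p_mc - p_expected), 0.02)

  # candidate with no mutations -> p = 1 by convention
  quiet <- pathway_graph("q", "q", "C")
  mat2 <- make_matrix(indicator_matrix(list(A = 1, C = integer(0)), m = 3))
  expect_equal(collab_pvalue(mat2, quiet, base, n_perm = 10), 1)
})

test_that("planted co-occurrence is significant, independence is not", {
  set.seed(6)
  m <- 300
  block <- 1:180  # 60% collaborative block
  mat <- make_matrix(indicator_matrix(list(A = block, B = block), m = m))
  pa <- pathway_graph("pa", "pa", "A"); pb <- pathway_graph("pb", "pb", "B")
  prof_a <- pathway_coverage(mat, pa)
  p_planted <- collab_pvalue(mat, pb, list(prof_a), n_perm = 1000)
  expect_lt(p_planted, 0.01)

  # independent candidate whose events land uniformly (with replacement):
  # the observed coverage is itself a draw from the redistribution null,
  # so p is approximately uniform over replicates
  set.seed(60)
  ps <- replicate(40, {
    ev <- tabulate(sample.int(m, 90, replace = TRUE), m)
    x <- rbind(A = as.integer(seq_len(m) %in% block), B = ev)
    mm <- make_matrix(x)
    collab_pvalue(mm, pb, list(pathway_coverage(mm, pa)), n_perm = 400)
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(mean(ps > 0.05), 0.6)
})

test_that("greedy rejects single-gene-dominated pathways outright", {
  # coverage produced entirely by one gene: rate == top gene rate
  mat <- make_matrix(indicator_matrix(list(A = 1:7, B = integer(0),
                                           C = 1:3, D = 4:6), m = 10))
  dom <- pathway_graph("dom", "dominated", c("A", "B"), rbind(c("A", "B")))
  other <- pathway_graph("oth", "spread", c("C", "D"), rbind(c("C", "D")))
  cfg <- run_config(n_perm_collab = 200, rng_seed = 1)
  res <- greedy_select(mat, list(dom, other), cfg)
  expect_false("dom" %in% res$steps$pathway_id)
  # 'other' covers 6/10 via two genes at 0.3 each -> passes dominance
  expect_equal(res$steps$pathway_id[1], "oth")

  all_dom <- greedy_select(mat, list(dom), cfg)
  expect_equal(nrow(all_dom$steps), 0L)
  expect_true(is.na(all_dom$mcr))
})

test_that("greedy trajectory is non-increasing and reproducible", {
  co <- generate_cohort(cohort_presets()$planted_trio, seed = 23)
  mat <- build_matrix(co$records, co$coverage, samples = co$samples)
  cfg <- run_config(n_perm_collab = 300, rng_seed = 23)
  set.seed(23); res1 <- greedy_select(mat, co$pathways, cfg)
  set.seed(23); res2 <- greedy_select(mat, co$pathways, cfg)
  expect_identical(res1$steps, res2$steps)
  expect_gte(nrow(res1$steps), 2L)
  expect_true(all(diff(res1$steps$mcr_after) <= 1e-12))
  # intersection coverage consistent with the recorded trajectory
  profs <- lapply(res1$steps$pathway_id, function(id) {
    pw <- co$pathways[[which(vapply(co$pathways, `[[`, character(1),
                                    "pathway_id") == id)]]
    pathway_coverage(mat, pw)
  })
  expect_equal(joint_coverage(profs, length(mat$samples)),
               utils::tail(res1$steps$mcr_after, 1))
})

test_that("removing mutations never increases pathway coverage", {
  set.seed(31)
  for (r in 1:10) {
    x <- indicator_matrix(list(A = which(runif(12) < 0.5),
                               B = which(runif(12) < 0.5)), m = 12)
    mat <- make_matrix(x)
    rate1 <- pathway_coverage(mat, pw2)$rate
    x2 <- x
    on_cells <- which(x2 > 0)
    if (length(on_cells) == 0) next
    x2[sample(on_cells, 1)] <- 0L
    rate2 <- pathway_coverage(make_matrix(x2), pw2)$rate
    expect_lte(rate2, rate1)
  }
})
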