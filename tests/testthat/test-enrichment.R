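test_that("ranking score is exp(MF) * IF, strictly increasing in both", {
  expect_equal(ranking_score(0, 0.5), 0.5)
  expect_equal(ranking_score(log(2), 0.25), 0.5)
  expect_gt(ranking_score(1, 0.3), ranking_score(0.5, 0.3))
  expect_gt(ranking_score(0.5, 0.4), ranking_score(0.5, 0.3))
  expect_error(ranking_score(0, 1), "\\(0, 1\\)")
  expect_error(ranking_score(0, 0), "\\(0, 1\\)")
})

test_that("imputation honors the passing probability", {
  set.seed(3)
  mf <- rep(0.1, 50)
  none <- impute_outside_scores(mf, 5, 1, pass_rate = 0, alpha = 0.005)
  expect_equal(none$score, exp(mf) * 0.005)
  expect_true(all(none$imputed))

  all_pass <- impute_outside_scores(mf, 5, 0, pass_rate = 1)
  expect_equal(all_pass$score, rep(5, 50))

  big <- impute_outside_scores(rep(0, 10000), 5, 1, pass_rate = 0.5)
  drawn <- big$score != exp(0) * 0.005
  # binomial 3 sigma around 0.5 at n = 10000
  expect_lt(abs(mean(drawn) - 0.5), 3 * sqrt(0.25 / 10000))
  expect_true(all(big$score > 0))
})

test_that("weighted KS statistic matches hand cases", {
  # all members occupy the top positions -> MD = 1
  rl <- ranked_list("p", paste0("g", 1:6), c(9, 8, 7, 3, 2, 1),
                    c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(wks_statistic(rl), 1)

  # six-gene list scanned exhaustively by the oracle
  rl2 <- ranked_list("p", paste0("g", 1:6), c(5, 4, 3, 2, 1, 1),
                     c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(wks_statistic(rl2), wks_scan_oracle(rl2$scores, rl2$member))

  # equal weights interleaved 1:1 -> deviation bounded by one member step
  n <- 10
  rl3 <- ranked_list("p", sprintf("g%02d", 1:n), rep(1, n),
                     rep(c(TRUE, FALSE), n / 2))
  expect_lte(wks_statistic(rl3), 1 / (n / 2) + 1e-12)
})

test_that("permuted MDs live on the exact support of position subsets", {
  set.seed(13)
  w <- c(5, 4, 3, 2, 1.5, 1)
  support <- apply(utils::combn(6, 2), 2, function(q) {
    member <- seq_len(6) %in% q
    wks_scan_oracle(w, member)
  })
  perm <- pathcollab:::.wks_perm_md(w, p = 2, n_perm = 300)
  expect_true(all(vapply(perm, function(x)
    any(abs(x - support) < 1e-12), logical(1))))
})

test_that("enrichment p-values use +1 smoothing and detect planted signal", {
  set.seed(4)
  n <- 80
  scores <- sort(rexp(n) + 0.01, decreasing = TRUE)
  member <- c(rep(TRUE, 8), rep(FALSE, n - 8))  # extreme enrichment
  rl <- ranked_list("p", sprintf("g%03d", 1:n), scores, member)
  res <- enrichment_pvalue(rl, n_perm = 200)
  expect_equal(res$md, 1)
  expect_equal(res$p, 1 / 201)   # no permutation beats a perfect split

  random_member <- sample(member)
  rl2 <- ranked_list("p", sprintf("g%03d", 1:n), scores, random_member)
  res2 <- enrichment_pvalue(rl2, n_perm = 200)
  expect_gt(res2$p, 0)
  expect_lte(res2$p, 1)
})

test_that("FDR is p*m/k capped at one and non-decreasing", {
  res <- data.frame(pathway_id = c("a", "b", "c"),
                    md = c(0.9, 0.5, 0.2),
                    p = c(0.001, 0.01, 1), stringsAsFactors = FALSE)
  out <- fdr_correct(res, m_total = 200)
  expect_equal(out$rank, 1:3)
  expect_equal(out$fdr[1], 0.001 * 200 / 1)
  expect_equal(out$fdr[2], 0.01 * 200 / 2)  # matches raw p*m/k directly
  expect_equal(out$fdr[3], 1)               # capped
  expect_true(all(diff(out$fdr) >= 0))

  one <- fdr_correct(data.frame(pathway_id = "x", md = 0.5, p = 0.05),
                     m_total = 1)
  expect_equal(one$fdr, 0.05)

  # ties share the ordering deterministically by pathway id
  tied <- fdr_correct(data.frame(pathway_id = c("b", "a"), md = c(0.1, 0.2),
                                 p = c(0.02, 0.02)), m_total = 10)
  expect_equal(tied$pathway_id, c("a", "b"))
})

test_that("FDR stays monotone under the running maximum on random inputs", {
  set.seed(8)
  for (r in 1:20) {
    k <- sample(3:30, 1)
    res <- data.frame(pathway_id = sprintf("p%02d", 1:k), md = runif(k),
                      p = runif(k))
    out <- fdr_correct(res, m_total = k + sample(0:100, 1))
    expect_true(all(diff(out$fdr) >= 0))
    expect_true(all(out$fdr <= 1))
  }
})

test_that("top-pathway selection breaks ties by MD then id", {
  res <- data.frame(pathway_id = c("a", "b", "c"), md = c(0.2, 0.9, 0.5),
                    p = c(0.001, 0.02, 0.5))
  expect_equal(select_top_pathways(res, 60), c("a", "b", "c"))
  expect_equal(select_top_pathways(res, 2), c("a", "b"))
  tie <- data.frame(pathway_id = c("x", "y"), md = c(0.5, 0.9),
                    p = c(0.01, 0.01))
  expect_equal(select_top_pathways(tie, 1), "y")
})

test_that("a pathway holding all non-synonymous mutations ranks first", {
  set.seed(17)
  spec <- cohort_spec(m_samples = 60, n_genes = 50, n_pathways = 4,
                      genes_per_pathway = c(8, 10),
                      background_nsy_rate = 0, background_sy_rate = 0.01,
                      planted_sets = list(list(pathways = 1, target = 0.8)),
                      rng_seed = 17)
  co <- generate_cohort(spec)
  mat <- build_matrix(co$records, co$coverage, samples = co$samples)
  cfg <- run_config(n_perm_enrichment = 200, rng_seed = 17)
  set.seed(17)
  enr <- enrich_pathways(mat, co$pathways, cfg)
  expect_equal(enr$results$pathway_id[1], "PW001")
  expect_lt(enr$results$p[1], 0.05)
})

test_that("ranking stage is deterministic given the seed", {
  co <- generate_cohort(cohort_spec(m_samples = 30, n_genes = 40,
                                    n_pathways = 3, rng_seed = 2))
  mat <- build_matrix(co$records, co$coverage, samples = co$samples)
  cfg <- run_config(n_perm_enrichment = 100, rng_seed = 5)
  set.seed(5); a <- enrich_pathways(mat, co$pathways, cfg)
  set.seed(5); b <- enrich_pathways(mat, co$pathways, cfg)
  expect_identical(a$results, b$results)
})
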