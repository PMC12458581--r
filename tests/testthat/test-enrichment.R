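test_that("ora reproduces exact combinatorial tail probabilities", {
  u <- paste0("g", 1:10)
  res <- ora(hits = u[1:4], gene_set = u[1:5], universe = u)
  expect_equal(res$p_value, 5 / 210)  # C(5,4)C(5,0)/C(10,4)
  # zero overlap: P(X >= 0) = 1
  res0 <- ora(hits = u[6:9], gene_set = u[1:5], universe = u)
  expect_equal(res0$n_overlap, 0)  # hits 6:9 vs set 1:5 share nothing
  expect_equal(ora(u[6:9], u[1:5], u)$p_value,
               stats::phyper(-1, 5, 5, 4, lower.tail = FALSE))
  # gene_set = universe forces k = n and p = 1
  resU <- ora(hits = u[1:4], gene_set = u, universe = u)
  expect_equal(resU$n_overlap, 4)
  expect_equal(resU$p_value, 1)
  expect_error(ora(u[1], u[1:2], character()), "empty universe")
})

test_that("gsea ES equals the step-by-step running-sum oracle", {
  set.seed(61)
  genes <- paste0("g", 1:10)
  scores <- round(rnorm(10), 2)
  gene_set <- c("g2", "g5", "g9")
  ranked <- tibble::tibble(gene_id = genes, score = scores)
  res <- gsea_preranked(ranked, gene_set, weight = 1, n_perm = 0)
  expect_equal(res$es, gsea_es_oracle(genes, scores, gene_set, weight = 1))
  res0 <- gsea_preranked(ranked, gene_set, weight = 0, n_perm = 0)
  expect_equal(res0$es, gsea_es_oracle(genes, scores, gene_set, weight = 0))
})

test_that("a top-k prefix set maximizes the running sum at rank k", {
  ranked <- tibble::tibble(gene_id = paste0("g", 1:100),
                           score = seq(5, 0.1, length.out = 100))
  res <- gsea_preranked(ranked, paste0("g", 1:5), n_perm = 0)
  expect_gt(res$es, 0)
  expect_equal(res$peak, 5L)
  expect_setequal(res$core_genes, paste0("g", 1:5))
})

test_that("gsea ES is invariant to positive score rescaling and handles degenerate sets", {
  set.seed(62)
  ranked <- tibble::tibble(gene_id = paste0("g", 1:50), score = rnorm(50))
  set <- sample(ranked$gene_id, 8)
  es1 <- gsea_preranked(ranked, set, n_perm = 0)$es
  es2 <- gsea_preranked(dplyr::mutate(ranked, score = score * 7.3), set,
                        n_perm = 0)$es
  expect_equal(es1, es2)
  # full-list set degenerates to ES 0
  expect_equal(gsea_preranked(ranked, ranked$gene_id, weight = 0,
                              n_perm = 0)$es, 0)
  # reversing the ranking negates the weight-0 statistic
  esf <- gsea_preranked(ranked, set, weight = 0, n_perm = 0)$es
  esr <- gsea_preranked(dplyr::mutate(ranked, score = -score), set,
                        weight = 0, n_perm = 0)$es
  expect_equal(esf, -esr, tolerance = 1e-9)
  expect_error(gsea_preranked(ranked, "not_a_gene", n_perm = 0),
               "no genes")
})

test_that("gsea ES agrees with an independent implementation", {
  set.seed(63)
  n <- 200
  ranked <- tibble::tibble(gene_id = paste0("g", 1:n),
                           score = sort(rnorm(n), decreasing = TRUE))
  for (k in c(5, 20)) {
    set <- sample(ranked$gene_id, k)
    ours <- gsea_preranked(ranked, set, weight = 1, n_perm = 0)$es
    stats_vec <- rlang::set_names(ranked$score, ranked$gene_id)
    theirs <- fgsea::calcGseaStat(stats_vec,
                                  selectedStats = which(ranked$gene_id %in% set),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-8)
  }
})

test_that("pathway overlap permutation null matches the closed-form mean", {
  u <- paste0("P", 1:100)
  res <- pathway_overlap_test(u[1:20], u[41:70], u, n_perm = 10000, seed = 2)
  # E[overlap] = n_a * n_b / N = 6; Monte-Carlo tolerance
  expect_lt(abs(res$perm_mean - 6), 3 * res$perm_sd / sqrt(10000))
  expect_false(res$degenerate)
  # seed-reproducible
  res2 <- pathway_overlap_test(u[1:20], u[41:70], u, n_perm = 10000, seed = 2)
  expect_identical(tidy(res), tidy(res2))
})

test_that("pathway overlap test flags degenerate nulls and nails obvious overlap", {
  u <- paste0("P", 1:30)
  res <- pathway_overlap_test(u, u, u, n_perm = 100, seed = 1)
  expect_true(res$degenerate)
  expect_equal(res$observed, 30)
  # observed equals the (constant) permutation overlap, so p collapses to 1
  expect_equal(res$p_value, 1)
  big_u <- paste0("P", 1:1000)
  res2 <- pathway_overlap_test(big_u[1:20], big_u[1:20], big_u,
                               n_perm = 2000, seed = 3)
  expect_lt(res2$p_value, 1e-10)
})

test_that("overlap network edges equal brute-force direction-matched intersections", {
  enriched <- list(
    A = list(positive = paste0("P", 1:10), negative = character()),
    B = list(positive = paste0("P", 1:10), negative = character()),
    C = list(positive = paste0("P", 1:10), negative = character())
  )
  net <- build_overlap_network(enriched)
  expect_equal(nrow(net$edges), 3)  # complete triangle
  expect_true(all(net$edges$weight == 10))
  # disjoint sets: no edges
  enriched2 <- list(A = list(positive = "P1", negative = character()),
                    B = list(positive = "P2", negative = character()))
  expect_equal(nrow(build_overlap_network(enriched2)$edges), 0)
  # random sets vs explicit intersections, per direction
  set.seed(71)
  u <- paste0("P", 1:50)
  mk <- function() list(positive = sample(u, 15), negative = sample(u, 10))
  enriched3 <- list(A = mk(), B = mk(), C = mk())
  net3 <- build_overlap_network(enriched3)
  for (i in seq_len(nrow(net3$edges))) {
    e <- net3$edges[i, ]
    expect_equal(e$weight,
                 length(intersect(enriched3[[e$from]][[e$direction]],
                                  enriched3[[e$to]][[e$direction]])))
  }
  expect_equal(net3$nodes$n_pathways, rep(25L, 3))
})
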