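toy_z <- function() {
  m <- rbind(
    g1 = c(1, 2, 3),
    g2 = c(5, 5, 5),
    g3 = c(2, 8, 2)
  )
  colnames(m) <- paste0("s", 1:3)
  m
}

test_that("zscore_matrix uses the population sd and zeroes flat genes", {
  z <- zscore_matrix(toy_z())
  expect_equal(unname(z["g1", ]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)
  expect_equal(unname(z["g1", 1]), -1.2247, tolerance = 1e-4)
  expect_true(all(z["g2", ] == 0))
  expect_equal(attr(z, "zero_variance"), "g2")
  # every row sums to zero
  expect_true(all(abs(rowSums(z)) < 1e-9))
  expect_error(zscore_matrix(toy_z()[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("signature scores add up genes and subtract down genes", {
  z <- rbind(g1 = c(1.2, 0), g2 = c(-0.5, 0))
  colnames(z) <- c("sA", "sB")
  sig <- gene_signature("s", up = "g1", down = "g2")
  sc <- signature_score(z, sig)
  expect_equal(sc$score[sc$sample_id == "sA"], 1.7)
  # swapping up/down negates every score
  sc_flip <- signature_score(z, flip_signature(sig))
  expect_equal(sc_flip$score, -sc$score)
  # missing genes are skipped and counted
  sig2 <- gene_signature("s2", up = c("g1", "absent"))
  sc2 <- signature_score(z, sig2)
  expect_equal(attr(sc2, "n_genes_used"), 1)
  expect_equal(attr(sc2, "n_genes_missing"), 1)
  expect_error(signature_score(z, gene_signature("none", up = "nope")),
               "none")
})

test_that("cohort-wide score mean is zero after z-scoring", {
  set.seed(81)
  m <- matrix(rnorm(50 * 20), nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
  z <- zscore_matrix(m)
  sig <- gene_signature("s", up = paste0("g", 1:10), down = paste0("g", 11:25))
  expect_lt(abs(mean(signature_score(z, sig)$score)), 1e-9)
})

test_that("scores are invariant to per-gene affine transforms", {
  set.seed(82)
  m <- matrix(rnorm(30 * 15), nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:15)))
  sig <- gene_signature("s", up = paste0("g", 1:8), down = paste0("g", 9:20))
  base <- signature_score(zscore_matrix(m), sig)
  a <- runif(30, 0.5, 4)
  b <- rnorm(30, 0, 10)
  m2 <- m * a + b
  transformed <- signature_score(zscore_matrix(m2), sig)
  expect_equal(transformed$score, base$score, tolerance = 1e-9)
})

test_that("score correlation behaves at the extremes and under flips", {
  set.seed(83)
  m <- matrix(rnorm(40 * 12), nrow = 40,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:12)))
  z <- zscore_matrix(m)
  sig <- gene_signature("s", up = paste0("g", 1:10), down = paste0("g", 11:20))
  sc <- signature_score(z, sig)
  expect_equal(score_correlation(sc, sc)$r, 1)
  sc_neg <- signature_score(z, flip_signature(sig))
  expect_equal(score_correlation(sc, sc_neg)$r, -1)
  # zero variance yields an explicit null result
  flat <- dplyr::mutate(sc, score = 0)
  res <- score_correlation(sc, flat)
  expect_true(is.na(res$r))
  expect_equal(res$note, "zero variance")
})

test_that("homolog mapping drops unmapped genes and direction conflicts", {
  map <- tibble::tibble(mouse = c("Alb", "Apoa1", "G1", "G2"),
                        human = c("ALB", "APOA1", "H1", "H1"))
  sig <- gene_signature("m", up = c("Alb", "G1", "Nomap"), down = c("G2"))
  expect_warning(hs <- map_homologs(sig, map), "conflicting")
  expect_equal(hs$up, "ALB")
  expect_equal(length(hs$down), 0)       # G2's target H1 was conflicted away
  expect_equal(attr(hs, "n_unmapped"), 1)
  expect_equal(attr(hs, "conflicts"), "H1")
  # clean 1:1 map
  hs2 <- map_homologs(gene_signature("m2", up = "Apoa1"), map)
  expect_equal(hs2$up, "APOA1")
})

test_that("severity association encodes states in the supplied order", {
  scores <- tibble::tibble(sample_id = paste0("s", 1:6),
                           score = c(0, 0, 1, 1, 2, 2))
  states <- c("a", "a", "b", "b", "c", "c")
  res <- severity_association(scores, states, levels = c("a", "b", "c"))
  expect_equal(res$r, 1)
  # reversing the declared order negates r
  res_rev <- severity_association(scores, states, levels = c("c", "b", "a"))
  expect_equal(res_rev$r, -1)
  expect_error(severity_association(scores, states, levels = c("a", "b")),
               "not in severity order")
})

test_that("the sign of the severity association is stable under monotone re-encoding", {
  set.seed(84)
  scores <- tibble::tibble(sample_id = paste0("s", 1:60),
                           score = rnorm(60) + rep(0:2, each = 20))
  states <- rep(c("lo", "mid", "hi"), each = 20)
  res <- severity_association(scores, states, levels = c("lo", "mid", "hi"))
  # unequal-spacing re-encoding keeps the sign
  unequal <- c(lo = 0, mid = 1, hi = 10)[states]
  expect_equal(sign(res$r), sign(stats::cor(scores$score, unequal)))
})

test_that("random scores show no severity association in a calibrated fraction of seeds", {
  hits <- vapply(1:40, function(seed) {
    set.seed(seed)
    scores <- tibble::tibble(sample_id = paste0("s", 1:200),
                             score = rnorm(200))
    states <- rep(c("a", "b", "c", "d"), each = 50)
    abs(severity_association(scores, states, c("a", "b", "c", "d"))$r) < 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
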