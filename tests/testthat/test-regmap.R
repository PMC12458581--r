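toy_annotation <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    tss = c(10000L, 1000L, 50000L),
    strand = c("+", "+", "-")
  )
}

test_that("promoter windows are symmetric, strand-agnostic in width, and clipped", {
  pw <- promoter_windows(toy_annotation(), flank = 3000)
  expect_equal(pw$start[pw$gene_id == "gA"], 7000L)
  expect_equal(pw$end[pw$gene_id == "gA"], 13000L)
  # clipped at zero
  expect_equal(pw$start[pw$gene_id == "gB"], 0L)
  expect_equal(pw$end[pw$gene_id == "gB"], 4000L)
  # minus-strand gene: same width, centred on the TSS
  gc <- pw[pw$gene_id == "gC", ]
  expect_equal(gc$end - gc$start, 6000L)
  expect_equal((gc$start + gc$end) / 2, 50000)
})

toy_enhancers <- function(starts, ends, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = starts, end = ends,
                 enhancer_id = sprintf("e%02d", seq_along(starts)))
}

test_that("build_anchors merges book-ended but not gapped intervals", {
  enh <- toy_enhancers(c(100L, 200L), c(200L, 300L))
  links <- tibble::tibble(enhancer_id = c("e01", "e02"), gene_id = c("g1", "g2"))
  a <- build_anchors(enh, links, max_gap = 0)
  expect_equal(nrow(a$anchors), 1)
  expect_equal(a$anchors$start, 100L)
  expect_equal(a$anchors$end, 300L)
  expect_equal(a$anchors$n_source_enhancers, 2L)
  expect_setequal(a$links$gene_id, c("g1", "g2"))

  enh2 <- toy_enhancers(c(100L, 250L), c(200L, 300L))
  a2 <- build_anchors(enh2, links, max_gap = 0)
  expect_equal(nrow(a2$anchors), 2)
  # a max_gap of 50 bridges the 50-bp gap
  a3 <- build_anchors(enh2, links, max_gap = 50)
  expect_equal(nrow(a3$anchors), 1)
})

test_that("build_anchors equals the base-coverage merge oracle on random inputs", {
  set.seed(51)
  for (i in 1:25) {
    iv <- random_intervals(sample(2:120, 1))
    links <- tibble::tibble(enhancer_id = iv$enhancer_id,
                            gene_id = sample(paste0("g", 1:20), nrow(iv),
                                             replace = TRUE))
    got <- build_anchors(iv, links)$anchors
    want <- brute_merge(iv)
    expect_equal(got[, c("chrom", "start", "end")], want, ignore_attr = TRUE)
    # source counts sum to the input count
    expect_equal(sum(got$n_source_enhancers), nrow(iv))
  }
})

test_that("build_anchors is idempotent and order-invariant", {
  set.seed(52)
  iv <- random_intervals(80)
  links <- tibble::tibble(enhancer_id = iv$enhancer_id, gene_id = "g1")
  a1 <- build_anchors(iv, links)
  # feeding the anchors back in changes nothing
  again <- build_anchors(
    dplyr::mutate(a1$anchors, enhancer_id = .data$anchor_id),
    dplyr::rename(a1$links, enhancer_id = "anchor_id"))
  expect_equal(again$anchors[, c("chrom", "start", "end")],
               a1$anchors[, c("chrom", "start", "end")])
  # shuffled input order gives identical output
  perm <- sample(nrow(iv))
  a2 <- build_anchors(iv[perm, ], links)
  expect_equal(a2$anchors, a1$anchors)
})

test_that("assign_peaks uses >= 1 bp overlap with half-open boundaries", {
  ann <- toy_annotation()
  pw <- promoter_windows(ann)
  enh <- toy_enhancers(30000L, 30500L)
  links <- tibble::tibble(enhancer_id = "e01", gene_id = c("g1", "g2", "g3"))
  anchors <- build_anchors(enh, links)
  dep <- function(start, end) {
    tibble::tibble(chrom = "chr1", start = start, end = end,
                   feature_id = paste0("p", start), direction = "up")
  }
  # inside gA's promoter [7000, 13000)
  hit <- assign_peaks(dep(7500L, 7600L), pw, anchors, mark = "H3K27ac")
  expect_equal(hit$gene_id, "gA")
  expect_equal(hit$region_class, "promoter")
  # exactly abutting the window end: no assignment
  miss <- assign_peaks(dep(13000L, 13100L), pw, anchors, mark = "H3K27ac")
  expect_equal(nrow(miss), 0)
  expect_equal(attr(miss, "n_unassigned"), 1L)
  # a peak across a 3-gene anchor yields three enhancer rows
  multi <- assign_peaks(dep(30400L, 30600L), pw, anchors, mark = "H3K27ac")
  expect_equal(nrow(multi), 3)
  expect_setequal(multi$gene_id, c("g1", "g2", "g3"))
  expect_true(all(multi$region_class == "enhancer"))
})

random_concordance_fixture <- function(n_genes = 60, seed = 1) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  gene_diff <- tibble::tibble(
    feature_id = genes,
    direction = sample(c("up", "down"), n_genes, replace = TRUE)
  )
  n_rec <- 3 * n_genes
  assignments <- tibble::tibble(
    gene_id = sample(genes, n_rec, replace = TRUE),
    mark = sample(c("H3K27ac", "H3K4me3", "H3K27me3"), n_rec, replace = TRUE),
    region_class = sample(c("promoter", "enhancer"), n_rec, replace = TRUE),
    peak_id = paste0("p", seq_len(n_rec)),
    peak_direction = sample(c("up", "down"), n_rec, replace = TRUE)
  )
  list(gene_diff = gene_diff, assignments = assignments)
}

test_that("concordance follows mark polarity", {
  gene_diff <- tibble::tibble(feature_id = c("g1", "g2"),
                              direction = c("down", "up"))
  assignments <- tibble::tibble(
    gene_id = c("g1", "g2"),
    mark = c("H3K27ac", "H3K27me3"),
    region_class = c("promoter", "enhancer"),
    peak_id = c("p1", "p2"),
    peak_direction = c("down", "up")
  )
  res <- classify_concordance(assignments, gene_diff)
  # loss of an active mark with decreased expression: concordant, promoter_only
  expect_true(res$records$concordant[res$records$gene_id == "g1"])
  expect_equal(res$categories$category[res$categories$gene_id == "g1"],
               "promoter_only")
  # gain of a repressive mark with increased expression: discordant -> neither
  expect_false(res$records$concordant[res$records$gene_id == "g2"])
  expect_equal(res$categories$category[res$categories$gene_id == "g2"],
               "neither")
  # unknown mark errors by name
  bad <- dplyr::mutate(assignments, mark = "H3K99me9")
  expect_error(classify_concordance(bad, gene_diff), "H3K99me9")
})

test_that("concordance categories always partition the differential genes", {
  for (seed in 1:5) {
    fx <- random_concordance_fixture(seed = seed)
    res <- classify_concordance(fx$assignments, fx$gene_diff)
    s <- res$summary
    expect_equal(s$promoter_only + s$enhancer_only + s$both + s$neither,
                 s$n_genes)
    expect_equal(s$n_genes, nrow(fx$gene_diff))
    expect_equal(anyDuplicated(res$categories$gene_id), 0)
  }
})

test_that("flipping all peak directions flips every concordance flag", {
  fx <- random_concordance_fixture(seed = 9)
  res <- classify_concordance(fx$assignments, fx$gene_diff)
  flipped <- dplyr::mutate(fx$assignments,
                           peak_direction = ifelse(.data$peak_direction == "up",
                                                   "down", "up"))
  res2 <- classify_concordance(flipped, fx$gene_diff)
  expect_equal(res$records$concordant, !res2$records$concordant)
})

test_that("linked-enhancer counts recover the catalog multiplicity when all anchors are hit", {
  ann <- simulate_study(simulation_config(
    n_genes = 1000, samples_per_group = 2,
    exposures = c("vehicle", "TBT"), seed = 13))$annotation
  cat8 <- simulate_enhancer_catalog(ann, n_enhancers_per_gene = 8, seed = 13)
  anchors <- build_anchors(cat8$enhancers, cat8$links)
  # one giant peak hits every anchor
  deps <- tibble::tibble(chrom = "chrS", start = 0L,
                         end = max(anchors$anchors$end),
                         feature_id = "all", direction = "up")
  st <- linked_enhancer_stats(anchors, deps, genes = ann$gene_id)
  expect_gte(st$mean_all, 7)
  expect_lte(st$mean_all, 9)
  # no peaks: all zero
  st0 <- linked_enhancer_stats(anchors, deps[0, ], genes = ann$gene_id)
  expect_true(all(st0$per_gene$n_hit_anchors == 0))
  expect_equal(st0$mean_hit, 0)
  expect_equal(st0$mean_all, 0)
})
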