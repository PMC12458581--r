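# Independent oracles used by the property tests. These deliberately take a
# different computational route from the package implementation.

# Transitive interval merge by literal base coverage: mark every covered
# base on each chromosome, then read off maximal runs of covered bases.
# With max_gap = 0 this is exactly transitive merging of overlapping or
# book-ended half-open intervals.
brute_merge <- function(intervals) {
  out <- lapply(split(intervals, intervals$chrom), function(iv) {
    maxend <- max(iv$end)
    cover <- logical(maxend)
    for (i in seq_len(nrow(iv))) {
      cover[(iv$start[i] + 1):iv$end[i]] <- TRUE
    }
    r <- rle(cover)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    tibble::tibble(
      chrom = iv$chrom[1],
      start = starts[keep] - 1L,  # back to 0-based
      end = ends[keep]
    )
  })
  dplyr::bind_rows(out) |> dplyr::arrange(chrom, start)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000,
                             max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + len,
    enhancer_id = sprintf("e%04d", seq_len(n))
  )
}

# Exhaustive hypergeometric upper tail: enumerate every size-n hit subset of
# the universe and count those overlapping the set in >= k genes.
enum_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)  # first K labels form the set
  mean(overlaps >= k)
}

# Step-by-step GSEA running-sum oracle: explicit loop, no vectorization.
gsea_es_oracle <- function(genes, scores, gene_set, weight = 1) {
  ord <- order(-scores)
  genes <- genes[ord]
  scores <- scores[ord]
  N <- length(genes)
  hit <- genes %in% gene_set
  K <- sum(hit)
  nr <- sum(abs(scores[hit])^weight)
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      cur <- cur + abs(scores[i])^weight / nr
    } else {
      cur <- cur - 1 / (N - K)
    }
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# a small deterministic differential table
toy_diff <- function(up, down, ns = character()) {
  tibble::tibble(
    feature_id = c(up, down, ns),
    log2fc = c(rep(1, length(up)), rep(-1, length(down)), rep(0, length(ns))),
    fold_change_linear = 2^c(rep(1, length(up)), rep(-1, length(down)),
                             rep(0, length(ns))),
    p_value = c(rep(0.001, length(up) + length(down)), rep(0.9, length(ns))),
    q_value = c(rep(0.01, length(up) + length(down)), rep(0.95, length(ns))),
    direction = c(rep("up", length(up)), rep("down", length(down)),
                  rep("ns", length(ns)))
  )
}
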