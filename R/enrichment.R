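#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of a hit list against a gene set within a
#' universe: P(X >= k) with N = |universe|, K = |set within universe|,
#' n = |hits|, k = |hits in set|.
#'
#' @param hits Character vector of hit gene IDs (subset of `universe`).
#' @param gene_set Character vector of set gene IDs (intersected with the
#'   universe before counting).
#' @param universe Character vector: the gene universe.
#' @return One-row tibble: `n_universe`, `n_set`, `n_hits`, `n_overlap`,
#'   `fold_enrichment`, `p_value`.
#' @export
ora <- function(hits, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  hits <- unique(intersect(hits, universe))
  set_u <- unique(intersect(gene_set, universe))
  bigN <- length(universe)
  bigK <- length(set_u)
  n <- length(hits)
  k <- length(intersect(hits, set_u))
  p <- stats::phyper(k - 1, bigK, bigN - bigK, n, lower.tail = FALSE)
  fe <- if (n > 0 && bigK > 0) (k / n) / (bigK / bigN) else NA_real_
  tibble::tibble(
    n_universe = bigN, n_set = bigK, n_hits = n, n_overlap = k,
    fold_enrichment = fe, p_value = p
  )
}

# weighted Kolmogorov-Smirnov running sum; scores must be ordered by rank
gsea_running_sum <- function(in_set, scores, weight) {
  n <- length(scores)
  k <- sum(in_set)
  if (k == 0 || k == n) return(list(es = 0, running = numeric(n), peak = NA_integer_))
  w <- abs(scores)^weight
  hit_norm <- sum(w[in_set])
  if (hit_norm == 0) {
    # all in-set weights zero (possible at weight > 0 with zero scores)
    inc <- ifelse(in_set, 1 / k, 0)
  } else {
    inc <- ifelse(in_set, w / hit_norm, 0)
  }
  dec <- ifelse(in_set, 0, 1 / (n - k))
  running <- cumsum(inc - dec)
  peak <- which.max(abs(running))
  list(es = running[peak], running = running, peak = peak)
}

#' Preranked gene-set enrichment
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment on a ranked gene list:
#' hits increment the running sum proportionally to `|score|^weight`
#' (normalized), misses decrement by `1/(N - K)`; the enrichment score (ES)
#' is the signed maximum deviation. The null is built from `n_perm` random
#' gene sets of the same size drawn from the ranked list; NES divides ES by
#' the mean |null ES| of matching sign and the p-value is the one-sided
#' empirical frequency among same-sign null ES. Core (leading-edge) genes
#' are the set members up to the ES extremum. Ties in scores keep stable
#' input order.
#'
#' @param ranked Tibble with columns `gene_id` and `score`, sorted by
#'   decreasing score by the caller (the function sorts stably if not).
#' @param gene_set Character vector of gene IDs (must share >= 1 gene with
#'   the ranked list).
#' @param weight Score weighting exponent (default 1; 0 gives the classic
#'   unweighted statistic).
#' @param n_perm Number of gene-set permutations for the null.
#' @param seed Integer seed for the permutation null.
#' @param set_name Optional label stored on the result.
#' @return A list of class `gsea_result`: `set_name`, `es`, `nes`,
#'   `p_value`, `direction` (`"positive"`/`"negative"`), `core_genes`,
#'   `n_set`, `n_ranked`, `running` (the running-sum vector), `peak`.
#' @export
gsea_preranked <- function(ranked, gene_set, weight = 1, n_perm = 1000,
                           seed = 1, set_name = "set") {
  stopifnot(all(c("gene_id", "score") %in% names(ranked)),
            all(is.finite(ranked$score)))
  if (anyDuplicated(ranked$gene_id)) stop("duplicate gene_id in ranked list")
  ord <- order(-ranked$score)  # stable: ties keep input order
  genes <- ranked$gene_id[ord]
  scores <- ranked$score[ord]
  in_set <- genes %in% gene_set
  if (!any(in_set)) stop("gene set shares no genes with the ranked list")
  obs <- gsea_running_sum(in_set, scores, weight)
  es <- obs$es

  nes <- NA_real_
  p <- NA_real_
  if (n_perm > 0 && es != 0) {
    set.seed(seed)
    k <- sum(in_set)
    null_es <- vapply(seq_len(n_perm), function(i) {
      perm <- logical(length(genes))
      perm[sample.int(length(genes), k)] <- TRUE
      gsea_running_sum(perm, scores, weight)$es
    }, numeric(1))
    same_sign <- null_es[sign(null_es) == sign(es)]
    if (length(same_sign) > 0) {
      nes <- es / mean(abs(same_sign))
      p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
    } else {
      nes <- sign(es) * Inf
      p <- 1 / (1 + n_perm)
    }
  }
  core <- if (is.na(obs$peak)) character() else if (es >= 0)
    genes[seq_len(obs$peak)][in_set[seq_len(obs$peak)]] else
    rev(genes[obs$peak:length(genes)][in_set[obs$peak:length(genes)]])
  structure(list(
    set_name = set_name, es = es, nes = nes, p_value = p,
    direction = if (es >= 0) "positive" else "negative",
    core_genes = core, n_set = sum(in_set), n_ranked = length(genes),
    running = obs$running, peak = obs$peak
  ), class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("<gsea_result> ", x$set_name, ": ES = ", signif(x$es, 3),
      ", NES = ", signif(x$nes, 3), ", p = ", signif(x$p_value, 3),
      " (", x$n_set, "/", x$n_ranked, " genes; ", length(x$core_genes),
      " core)\n", sep = "")
  invisible(x)
}

#' Permutation test for pathway-set overlap
#'
#' Tests whether two significant-pathway sets share more pathways than
#' expected by chance: each of `n_perm` permutations draws random pathway
#' sets of the observed sizes (uniformly, without replacement) from the
#' universe and records the overlap; a normal distribution is fitted to the
#' permutation overlaps and the p-value is the upper-tail normal survival of
#' the observed overlap.
#'
#' @param sig_a,sig_b Character vectors of significant pathway names
#'   (subsets of `universe`).
#' @param universe Character vector of all candidate pathways.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return A list of class `overlap_test`: `observed`, `perm_mean`,
#'   `perm_sd`, `z`, `p_value`, `n_perm`, `degenerate` (TRUE when the
#'   permutation sd is zero).
#' @export
pathway_overlap_test <- function(sig_a, sig_b, universe, n_perm = 10000,
                                 seed = 1) {
  universe <- unique(universe)
  sig_a <- unique(sig_a)
  sig_b <- unique(sig_b)
  stopifnot(all(sig_a %in% universe), all(sig_b %in% universe))
  observed <- length(intersect(sig_a, sig_b))
  set.seed(seed)
  n <- length(universe)
  na <- length(sig_a)
  nb <- length(sig_b)
  perm <- vapply(seq_len(n_perm), function(i) {
    a <- sample.int(n, na)
    b <- sample.int(n, nb)
    length(intersect(a, b))
  }, numeric(1))
  m <- mean(perm)
  s <- stats::sd(perm)
  degenerate <- is.na(s) || s == 0
  if (degenerate) {
    z <- NA_real_
    p <- if (observed <= m) 1 else .Machine$double.xmin
  } else {
    z <- (observed - m) / s
    p <- stats::pnorm(observed, mean = m, sd = s, lower.tail = FALSE)
  }
  structure(list(observed = observed, perm_mean = m, perm_sd = s, z = z,
                 p_value = p, n_perm = n_perm, degenerate = degenerate),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("<overlap_test> observed = ", x$observed, ", null = ",
      signif(x$perm_mean, 4), " +/- ", signif(x$perm_sd, 4),
      " (", x$n_perm, " perms), z = ", signif(x$z, 3), ", p = ",
      signif(x$p_value, 3), if (x$degenerate) " [degenerate null]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Build a shared-pathway overlap network across exposures
#'
#' Nodes are exposures sized by their number of enriched pathways; an
#' undirected edge connects two exposures for every direction in which they
#' share at least one pathway enriched in the same direction, weighted by
#' the shared count. When a pathway universe is supplied, each edge also
#' carries a [pathway_overlap_test()] result.
#'
#' @param enriched Named list (>= 2 exposures); each element is a list with
#'   character vectors `positive` and `negative` of enriched pathway names.
#' @param universe Optional pathway universe for per-edge permutation tests.
#' @param n_perm Permutations per edge test (0 disables the tests).
#' @param seed Integer seed.
#' @return A list of class `overlap_network` with `nodes` (tibble
#'   `exposure`, `n_pathways`) and `edges` (tibble `from`, `to`,
#'   `direction`, `weight`, and `perm_mean`/`perm_sd`/`z`/`p_value` when
#'   tested).
#' @export
build_overlap_network <- function(enriched, universe = NULL, n_perm = 0,
                                  seed = 1) {
  stopifnot(length(enriched) >= 2, !is.null(names(enriched)))
  nodes <- tibble::tibble(
    exposure = names(enriched),
    n_pathways = vapply(enriched, function(e) {
      length(e$positive) + length(e$negative)
    }, integer(1), USE.NAMES = FALSE)
  )
  pairs <- utils::combn(names(enriched), 2, simplify = FALSE)
  edges <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(c("positive", "negative"), function(dir) {
      a <- enriched[[pr[1]]][[dir]]
      b <- enriched[[pr[2]]][[dir]]
      w <- length(intersect(a, b))
      if (w < 1) return(NULL)
      row <- tibble::tibble(from = pr[1], to = pr[2], direction = dir,
                            weight = w)
      if (!is.null(universe) && n_perm > 0) {
        tst <- pathway_overlap_test(a, b, universe, n_perm = n_perm,
                                    seed = seed)
        row$perm_mean <- tst$perm_mean
        row$perm_sd <- tst$perm_sd
        row$z <- tst$z
        row$p_value <- tst$p_value
      }
      row
    })
  })
  structure(list(nodes = nodes, edges = edges), class = "overlap_network")
}

#' @export
print.overlap_network <- function(x, ...) {
  cat("<overlap_network> ", nrow(x$nodes), " exposures, ", nrow(x$edges),
      " direction-matched edges\n", sep = "")
  invisible(x)
}
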