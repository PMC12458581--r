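#' Per-gene z-score matrix
#'
#' Each gene (row) is centred and scaled across samples using the population
#' standard deviation (divisor n). Zero-variance genes are set to z = 0
#' everywhere and flagged in the `zero_variance` attribute.
#'
#' @param expression Genes-by-samples numeric matrix (>= 2 samples).
#' @return Matrix of the same shape; attribute `zero_variance` lists the
#'   flattened genes.
#' @export
zscore_matrix <- function(expression) {
  stopifnot(is.matrix(expression))
  if (ncol(expression) < 2) stop("z-scoring needs >= 2 samples")
  mu <- rowMeans(expression)
  centred <- expression - mu
  sd_pop <- sqrt(rowMeans(centred^2))
  flat <- sd_pop == 0
  sd_pop[flat] <- 1
  z <- centred / sd_pop
  z[flat, ] <- 0
  attr(z, "zero_variance") <- rownames(expression)[flat]
  z
}

#' Summed z-score signature activity
#'
#' The per-sample signature score adds the z-scores of the signature's up
#' genes and subtracts the z-scores of its down genes. Signature genes
#' absent from the matrix are skipped; `n_genes_used` records how many were
#' present.
#'
#' @param z Z-score matrix from [zscore_matrix()].
#' @param signature A [gene_signature()] (at least one gene must be present
#'   in the matrix).
#' @return Tibble with columns `sample_id`, `score`; attributes
#'   `signature_name`, `n_genes_used`, `n_genes_missing`.
#' @export
signature_score <- function(z, signature) {
  stopifnot(inherits(signature, "gene_signature"))
  up <- intersect(signature$up, rownames(z))
  down <- intersect(signature$down, rownames(z))
  n_used <- length(up) + length(down)
  if (n_used == 0) {
    stop("no genes of signature '", signature$name, "' present in the matrix")
  }
  score <- colSums(z[up, , drop = FALSE]) - colSums(z[down, , drop = FALSE])
  out <- tibble::tibble(sample_id = colnames(z), score = unname(score))
  attr(out, "signature_name") <- signature$name
  attr(out, "n_genes_used") <- n_used
  attr(out, "n_genes_missing") <- length(signature) - n_used
  out
}

assoc_result <- function(r, p, n, note = NA_character_) {
  structure(list(r = r, p_value = p, n = n, note = note),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("<assoc_result> r = ", signif(x$r, 3), ", p = ", signif(x$p_value, 3),
      ", n = ", x$n, if (!is.na(x$note)) paste0(" [", x$note, "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Pearson correlation between two signature score vectors
#'
#' Scores are matched by `sample_id`; pairs with a missing score are
#' dropped. Zero variance in either vector yields an explicit null result
#' (`r = NA`).
#'
#' @param scores_a,scores_b Score tibbles from [signature_score()].
#' @return An `assoc_result`: `r`, `p_value` (two-sided t approximation),
#'   `n`.
#' @export
score_correlation <- function(scores_a, scores_b) {
  joined <- dplyr::inner_join(scores_a, scores_b, by = "sample_id",
                              suffix = c("_a", "_b")) |>
    dplyr::filter(!is.na(.data$score_a), !is.na(.data$score_b))
  n <- nrow(joined)
  if (n < 3) stop("need >= 3 paired samples")
  if (stats::sd(joined$score_a) == 0 || stats::sd(joined$score_b) == 0) {
    return(assoc_result(NA_real_, NA_real_, n, note = "zero variance"))
  }
  ct <- stats::cor.test(joined$score_a, joined$score_b, method = "pearson")
  assoc_result(unname(ct$estimate), ct$p.value, n)
}

#' Map a mouse signature to human homologs
#'
#' Replaces each mouse gene by all of its mapped human genes. Unmapped mouse
#' genes are dropped and counted; a human gene receiving conflicting
#' directions (one mouse source up, another down) is excluded with a
#' warning.
#'
#' @param signature A mouse [gene_signature()].
#' @param map Tibble with columns `mouse`, `human` (unique pairs).
#' @return A human [gene_signature()]; attributes `n_unmapped` and
#'   `conflicts` record the dropped genes.
#' @export
map_homologs <- function(signature, map) {
  stopifnot(all(c("mouse", "human") %in% names(map)))
  map <- dplyr::distinct(map, .data$mouse, .data$human)
  tab <- signature_table(signature) |>
    dplyr::left_join(map, by = c(gene_id = "mouse"),
                     relationship = "many-to-many")
  n_unmapped <- length(unique(tab$gene_id[is.na(tab$human)]))
  tab <- dplyr::filter(tab, !is.na(.data$human))
  dirs <- tab |>
    dplyr::distinct(.data$human, .data$direction) |>
    dplyr::count(.data$human, name = "n_dir")
  conflicts <- dirs$human[dirs$n_dir > 1]
  if (length(conflicts) > 0) {
    warning("dropping ", length(conflicts),
            " human gene(s) with conflicting directions: ",
            paste(utils::head(conflicts, 5), collapse = ", "))
    tab <- dplyr::filter(tab, !.data$human %in% conflicts)
  }
  out <- gene_signature(
    paste0(signature$name, ".human"),
    up = tab$human[tab$direction == "up"],
    down = tab$human[tab$direction == "down"]
  )
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "conflicts") <- conflicts
  out
}

#' Ordinal disease-severity association of signature scores
#'
#' Encodes the supplied severity labels as 0 .. k-1 in the given order and
#' correlates the encoding with the signature scores (Pearson, two-sided
#' p).
#'
#' @param scores Score tibble from [signature_score()].
#' @param states Character vector of per-sample severity labels, parallel to
#'   `scores$sample_id` or named by sample ID.
#' @param levels Ordered severity labels, least severe first.
#' @return An `assoc_result`: `r`, `p_value`, `n`.
#' @export
severity_association <- function(scores, states, levels) {
  if (!is.null(names(states))) states <- states[scores$sample_id]
  stopifnot(length(states) == nrow(scores))
  if (length(levels) < 2) stop("need >= 2 severity levels")
  unseen <- setdiff(unique(states), levels)
  if (length(unseen) > 0) {
    stop("state label(s) not in severity order: ",
         paste(unseen, collapse = ", "))
  }
  enc <- match(states, levels) - 1
  if (length(unique(enc)) < 2) {
    return(assoc_result(NA_real_, NA_real_, length(enc),
                        note = "single observed severity level"))
  }
  ct <- stats::cor.test(scores$score, enc, method = "pearson")
  assoc_result(unname(ct$estimate), ct$p.value, nrow(scores))
}
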