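#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a preranked GSEA result
#'
#' @param x A [gsea_preranked()] result.
#' @param ... Unused.
#' @return One-row tibble: `set_name`, `es`, `nes`, `p_value`, `direction`,
#'   `n_core`.
#' @method tidy gsea_result
#' @export
tidy.gsea_result <- function(x, ...) {
  tibble::tibble(
    set_name = x$set_name, es = x$es, nes = x$nes, p_value = x$p_value,
    direction = x$direction, n_core = length(x$core_genes)
  )
}

#' @rdname tidy.gsea_result
#' @method glance gsea_result
#' @export
glance.gsea_result <- function(x, ...) {
  tibble::tibble(n_set = x$n_set, n_ranked = x$n_ranked, peak_rank = x$peak)
}

#' Tidy a pathway-overlap permutation test
#'
#' @param x A [pathway_overlap_test()] result.
#' @param ... Unused.
#' @return One-row tibble: `observed`, `perm_mean`, `perm_sd`, `z`,
#'   `p_value`, `n_perm`, `degenerate`.
#' @method tidy overlap_test
#' @export
tidy.overlap_test <- function(x, ...) {
  tibble::tibble(
    observed = x$observed, perm_mean = x$perm_mean, perm_sd = x$perm_sd,
    z = x$z, p_value = x$p_value, n_perm = x$n_perm,
    degenerate = x$degenerate
  )
}

#' Tidy a correlation / association result
#'
#' @param x An `assoc_result` from [score_correlation()] or
#'   [severity_association()].
#' @param ... Unused.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @method tidy assoc_result
#' @export
tidy.assoc_result <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, n = x$n)
}

#' Tidy a trajectory classification
#'
#' @param x A [classify_trajectories()] result.
#' @param ... Unused.
#' @return The per-gene calls tibble.
#' @method tidy trajectory_classification
#' @export
tidy.trajectory_classification <- function(x, ...) x$calls

#' @rdname tidy.trajectory_classification
#' @method glance trajectory_classification
#' @export
glance.trajectory_classification <- function(x, ...) x$summary

#' Tidy a concordance classification
#'
#' @param x A [classify_concordance()] result.
#' @param ... Unused.
#' @return The per-record tibble with concordant flags.
#' @method tidy concordance_result
#' @export
tidy.concordance_result <- function(x, ...) x$records

#' @rdname tidy.concordance_result
#' @method glance concordance_result
#' @export
glance.concordance_result <- function(x, ...) x$summary
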