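#' Overlap fraction as an integer percent
#'
#' Reported overlap fractions are printed as integer percents; this helper
#' computes the exact percent plus two rounding conventions that both occur
#' in practice: nearest integer (half away from zero) and floor (truncation).
#'
#' @param n_overlap Overlap count (0 <= n_overlap <= n_total).
#' @param n_total Total count (> 0).
#' @return A tibble with one row: `n_overlap`, `n_total`, `percent_exact`,
#'   `percent` (nearest integer, half away from zero), `percent_floor`.
#' @export
overlap_fraction <- function(n_overlap, n_total) {
  if (any(n_total <= 0)) stop("n_total must be > 0")
  if (any(n_overlap < 0) || any(n_overlap > n_total)) {
    stop("need 0 <= n_overlap <= n_total")
  }
  pct <- 100 * n_overlap / n_total
  tibble::tibble(
    n_overlap = n_overlap,
    n_total = n_total,
    percent_exact = pct,
    percent = round_half_away(pct),
    percent_floor = floor(pct)
  )
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Partition two sex-specific signatures
#'
#' Splits the union of two sex-specific signatures into seven disjoint sets:
#' shared (same direction in both sexes), sex-specific (up/down, one sex
#' only), and discordant (opposite directions in the two sexes).
#'
#' @param sig_male,sig_female [gene_signature()] objects.
#' @return A named list of character vectors: `shared_up`, `shared_down`,
#'   `male_only_up`, `male_only_down`, `female_only_up`, `female_only_down`,
#'   `discordant`.
#' @export
sex_partition <- function(sig_male, sig_female) {
  list(
    shared_up = intersect(sig_male$up, sig_female$up),
    shared_down = intersect(sig_male$down, sig_female$down),
    male_only_up = setdiff(sig_male$up, signature_genes(sig_female)),
    male_only_down = setdiff(sig_male$down, signature_genes(sig_female)),
    female_only_up = setdiff(sig_female$up, signature_genes(sig_male)),
    female_only_down = setdiff(sig_female$down, signature_genes(sig_male)),
    discordant = union(intersect(sig_male$up, sig_female$down),
                       intersect(sig_male$down, sig_female$up))
  )
}

#' Build a composite signature from two sex-specific signatures
#'
#' Union of same-direction calls across sexes; genes discordant between the
#' sexes are excluded from the composite (they remain visible in
#' [sex_partition()]).
#'
#' @param sig_male,sig_female [gene_signature()] objects.
#' @param name Name for the composite.
#' @return A [gene_signature()].
#' @export
composite_signature <- function(sig_male, sig_female, name = "composite") {
  disc <- sex_partition(sig_male, sig_female)$discordant
  gene_signature(
    name,
    up = setdiff(union(sig_male$up, sig_female$up), disc),
    down = setdiff(union(sig_male$down, sig_female$down), disc)
  )
}

#' Classify exposure-vs-aging trajectories
#'
#' For every gene present in both an exposure signature and an
#' aging-plasticity signature, compares the exposure direction with the
#' normal aging direction: opposite directions mean the exposure attenuated
#' the gene's aging trajectory (an aging-up gene stays low, an aging-down
#' gene stays high); same direction means acceleration.
#'
#' @param exposure_sig Exposure [gene_signature()].
#' @param laasp_sig Aging-plasticity [gene_signature()].
#' @return A list of class `trajectory_classification` with `calls` (tibble
#'   `gene_id`, `aging_direction`, `exposure_direction`, `class`) and
#'   `summary` (one-row tibble: `exposure`, `n_signature`, `n_overlap`,
#'   `percent` columns from [overlap_fraction()], `n_attenuated`,
#'   `n_accelerated`).
#' @export
classify_trajectories <- function(exposure_sig, laasp_sig) {
  expo <- signature_table(exposure_sig)
  aging <- signature_table(laasp_sig)
  calls <- dplyr::inner_join(
    dplyr::select(expo, "gene_id", exposure_direction = "direction"),
    dplyr::select(aging, "gene_id", aging_direction = "direction"),
    by = "gene_id"
  ) |>
    dplyr::mutate(
      class = ifelse(.data$aging_direction == .data$exposure_direction,
                     "accelerated", "attenuated")
    ) |>
    dplyr::select("gene_id", "aging_direction", "exposure_direction", "class")
  n_sig <- length(exposure_sig)
  frac <- if (n_sig > 0) overlap_fraction(nrow(calls), n_sig) else
    tibble::tibble(n_overlap = 0L, n_total = 0L, percent_exact = NA_real_,
                   percent = NA_real_, percent_floor = NA_real_)
  summary <- tibble::tibble(
    exposure = exposure_sig$name,
    n_signature = n_sig,
    n_overlap = nrow(calls),
    percent_exact = frac$percent_exact,
    percent = frac$percent,
    n_attenuated = sum(calls$class == "attenuated"),
    n_accelerated = sum(calls$class == "accelerated")
  )
  structure(list(calls = calls, summary = summary),
            class = "trajectory_classification")
}

#' @export
print.trajectory_classification <- function(x, ...) {
  s <- x$summary
  cat("<trajectory_classification> ", s$exposure, ": ", s$n_overlap, "/",
      s$n_signature, " signature genes are aging-plasticity genes (",
      round(s$percent_exact, 1), "%); ", s$n_attenuated, " attenuated, ",
      s$n_accelerated, " accelerated\n", sep = "")
  invisible(x)
}

#' Exact multi-set overlap (Venn region) counts
#'
#' Assigns every gene in the union to its exact membership pattern across
#' the named sets and counts each non-empty region by inclusion-exclusion
#' enumeration (region counts always sum to the union size).
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return A tibble with columns `region` (set names joined by `&`),
#'   `degree` (number of member sets) and `n` (exclusive region count),
#'   plus attribute `union_size`.
#' @export
core_overlap <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  out <- tibble::tibble(region = pattern) |>
    dplyr::count(.data$region, name = "n") |>
    dplyr::mutate(degree = stringr::str_count(.data$region, "&") + 1L) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$region) |>
    dplyr::select("region", "degree", "n")
  attr(out, "union_size") <- length(universe)
  out
}
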