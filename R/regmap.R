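#' Default histone-mark polarity map
#'
#' H3K27ac, H3K4me1 and H3K4me3 are active marks; H3K27me3 and H3K9me3 are
#' repressive.
#'
#' @return Named character vector mark -> `"active"` / `"repressive"`.
#' @export
mark_polarity <- function() {
  c(H3K27ac = "active", H3K4me1 = "active", H3K4me3 = "active",
    H3K27me3 = "repressive", H3K9me3 = "repressive")
}

# 0-based half-open tibble -> GRanges (1-based closed) on the way in
intervals_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Strand-aware promoter windows around TSS
#'
#' For every gene, the window `[tss - flank, tss + flank)` (0-based
#' half-open) clipped at zero. The window is symmetric about the TSS, so it
#' has identical width on either strand when unclipped.
#'
#' @param annotation Tibble with columns `gene_id`, `chrom`, `tss`,
#'   `strand`.
#' @param flank Flank in bp on each side of the TSS (default 3000).
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
promoter_windows <- function(annotation, flank = 3000) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(annotation)),
            all(annotation$tss >= 0), flank > 0)
  if (anyDuplicated(annotation$gene_id)) stop("duplicate gene_id in annotation")
  tibble::tibble(
    gene_id = annotation$gene_id,
    chrom = annotation$chrom,
    start = as.integer(pmax(0L, annotation$tss - as.integer(flank))),
    end = as.integer(annotation$tss + as.integer(flank)),
    strand = annotation$strand
  )
}

#' Merge catalog enhancers into anchors
#'
#' Enhancers that overlap, or whose gap is at most `max_gap` bp (0 means
#' only overlapping or book-ended intervals), are consolidated into a single
#' anchor spanning their union; each anchor carries the union of its
#' constituent enhancers' linked genes. Output is deterministic for any
#' input order.
#'
#' @param enhancers Tibble with columns `chrom`, `start`, `end`,
#'   `enhancer_id` (0-based half-open).
#' @param links Tibble with columns `enhancer_id`, `gene_id`.
#' @param max_gap Maximum gap in bp merged across (default 0).
#' @return A list of class `anchor_set` with `anchors` (tibble `chrom`,
#'   `start`, `end`, `anchor_id`, `n_source_enhancers`) and `links` (tibble
#'   `anchor_id`, `gene_id`).
#' @export
build_anchors <- function(enhancers, links, max_gap = 0) {
  validate_intervals(enhancers)
  stopifnot("enhancer_id" %in% names(enhancers),
            all(c("enhancer_id", "gene_id") %in% names(links)),
            max_gap >= 0)
  enh <- dplyr::arrange(enhancers, .data$chrom, .data$start, .data$end)
  gr <- intervals_to_gr(enh)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  # with min.gapwidth merging, every enhancer overlaps exactly one reduced range
  grp <- integer(nrow(enh))
  grp[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  anchors <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red)
  ) |>
    dplyr::mutate(
      anchor_id = paste0(.data$chrom, ":", .data$start, "-", .data$end),
      n_source_enhancers = as.integer(tabulate(grp, nbins = dplyr::n()))
    )
  anchor_links <- tibble::tibble(
    enhancer_id = enh$enhancer_id,
    anchor_id = anchors$anchor_id[grp]
  ) |>
    dplyr::inner_join(links, by = "enhancer_id",
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$anchor_id, .data$gene_id) |>
    dplyr::arrange(.data$anchor_id, .data$gene_id)
  structure(list(anchors = anchors, links = anchor_links),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("<anchor_set> ", nrow(x$anchors), " anchors from ",
      sum(x$anchors$n_source_enhancers), " enhancers; ",
      nrow(x$links), " anchor-gene links\n", sep = "")
  invisible(x)
}

#' Assign differential peaks to promoters and enhancer anchors
#'
#' A peak is assigned to a gene when it overlaps the gene's promoter window
#' or a linked enhancer anchor by at least 1 bp (half-open semantics: an
#' exactly abutting peak is not assigned). Peaks hitting several promoters
#' or multi-gene anchors produce one row per (gene, region); peaks hitting
#' nothing are dropped and counted in the `n_unassigned` attribute.
#'
#' @param deps Differential-peak tibble (from [call_deps()]): columns
#'   `chrom`, `start`, `end`, `feature_id`, `direction`.
#' @param promoters Promoter windows from [promoter_windows()].
#' @param anchors An [build_anchors()] `anchor_set`.
#' @param mark Mark name recorded on every row.
#' @return Tibble with columns `gene_id`, `mark`, `region_class`
#'   (`"promoter"` / `"enhancer"`), `peak_id`, `peak_direction`; attribute
#'   `n_unassigned` counts dropped peaks.
#' @export
assign_peaks <- function(deps, promoters, anchors, mark) {
  stopifnot(inherits(anchors, "anchor_set"))
  if (nrow(deps) == 0) {
    out <- tibble::tibble(gene_id = character(), mark = character(),
                          region_class = character(), peak_id = character(),
                          peak_direction = character())
    attr(out, "n_unassigned") <- 0L
    return(out)
  }
  gr_peak <- intervals_to_gr(deps)
  overlap_rows <- function(targets, ids, region_class) {
    if (nrow(targets) == 0) return(NULL)
    hit <- GenomicRanges::findOverlaps(gr_peak, intervals_to_gr(targets))
    if (length(hit) == 0) return(NULL)
    tibble::tibble(
      peak_row = S4Vectors::queryHits(hit),
      target_id = ids[S4Vectors::subjectHits(hit)],
      region_class = region_class
    )
  }
  prom_hits <- overlap_rows(promoters, promoters$gene_id, "promoter")
  anch_hits <- overlap_rows(anchors$anchors, anchors$anchors$anchor_id,
                            "enhancer")
  if (!is.null(anch_hits)) {
    anch_hits <- dplyr::inner_join(
      anch_hits, anchors$links, by = c(target_id = "anchor_id"),
      relationship = "many-to-many"
    ) |>
      dplyr::transmute(.data$peak_row, target_id = .data$gene_id,
                       .data$region_class)
  }
  hits <- dplyr::bind_rows(prom_hits, anch_hits)
  if (is.null(hits) || nrow(hits) == 0) {
    out <- tibble::tibble(gene_id = character(), mark = character(),
                          region_class = character(), peak_id = character(),
                          peak_direction = character())
    attr(out, "n_unassigned") <- nrow(deps)
    return(out)
  }
  out <- tibble::tibble(
    gene_id = hits$target_id,
    mark = mark,
    region_class = hits$region_class,
    peak_id = deps$feature_id[hits$peak_row],
    peak_direction = deps$direction[hits$peak_row]
  ) |>
    dplyr::distinct()
  attr(out, "n_unassigned") <- nrow(deps) - length(unique(hits$peak_row))
  out
}

#' Classify expression / histone-mark concordance
#'
#' A peak record is concordant with its gene when, for an active mark, the
#' peak direction matches the expression direction, or, for a repressive
#' mark, opposes it (loss of active or gain of repressive marks with
#' decreased expression; gain of active or loss of repressive marks with
#' increased expression). Each differential gene is then assigned a category
#' from its concordant records only: `promoter_only`, `enhancer_only`,
#' `both`, or `neither`; the categories partition the differential gene
#' list.
#'
#' @param assignments Peak-to-gene assignment table from [assign_peaks()]
#'   (rows from several marks may be bound together).
#' @param gene_diff Differential gene tibble restricted to non-`ns` genes:
#'   columns `feature_id`, `direction`.
#' @param polarity Named vector mark -> polarity; see [mark_polarity()].
#' @return A list of class `concordance_result` with `records` (per
#'   gene x mark x region row with `concordant` flag), `categories` (tibble
#'   `gene_id`, `category`), and `summary` (category counts plus the percent
#'   of genes with >= 1 concordant record, via [overlap_fraction()]).
#' @export
classify_concordance <- function(assignments, gene_diff,
                                 polarity = mark_polarity()) {
  stopifnot(all(c("feature_id", "direction") %in% names(gene_diff)))
  gene_diff <- dplyr::filter(gene_diff, .data$direction %in% c("up", "down"))
  unknown <- setdiff(unique(assignments$mark), names(polarity))
  if (length(unknown) > 0) {
    stop("mark(s) absent from polarity map: ", paste(unknown, collapse = ", "))
  }
  records <- dplyr::inner_join(
    assignments,
    dplyr::select(gene_diff, gene_id = "feature_id",
                  expression_direction = "direction"),
    by = "gene_id"
  ) |>
    dplyr::mutate(
      polarity = unname(polarity[.data$mark]),
      concordant = ifelse(.data$polarity == "active",
                          .data$peak_direction == .data$expression_direction,
                          .data$peak_direction != .data$expression_direction)
    )
  conc <- dplyr::filter(records, .data$concordant) |>
    dplyr::distinct(.data$gene_id, .data$region_class) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      category = dplyr::case_when(
        all(c("promoter", "enhancer") %in% region_class) ~ "both",
        "promoter" %in% region_class ~ "promoter_only",
        TRUE ~ "enhancer_only"
      ),
      .groups = "drop"
    )
  categories <- tibble::tibble(gene_id = gene_diff$feature_id) |>
    dplyr::left_join(conc, by = "gene_id") |>
    dplyr::mutate(category = dplyr::coalesce(.data$category, "neither"))
  n_conc <- sum(categories$category != "neither")
  summary <- tibble::tibble(
    n_genes = nrow(categories),
    promoter_only = sum(categories$category == "promoter_only"),
    enhancer_only = sum(categories$category == "enhancer_only"),
    both = sum(categories$category == "both"),
    neither = sum(categories$category == "neither")
  )
  summary <- dplyr::bind_cols(
    summary,
    if (nrow(categories) > 0) {
      dplyr::select(overlap_fraction(n_conc, nrow(categories)),
                    percent_concordant_exact = "percent_exact",
                    percent_concordant = "percent",
                    percent_concordant_floor = "percent_floor")
    } else {
      tibble::tibble(percent_concordant_exact = NA_real_,
                     percent_concordant = NA_real_,
                     percent_concordant_floor = NA_real_)
    }
  )
  structure(list(records = records, categories = categories,
                 summary = summary),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  s <- x$summary
  cat("<concordance_result> ", s$n_genes, " differential genes: ",
      s$promoter_only, " promoter-only, ", s$enhancer_only,
      " enhancer-only, ", s$both, " both, ", s$neither, " neither (",
      round(s$percent_concordant_exact, 1), "% concordant)\n", sep = "")
  invisible(x)
}

#' Per-gene counts of linked anchors carrying differential peaks
#'
#' For every gene, counts the linked enhancer anchors that overlap at least
#' one differential peak, and reports the mean over genes with at least one
#' hit as well as over all genes.
#'
#' @param anchors An [build_anchors()] `anchor_set`.
#' @param deps Differential-peak tibble (`chrom`, `start`, `end`).
#' @param genes Character vector of gene IDs to report on.
#' @return A list with `per_gene` (tibble `gene_id`, `n_hit_anchors`),
#'   `mean_hit` (mean over genes with >= 1 hit; 0 when none) and `mean_all`
#'   (mean over all requested genes).
#' @export
linked_enhancer_stats <- function(anchors, deps, genes) {
  stopifnot(inherits(anchors, "anchor_set"))
  hit_anchor_ids <- character()
  if (nrow(deps) > 0 && nrow(anchors$anchors) > 0) {
    hit <- GenomicRanges::findOverlaps(intervals_to_gr(anchors$anchors),
                                       intervals_to_gr(deps))
    hit_anchor_ids <- anchors$anchors$anchor_id[
      unique(S4Vectors::queryHits(hit))]
  }
  per_gene <- tibble::tibble(gene_id = unique(genes)) |>
    dplyr::left_join(
      anchors$links |>
        dplyr::filter(.data$anchor_id %in% hit_anchor_ids) |>
        dplyr::count(.data$gene_id, name = "n_hit_anchors"),
      by = "gene_id"
    ) |>
    dplyr::mutate(n_hit_anchors = dplyr::coalesce(.data$n_hit_anchors, 0L))
  with_hit <- per_gene$n_hit_anchors[per_gene$n_hit_anchors > 0]
  list(
    per_gene = per_gene,
    mean_hit = if (length(with_hit) > 0) mean(with_hit) else 0,
    mean_all = mean(per_gene$n_hit_anchors)
  )
}
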