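#' Simulate a gene-set compendium correlated with planted structure
#'
#' Builds an MSigDB-style compendium over the simulated gene universe. A
#' fraction of the sets is biased toward the planted aging-plasticity genes
#' (members drawn 60/40 from aging genes vs the rest), emulating the way
#' real aging genes concentrate in functional pathways; the remaining sets
#' are uniform draws.
#'
#' @param study A [simulate_study()] result.
#' @param n_sets Number of gene sets.
#' @param set_size Genes per set.
#' @param frac_biased Fraction of sets biased toward aging genes.
#' @param seed Integer seed.
#' @return Named list of character vectors (a `read_gmt()`-shaped
#'   collection).
#' @export
simulate_gene_sets <- function(study, n_sets = 50, set_size = 40,
                               frac_biased = 0.3, seed = 1) {
  stopifnot(inherits(study, "sim_study"))
  set.seed(seed)
  genes <- study$annotation$gene_id
  aging <- study$truth$aging
  up <- aging$gene_id[aging$aging_direction == "up"]
  down <- aging$gene_id[aging$aging_direction == "down"]
  n_biased <- round(frac_biased * n_sets)
  sets <- lapply(seq_len(n_sets), function(i) {
    if (i <= n_biased) {
      pool <- if (i %% 2 == 1) up else down
      n_pool <- min(round(0.6 * set_size), length(pool))
      c(sample(pool, n_pool),
        sample(setdiff(genes, pool), set_size - n_pool))
    } else {
      sample(genes, set_size)
    }
  })
  names(sets) <- sprintf("PATHWAY_%03d", seq_len(n_sets))
  sets
}

#' Configuration for a full pipeline run
#'
#' @param sim A [simulation_config()]; its seed drives every stage.
#' @param thr A [thresholds()] object.
#' @param flank Promoter flank in bp.
#' @param max_gap Anchor-merge gap in bp.
#' @param n_gene_sets,set_size Compendium shape for [simulate_gene_sets()].
#' @param gsea_n_perm Permutations per preranked GSEA run.
#' @param overlap_n_perm Permutations per pathway-overlap edge test.
#' @param cohort_n,cohort_effect,severity_levels Cohort simulation settings
#'   for [simulate_cohort()].
#' @param out_dir Optional directory: when set, every intermediate table and
#'   the report JSON are written there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(),
                       thr = thresholds(),
                       flank = 3000,
                       max_gap = 0,
                       n_gene_sets = 50,
                       set_size = 40,
                       gsea_n_perm = 200,
                       overlap_n_perm = 2000,
                       cohort_n = 200,
                       cohort_effect = 1,
                       severity_levels = c("normal", "steatosis", "NASH", "HCC"),
                       out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"), inherits(thr, "laasp_thresholds"))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full synthetic study pipeline
#'
#' Executes every stage on a simulated study: differential expression per
#' contrast, aging-plasticity signature derivation, exposure trajectory
#' classification (attenuated vs accelerated), differential peaks with
#' promoter/anchor assignment and concordance categories, ORA-based
#' pathway enrichment with the shared-pathway overlap network and its
#' permutation tests, preranked GSEA of the aging ranking, and summed
#' z-score signature scoring on a simulated severity cohort. All randomness
#' derives from the simulation seed; identical configs give identical
#' reports.
#'
#' @param config A [run_config()].
#' @return A list of class `study_report`; see the elements written in the
#'   report JSON when `out_dir` is set.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$sim$seed
  study <- simulate_study(config$sim)
  sims <- study$samples
  ages <- config$sim$age_groups
  adult <- ages[length(ages)]
  arms <- setdiff(config$sim$exposures, "vehicle")

  sample_ids <- function(exposure, age) {
    sims$sample_id[sims$exposure == exposure & sims$age == age]
  }

  # aging contrast (vehicle young vs vehicle adult) and exposure contrasts
  aging_diff <- call_degs(study$counts,
                          group_a = sample_ids("vehicle", ages[1]),
                          group_b = sample_ids("vehicle", adult),
                          thr = config$thr)
  laasp_sig <- derive_signature(aging_diff, "aging")
  exposure_diff <- purrr::map(
    rlang::set_names(arms),
    function(arm) call_degs(study$counts,
                            group_a = sample_ids("vehicle", adult),
                            group_b = sample_ids(arm, adult),
                            thr = config$thr)
  )
  exposure_sigs <- purrr::imap(exposure_diff, derive_signature)
  trajectories <- purrr::map(exposure_sigs, classify_trajectories,
                             laasp_sig = laasp_sig)
  trajectory_summary <- purrr::map_dfr(trajectories, "summary") |>
    dplyr::mutate(
      attenuated_share = ifelse(.data$n_overlap > 0,
                                .data$n_attenuated / .data$n_overlap, NA_real_),
      accelerated_share = ifelse(.data$n_overlap > 0,
                                 .data$n_accelerated / .data$n_overlap, NA_real_)
    )

  # regulatory map on the aging contrast
  promoters <- promoter_windows(study$annotation, flank = config$flank)
  anchors <- build_anchors(study$enhancers, study$enhancer_links,
                           max_gap = config$max_gap)
  chip_a <- study$peak_samples$sample_id[study$peak_samples$age == ages[1]]
  chip_b <- study$peak_samples$sample_id[study$peak_samples$age ==
                                           ages[length(ages)]]
  deps <- purrr::imap(study$peak_counts, function(m, mark) {
    call_deps(study$peak_windows, m, group_a = chip_a, group_b = chip_b,
              thr = config$thr)
  })
  assignments <- purrr::imap_dfr(deps, function(d, mark) {
    assign_peaks(d, promoters, anchors, mark = mark)
  })
  polarity <- config$sim$marks
  concordance <- classify_concordance(assignments, aging_diff,
                                      polarity = polarity)
  all_deps <- dplyr::bind_rows(deps)
  enh_stats <- linked_enhancer_stats(anchors, all_deps,
                                     genes = signature_genes(laasp_sig))

  # enrichment: ORA per exposure signature, overlap network, aging GSEA
  gene_sets <- simulate_gene_sets(study, n_sets = config$n_gene_sets,
                                  set_size = config$set_size,
                                  seed = seed + 3L)
  universe <- study$annotation$gene_id
  ora_by_direction <- function(sig) {
    purrr::map(rlang::set_names(c("up", "down")), function(dir) {
      hits <- sig[[dir]]
      if (length(hits) == 0) return(character())
      p <- vapply(gene_sets, function(s) ora(hits, s, universe)$p_value,
                  numeric(1))
      names(gene_sets)[bh_fdr(p) < config$thr$alpha]
    })
  }
  enriched <- purrr::map(exposure_sigs, function(sig) {
    by_dir <- ora_by_direction(sig)
    list(positive = by_dir$up, negative = by_dir$down)
  })
  network <- build_overlap_network(enriched, universe = names(gene_sets),
                                   n_perm = config$overlap_n_perm,
                                   seed = seed + 4L)
  ranked <- dplyr::arrange(
    tibble::tibble(gene_id = aging_diff$feature_id,
                   score = aging_diff$log2fc),
    dplyr::desc(.data$score))
  gsea <- purrr::imap_dfr(gene_sets, function(s, nm) {
    res <- gsea_preranked(ranked, s, n_perm = config$gsea_n_perm,
                          seed = seed + 5L, set_name = nm)
    tibble::tibble(set_name = nm, es = res$es, nes = res$nes,
                   p_value = res$p_value, n_core = length(res$core_genes))
  })
  gsea$q_value <- bh_fdr(gsea$p_value)

  # signature scoring on a simulated severity cohort
  cohort <- simulate_cohort(laasp_sig, n_samples = config$cohort_n,
                            severity_levels = config$severity_levels,
                            effect = config$cohort_effect, seed = seed + 6L)
  z <- zscore_matrix(cohort$expression)
  scores <- purrr::map(c(list(aging = laasp_sig), exposure_sigs),
                       function(sig) signature_score(z, sig))
  sig_names <- names(scores)
  cor_matrix <- purrr::map_dfr(sig_names, function(a) {
    row <- purrr::map_dbl(sig_names, function(b) {
      score_correlation(scores[[a]], scores[[b]])$r
    })
    tibble::tibble(signature = a, !!!rlang::set_names(as.list(row), sig_names))
  })
  severity <- severity_association(scores$aging,
                                   cohort$samples$state,
                                   levels = cohort$severity_levels)

  report <- structure(list(
    seed = seed,
    n_genes = config$sim$n_genes,
    aging_diff = aging_diff,
    laasp_signature = laasp_sig,
    exposure_diff = exposure_diff,
    trajectories = trajectories,
    trajectory_summary = trajectory_summary,
    anchors = anchors,
    deps = deps,
    concordance = concordance,
    linked_enhancer_stats = enh_stats,
    enriched_pathways = enriched,
    overlap_network = network,
    gsea = gsea,
    score_correlation = cor_matrix,
    severity_association = severity,
    truth = study$truth,
    config = config
  ), class = "study_report")

  if (!is.null(config$out_dir)) write_report(report, study, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed ", x$seed, "\n", sep = "")
  cat("  aging signature: ", length(x$laasp_signature$up), " up, ",
      length(x$laasp_signature$down), " down\n", sep = "")
  print(x$trajectory_summary)
  print(x$concordance)
  invisible(x)
}

write_report <- function(report, study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$aging_diff, file.path(dir, "aging_diff.tsv"),
                   progress = FALSE)
  purrr::iwalk(report$exposure_diff, function(d, arm) {
    readr::write_tsv(d, file.path(dir, paste0("diff_", arm, ".tsv")),
                     progress = FALSE)
  })
  readr::write_tsv(signature_table(report$laasp_signature),
                   file.path(dir, "laasp_signature.tsv"), progress = FALSE)
  purrr::iwalk(report$trajectories, function(tr, arm) {
    readr::write_tsv(tr$calls, file.path(dir, paste0("trajectory_", arm, ".tsv")),
                     progress = FALSE)
  })
  write_bed(dplyr::mutate(report$anchors$anchors, name = .data$anchor_id),
            file.path(dir, "anchors.bed"))
  readr::write_tsv(report$anchors$links, file.path(dir, "anchor_links.tsv"),
                   progress = FALSE)
  purrr::iwalk(report$deps, function(d, mark) {
    readr::write_tsv(d, file.path(dir, paste0("deps_", mark, ".tsv")),
                     progress = FALSE)
  })
  readr::write_tsv(report$concordance$records,
                   file.path(dir, "concordance_records.tsv"), progress = FALSE)
  readr::write_tsv(report$concordance$categories,
                   file.path(dir, "concordance_categories.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$overlap_network$edges,
                   file.path(dir, "network_edges.tsv"), progress = FALSE)
  readr::write_tsv(report$gsea, file.path(dir, "gsea_aging.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$score_correlation,
                   file.path(dir, "score_correlation.tsv"), progress = FALSE)
  summary <- list(
    seed = report$seed,
    trajectory_summary = report$trajectory_summary,
    concordance_summary = report$concordance$summary,
    linked_enhancers = list(mean_hit = report$linked_enhancer_stats$mean_hit,
                            mean_all = report$linked_enhancer_stats$mean_all),
    severity_association = list(r = report$severity_association$r,
                                p_value = report$severity_association$p_value)
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
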