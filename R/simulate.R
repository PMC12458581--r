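#' Configuration for a synthetic exposure-aging study
#'
#' Defines the study design the generator emulates: age groups crossed with
#' exposure arms, negative-binomial expression counts with planted aging
#' effects, exposure effects that reverse (attenuate) or reinforce
#' (accelerate) a chosen fraction of the aging effects, tiled histone-mark
#' window counts whose differential direction is concordant with expression
#' at a configurable rate, and an enhancer catalog with adjacent intervals
#' and many-to-one gene links.
#'
#' @param n_genes Number of genes.
#' @param samples_per_group Replicates per exposure-by-age cell (>= 2).
#' @param age_groups Ordered age labels, youngest first.
#' @param exposures Exposure labels; must include `"vehicle"` first.
#' @param frac_age_up,frac_age_down Fractions of genes planted to go up /
#'   down with age (the aging-plasticity genes).
#' @param age_log2fc Absolute log2 fold change of the planted aging effect.
#' @param exposure_log2fc Absolute log2 fold change of planted exposure
#'   effects (applied at the adult age group only).
#' @param n_exposure_genes Number of genes perturbed per exposure arm.
#' @param frac_attenuated Fraction of each exposure's perturbed genes drawn
#'   from aging genes with the exposure direction opposing the aging
#'   direction.
#' @param frac_accelerated Fraction drawn from aging genes with the same
#'   direction as aging. The remainder are exposure-only genes.
#' @param nb_mean_log Mean of the log-normal baseline gene means (natural
#'   log scale).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); > 0.
#' @param n_enhancers_per_gene Mean number of catalog enhancer links per
#'   gene.
#' @param adjacency_rate Fraction of within-gene enhancer pairs placed
#'   book-ended so that anchor merging is exercised.
#' @param concordance_rate Probability that a planted histone-mark peak's
#'   direction is concordant with its gene's expression direction (given the
#'   mark's polarity).
#' @param marks Named character vector mapping simulated marks to polarity
#'   (`"active"` / `"repressive"`).
#' @param peak_log2fc Absolute log2 fold change of planted peaks.
#' @param window_size Tiling window width in bp for peak counts.
#' @param gene_spacing Genomic spacing between consecutive TSS on the single
#'   synthetic chromosome `"chrS"`.
#' @param seed Integer seed; the same config + seed gives identical output.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              samples_per_group = 6,
                              age_groups = c("wk3", "mo5"),
                              exposures = c("vehicle", "BPA.hi", "TBT", "TCDD"),
                              frac_age_up = 0.05,
                              frac_age_down = 0.15,
                              age_log2fc = 1.5,
                              exposure_log2fc = 1.5,
                              n_exposure_genes = 300,
                              frac_attenuated = 0.5,
                              frac_accelerated = 0.2,
                              nb_mean_log = 5,
                              nb_dispersion = 0.1,
                              n_enhancers_per_gene = 8,
                              adjacency_rate = 0.2,
                              concordance_rate = 0.85,
                              marks = c(H3K27ac = "active", H3K27me3 = "repressive"),
                              peak_log2fc = 2,
                              window_size = 1000,
                              gene_spacing = 20000,
                              seed = 1) {
  props <- c(frac_age_up, frac_age_down, frac_attenuated, frac_accelerated,
             adjacency_rate, concordance_rate)
  if (any(props < 0) || any(props > 1)) stop("proportions must lie in [0, 1]")
  if (frac_age_up + frac_age_down > 1) stop("frac_age_up + frac_age_down > 1")
  if (frac_attenuated + frac_accelerated > 1) {
    stop("frac_attenuated + frac_accelerated > 1")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (samples_per_group < 2) stop("samples_per_group must be >= 2")
  if (length(age_groups) < 2) stop("need >= 2 age groups")
  if (exposures[1] != "vehicle") stop("exposures must start with 'vehicle'")
  if (!all(marks %in% c("active", "repressive"))) {
    stop("marks must map to 'active' or 'repressive'")
  }
  structure(as.list(environment()), class = "sim_config")
}

sim_gene_annotation <- function(cfg) {
  idx <- seq_len(cfg$n_genes)
  tibble::tibble(
    gene_id = sprintf("g%04d", idx),
    chrom = "chrS",
    tss = as.integer((idx - 1L) * cfg$gene_spacing + 5000L),
    strand = rep_len(c("+", "-"), cfg$n_genes)
  )
}

#' Simulate an enhancer catalog with gene links
#'
#' Places catalog enhancers in each gene's genomic neighbourhood. Enhancers
#' are laid out in pairs; within a pair the second interval is book-ended to
#' the first with probability `adjacency_rate` (so anchor merging has known
#' expected behaviour), and distinct pairs never touch. Each enhancer links
#' its owner gene and, with probability 0.25, one neighbouring gene, with
#' per-gene enhancer counts drawn so the mean number of linked enhancers per
#' gene is `n_enhancers_per_gene`.
#'
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `tss`,
#'   `strand`), as from [simulate_study()].
#' @param n_enhancers_per_gene Target mean linked enhancers per gene.
#' @param adjacency_rate Probability a within-pair enhancer is book-ended.
#' @param enhancer_width Interval width in bp.
#' @param gene_spacing Spacing used to lay out the annotation.
#' @param seed Integer seed.
#' @return A list with `enhancers` (tibble `chrom`, `start`, `end`,
#'   `enhancer_id`) and `links` (tibble `enhancer_id`, `gene_id`).
#' @export
simulate_enhancer_catalog <- function(annotation,
                                      n_enhancers_per_gene = 8,
                                      adjacency_rate = 0.2,
                                      enhancer_width = 500,
                                      gene_spacing = 20000,
                                      seed = 1) {
  set.seed(seed)
  p_extra <- 0.25
  lambda <- n_enhancers_per_gene / (1 + p_extra)
  n_genes <- nrow(annotation)
  out_e <- vector("list", n_genes)
  out_l <- vector("list", n_genes)
  counter <- 0L
  for (i in seq_len(n_genes)) {
    slot_start <- annotation$tss[i] + 4000L
    slot_end <- annotation$tss[i] + gene_spacing - 6000L
    capacity <- floor((slot_end - slot_start) / (2L * enhancer_width + 200L))
    n_i <- min(stats::rpois(1, lambda), 2L * capacity)
    if (n_i == 0) next
    starts <- integer(n_i)
    pos <- slot_start
    j <- 1L
    while (j <= n_i) {
      starts[j] <- pos
      pos <- pos + enhancer_width
      if (j < n_i) {
        # second member of the pair: book-ended with prob adjacency_rate
        if (stats::runif(1) >= adjacency_rate) pos <- pos + 100L
        starts[j + 1L] <- pos
        pos <- pos + enhancer_width
      }
      pos <- pos + 200L  # gap between pairs: never merges
      j <- j + 2L
    }
    ids <- sprintf("e%06d", counter + seq_len(n_i))
    counter <- counter + n_i
    out_e[[i]] <- tibble::tibble(
      chrom = annotation$chrom[i],
      start = starts,
      end = starts + enhancer_width,
      enhancer_id = ids
    )
    extra <- stats::runif(n_i) < p_extra
    neighbor <- ifelse(i < n_genes, i + 1L, i - 1L)
    out_l[[i]] <- tibble::tibble(
      enhancer_id = c(ids, ids[extra]),
      gene_id = c(rep(annotation$gene_id[i], n_i),
                  rep(annotation$gene_id[neighbor], sum(extra)))
    )
  }
  list(enhancers = dplyr::bind_rows(out_e), links = dplyr::bind_rows(out_l))
}

#' Simulate a complete synthetic exposure-aging study
#'
#' Generates negative-binomial expression counts for every exposure-by-age
#' cell, tiled histone-mark window counts for the aging contrast with
#' planted peaks at promoters and linked enhancers, an enhancer catalog, and
#' a ground-truth record of every planted effect.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `sim_study` with elements:
#'   `counts` (genes x samples matrix), `samples` (tibble `sample_id`, `age`,
#'   `exposure`, `sex`), `annotation` (gene TSS tibble), `enhancers`,
#'   `enhancer_links`, `peak_windows` (tiling tibble), `peak_counts` (named
#'   list per mark: windows x samples matrix for the aging contrast),
#'   `peak_samples` (tibble `sample_id`, `age`), `truth` (list: `aging`,
#'   `exposure`, `peaks` tibbles), and `config`.
#' @export
simulate_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  annotation <- sim_gene_annotation(cfg)
  genes <- annotation$gene_id
  n <- cfg$n_genes

  # planted aging directions; a zero effect size means nothing is planted
  n_up <- if (cfg$age_log2fc == 0) 0L else round(cfg$frac_age_up * n)
  n_down <- if (cfg$age_log2fc == 0) 0L else round(cfg$frac_age_down * n)
  aging_dir <- rep("none", n)
  pick <- sample.int(n, n_up + n_down)
  aging_dir[pick[seq_len(n_up)]] <- "up"
  if (n_down > 0) aging_dir[pick[n_up + seq_len(n_down)]] <- "down"
  names(aging_dir) <- genes

  # planted exposure effects per arm
  arms <- setdiff(cfg$exposures, "vehicle")
  n_expo <- if (cfg$exposure_log2fc == 0) 0L else cfg$n_exposure_genes
  n_att <- round(cfg$frac_attenuated * n_expo)
  n_acc <- round(cfg$frac_accelerated * n_expo)
  n_only <- n_expo - n_att - n_acc
  laasp_genes <- genes[aging_dir != "none"]
  null_genes <- genes[aging_dir == "none"]
  truth_exposure <- purrr::map_dfr(arms, function(arm) {
    att <- sample(laasp_genes, min(n_att, length(laasp_genes)))
    acc <- sample(setdiff(laasp_genes, att),
                  min(n_acc, length(laasp_genes) - length(att)))
    only <- sample(null_genes, min(n_only, length(null_genes)))
    tibble::tibble(
      exposure = arm,
      gene_id = c(att, acc, only),
      class = c(rep("attenuated", length(att)), rep("accelerated", length(acc)),
                rep("exposure_only", length(only))),
      exposure_direction = c(
        ifelse(aging_dir[att] == "up", "down", "up"),
        aging_dir[acc],
        sample(c("up", "down"), length(only), replace = TRUE)
      )
    )
  })

  # expression counts
  base_log_mu <- stats::rnorm(n, cfg$nb_mean_log, 1)
  adult_ages <- cfg$age_groups[-1]
  design <- tidyr::expand_grid(
    exposure = cfg$exposures, age = cfg$age_groups,
    rep = seq_len(cfg$samples_per_group)
  ) |>
    dplyr::filter(.data$exposure == "vehicle" | .data$age %in% adult_ages) |>
    dplyr::mutate(
      sample_id = paste(.data$exposure, .data$age, paste0("r", .data$rep), sep = "_"),
      sex = "male"
    )
  dir_sign <- c(up = 1, down = -1, none = 0)
  age_shift <- dir_sign[aging_dir] * cfg$age_log2fc
  expo_shift <- matrix(0, nrow = n, ncol = length(cfg$exposures),
                       dimnames = list(genes, cfg$exposures))
  for (arm in arms) {
    te <- truth_exposure[truth_exposure$exposure == arm, ]
    expo_shift[te$gene_id, arm] <- dir_sign[te$exposure_direction] * cfg$exposure_log2fc
  }
  lib_factor <- stats::rlnorm(nrow(design), 0, 0.2)
  size <- 1 / cfg$nb_dispersion
  counts <- matrix(0, nrow = n, ncol = nrow(design),
                   dimnames = list(genes, design$sample_id))
  for (s in seq_len(nrow(design))) {
    lmu <- base_log_mu
    if (design$age[s] != cfg$age_groups[1]) lmu <- lmu + age_shift * log(2)
    if (design$age[s] %in% adult_ages) {
      lmu <- lmu + expo_shift[, design$exposure[s]] * log(2)
    }
    counts[, s] <- stats::rnbinom(n, mu = exp(lmu) * lib_factor[s], size = size)
  }

  catalog <- simulate_enhancer_catalog(
    annotation,
    n_enhancers_per_gene = cfg$n_enhancers_per_gene,
    adjacency_rate = cfg$adjacency_rate,
    gene_spacing = cfg$gene_spacing,
    seed = cfg$seed + 1L
  )

  peaks <- sim_peak_tracks(cfg, annotation, aging_dir, catalog)

  structure(list(
    counts = counts,
    samples = design[, c("sample_id", "age", "exposure", "sex")],
    annotation = annotation,
    enhancers = catalog$enhancers,
    enhancer_links = catalog$links,
    peak_windows = peaks$windows,
    peak_counts = peaks$counts,
    peak_samples = peaks$samples,
    truth = list(
      aging = tibble::tibble(gene_id = genes, aging_direction = unname(aging_dir)),
      exposure = truth_exposure,
      peaks = peaks$truth
    ),
    config = cfg
  ), class = "sim_study")
}

# tiled window counts for the aging contrast, with planted peaks at
# promoters / linked enhancers of aging genes
sim_peak_tracks <- function(cfg, annotation, aging_dir, catalog) {
  set.seed(cfg$seed + 2L)
  ws <- cfg$window_size
  chrom_len <- cfg$n_genes * cfg$gene_spacing
  starts <- seq(0L, chrom_len - ws, by = ws)
  windows <- tibble::tibble(chrom = "chrS", start = as.integer(starts),
                            end = as.integer(starts + ws))
  nw <- nrow(windows)
  groups <- c(rep(cfg$age_groups[1], cfg$samples_per_group),
              rep(cfg$age_groups[2], cfg$samples_per_group))
  sample_ids <- paste0("chip_", groups, "_r",
                       rep(seq_len(cfg$samples_per_group), 2))
  lib_factor <- stats::rlnorm(length(sample_ids), 0, 0.2)
  lambda0 <- 20
  dir_sign <- c(up = 1, down = -1)
  aging_genes <- annotation[aging_dir[annotation$gene_id] != "none", ]
  links_by_gene <- split(catalog$links$enhancer_id, catalog$links$gene_id)

  truth_list <- vector("list", 0L)
  peak_counts <- list()
  for (mark in names(cfg$marks)) {
    polarity <- cfg$marks[[mark]]
    # per-window log2 shift in the older group
    shift <- numeric(nw)
    truth_rows <- vector("list", nrow(aging_genes))
    for (i in seq_len(nrow(aging_genes))) {
      g <- aging_genes$gene_id[i]
      expr_dir <- aging_dir[g]
      concord <- stats::runif(1) < cfg$concordance_rate
      peak_dir <- if (polarity == "active") expr_dir else
        ifelse(expr_dir == "up", "down", "up")
      if (!concord) peak_dir <- ifelse(peak_dir == "up", "down", "up")
      # site: promoter (prob 0.5) or a random linked enhancer
      own_enh <- links_by_gene[[g]]
      use_prom <- length(own_enh) == 0 || stats::runif(1) < 0.5
      if (use_prom) {
        site <- aging_genes$tss[i] - ws
        region <- "promoter"
      } else {
        e <- sample(own_enh, 1)
        site <- catalog$enhancers$start[match(e, catalog$enhancers$enhancer_id)]
        region <- "enhancer"
      }
      w0 <- max(0L, floor(site / ws))
      idx <- w0 + seq_len(3L)
      idx <- idx[idx >= 1 & idx <= nw]
      shift[idx] <- dir_sign[[peak_dir]] * cfg$peak_log2fc
      truth_rows[[i]] <- tibble::tibble(
        gene_id = g, mark = mark, region_class = region,
        chrom = "chrS", start = windows$start[idx[1]],
        end = windows$end[idx[length(idx)]],
        peak_direction = peak_dir, expression_direction = expr_dir,
        concordant = concord
      )
    }
    m <- matrix(0, nrow = nw, ncol = length(sample_ids),
                dimnames = list(NULL, sample_ids))
    for (s in seq_along(sample_ids)) {
      lam <- lambda0 * lib_factor[s]
      if (groups[s] == cfg$age_groups[2]) {
        lam <- lam * 2^shift
      } else {
        lam <- rep(lam, nw)
      }
      m[, s] <- stats::rpois(nw, lam)
    }
    peak_counts[[mark]] <- m
    truth_list[[mark]] <- dplyr::bind_rows(truth_rows)
  }
  list(
    windows = windows,
    counts = peak_counts,
    samples = tibble::tibble(sample_id = sample_ids, age = groups),
    truth = dplyr::bind_rows(truth_list)
  )
}

#' Simulate a human-like cohort with ordinal disease severity
#'
#' Expression of the signature's up genes increases, and of its down genes
#' decreases, linearly with the ordinal severity index, scaled by `effect`,
#' on a unit-variance noise background; background genes are pure noise.
#' Severity labels are assigned in balanced blocks.
#'
#' @param signature A [gene_signature()].
#' @param n_samples Number of cohort samples.
#' @param severity_levels Ordered severity labels (>= 2), least severe first.
#' @param effect Linear effect size per severity step (0 = null cohort).
#' @param n_background Extra noise genes appended to the matrix.
#' @param seed Integer seed.
#' @return A list of class `sim_cohort` with `expression` (genes x samples
#'   matrix), `samples` (tibble `sample_id`, `state`), and
#'   `severity_levels`.
#' @export
simulate_cohort <- function(signature, n_samples = 200,
                            severity_levels = c("normal", "steatosis", "NASH", "HCC"),
                            effect = 1, n_background = 200, seed = 1) {
  stopifnot(inherits(signature, "gene_signature"))
  if (length(signature) == 0) stop("signature is empty")
  if (length(severity_levels) < 2) stop("need >= 2 severity levels")
  set.seed(seed)
  k <- length(severity_levels)
  state_idx <- rep(seq_len(k), length.out = n_samples)
  state_idx <- sort(state_idx)  # balanced blocks, least severe first
  sev <- state_idx - 1L
  genes <- c(signature$up, signature$down,
             sprintf("bg%04d", seq_len(n_background)))
  dir <- c(rep(1, length(signature$up)), rep(-1, length(signature$down)),
           rep(0, n_background))
  signal <- outer(dir, sev) * effect
  noise <- matrix(stats::rnorm(length(genes) * n_samples),
                  nrow = length(genes))
  expr <- signal + noise
  dimnames(expr) <- list(genes, sprintf("s%04d", seq_len(n_samples)))
  structure(list(
    expression = expr,
    samples = tibble::tibble(sample_id = colnames(expr),
                             state = severity_levels[state_idx]),
    severity_levels = severity_levels
  ), class = "sim_cohort")
}

#' Write a simulated study to disk as plain-text files
#'
#' Emits the same TSV/BED formats the package readers consume, plus a
#' `truth_*.tsv` sidecar per ground-truth table, so the pipeline can be run
#' end-to-end from files.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(study$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(study$samples, file.path(dir, "samples.tsv"), progress = FALSE)
  readr::write_tsv(study$annotation, file.path(dir, "annotation.tsv"), progress = FALSE)
  write_bed(dplyr::mutate(study$enhancers, name = .data$enhancer_id),
            file.path(dir, "enhancers.bed"))
  readr::write_tsv(study$enhancer_links, file.path(dir, "enhancer_links.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$peak_windows, file.path(dir, "peak_windows.tsv"),
                   progress = FALSE)
  for (mark in names(study$peak_counts)) {
    write_counts(study$peak_counts[[mark]] |>
                   `rownames<-`(paste0("w", seq_len(nrow(study$peak_windows)))),
                 file.path(dir, paste0("peak_counts_", mark, ".tsv")),
                 id_col = "window_id")
  }
  readr::write_tsv(study$peak_samples, file.path(dir, "peak_samples.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$truth$aging, file.path(dir, "truth_aging.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$truth$exposure, file.path(dir, "truth_exposure.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$truth$peaks, file.path(dir, "truth_peaks.tsv"),
                   progress = FALSE)
  invisible(dir)
}
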