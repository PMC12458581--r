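#' Significance thresholds for differential calls
#'
#' The default rule for both differential genes and differential peaks:
#' BH-adjusted FDR below 0.05 and a linear fold change exceeding 1.5x.
#'
#' @param alpha FDR cutoff (0 < alpha < 1).
#' @param min_fc Minimum linear fold change (> 1); a feature is `up` when
#'   `fold_change_linear > min_fc`, `down` when `< 1/min_fc`.
#' @return A list of class `laasp_thresholds`.
#' @export
thresholds <- function(alpha = 0.05, min_fc = 1.5) {
  stopifnot(alpha > 0, alpha < 1, min_fc > 1)
  structure(list(alpha = alpha, min_fc = min_fc), class = "laasp_thresholds")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotone enforcement, preserving input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must be in [0, 1] and non-missing")
  }
  stats::p.adjust(p_values, method = "BH")
}

direction_call <- function(fold_change_linear, q_value, thr) {
  dplyr::case_when(
    q_value < thr$alpha & fold_change_linear > thr$min_fc ~ "up",
    q_value < thr$alpha & fold_change_linear < 1 / thr$min_fc ~ "down",
    TRUE ~ "ns"
  )
}

#' Call differentially expressed genes
#'
#' A lightweight declared substitute for a full count-model fit: counts are
#' CPM-normalized, `log2(CPM + 0.5)` values are compared between the two
#' groups with a Welch (unequal-variance) two-sample t-test, and p-values are
#' BH-adjusted. The fold change is the ratio of group mean CPMs with a 0.5
#' pseudo-count, so it is finite and exactly inverts under a group swap.
#'
#' @param counts Genes-by-samples numeric matrix of raw counts, with
#'   rownames (gene IDs) and colnames (sample IDs).
#' @param group_a,group_b Character vectors of sample IDs (disjoint, each of
#'   size >= 2). Fold changes are reported as b over a.
#' @param thr A [thresholds()] object.
#' @return Tibble with columns `feature_id`, `log2fc`, `fold_change_linear`,
#'   `p_value`, `q_value`, `direction`.
#' @export
call_degs <- function(counts, group_a, group_b, thr = thresholds()) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  stopifnot(length(group_a) >= 2, length(group_b) >= 2,
            length(intersect(group_a, group_b)) == 0)
  miss <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(miss) > 0) stop("unknown sample(s): ", paste(miss, collapse = ", "))

  lib <- colSums(counts)
  lib[lib == 0] <- 1
  cpm <- sweep(counts, 2, lib / 1e6, "/")
  a <- cpm[, group_a, drop = FALSE]
  b <- cpm[, group_b, drop = FALSE]
  la <- log2(a + 0.5)
  lb <- log2(b + 0.5)

  p <- vapply(seq_len(nrow(cpm)), function(i) {
    xa <- la[i, ]
    xb <- lb[i, ]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      return(if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0)
    }
    stats::t.test(xb, xa)$p.value
  }, numeric(1))

  mean_a <- rowMeans(a) + 0.5
  mean_b <- rowMeans(b) + 0.5
  fc <- mean_b / mean_a
  q <- bh_fdr(p)
  tibble::tibble(
    feature_id = rownames(counts),
    log2fc = log2(fc),
    fold_change_linear = fc,
    p_value = p,
    q_value = q,
    direction = direction_call(fc, q, thr)
  )
}

#' Call differential peaks from tiled window counts
#'
#' A declared substitute for a window-based differential ChIP caller: per
#' window, pooled counts of the two groups are compared with a
#' library-size-normalized G-test (likelihood-ratio test against expected
#' sharing proportional to total library size), p-values are BH-adjusted
#' across tested windows, and significant adjacent windows with the same
#' direction are merged into one peak interval carrying the extreme log2
#' fold change and the smallest q-value of its windows. Windows with zero
#' counts in both groups are skipped.
#'
#' @param windows Tibble with columns `chrom`, `start`, `end` describing
#'   non-overlapping tiling windows (0-based half-open), ordered by position.
#' @param counts Windows-by-samples numeric matrix of window counts, with
#'   colnames (sample IDs); rows parallel `windows`.
#' @param group_a,group_b Character vectors of sample IDs.
#' @param thr A [thresholds()] object.
#' @param lib_sizes Optional named numeric vector of library sizes; defaults
#'   to column sums of `counts`.
#' @return Tibble of merged differential-peak intervals with columns `chrom`,
#'   `start`, `end`, `feature_id`, `log2fc`, `fold_change_linear`, `p_value`,
#'   `q_value`, `direction` (`"up"`/`"down"` only), `n_windows`.
#' @export
call_deps <- function(windows, counts, group_a, group_b, thr = thresholds(),
                      lib_sizes = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) == nrow(windows),
            all(c("chrom", "start", "end") %in% names(windows)))
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  na <- sum(lib_sizes[group_a])
  nb <- sum(lib_sizes[group_b])
  a <- rowSums(counts[, group_a, drop = FALSE])
  b <- rowSums(counts[, group_b, drop = FALSE])

  tested <- (a + b) > 0
  tot <- a + b
  ea <- tot * na / (na + nb)
  eb <- tot * nb / (na + nb)
  gterm <- function(obs, exp) ifelse(obs > 0, obs * log(obs / exp), 0)
  g <- 2 * (gterm(a, ea) + gterm(b, eb))
  p <- rep(NA_real_, length(a))
  p[tested] <- stats::pchisq(g[tested], df = 1, lower.tail = FALSE)
  q <- rep(NA_real_, length(a))
  q[tested] <- bh_fdr(p[tested])
  fc <- ((b + 0.5) / nb) / ((a + 0.5) / na)
  dir <- rep("ns", length(a))
  dir[tested] <- direction_call(fc[tested], q[tested], thr)

  sig <- which(dir %in% c("up", "down"))
  if (length(sig) == 0) return(empty_dep_table())

  w <- windows[sig, , drop = FALSE]
  # merge runs of strictly adjacent (book-ended) same-chrom same-direction windows
  new_run <- c(TRUE,
               w$chrom[-1] != w$chrom[-nrow(w)] |
                 w$start[-1] != w$end[-nrow(w)] |
                 dir[sig][-1] != dir[sig][-length(sig)])
  run_id <- cumsum(new_run)
  lf <- log2(fc[sig])
  tibble::tibble(
    chrom = w$chrom, start = w$start, end = w$end,
    log2fc = lf, p_value = p[sig], q_value = q[sig],
    direction = dir[sig], run = run_id
  ) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      log2fc = .data$log2fc[which.max(abs(.data$log2fc))],
      p_value = min(.data$p_value),
      q_value = min(.data$q_value),
      direction = dplyr::first(.data$direction),
      n_windows = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      feature_id = paste0(.data$chrom, ":", .data$start, "-", .data$end),
      fold_change_linear = 2^.data$log2fc
    ) |>
    dplyr::select("chrom", "start", "end", "feature_id", "log2fc",
                  "fold_change_linear", "p_value", "q_value", "direction",
                  "n_windows")
}

empty_dep_table <- function() {
  tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    feature_id = character(), log2fc = numeric(),
    fold_change_linear = numeric(), p_value = numeric(), q_value = numeric(),
    direction = character(), n_windows = integer()
  )
}

#' Jensen-Shannon distance between two binned coverage histograms
#'
#' The square root of the Jensen-Shannon divergence with base-2 logarithms,
#' so the result lies in \[0, 1\]; used as a ChIP signal-quality distance
#' from an ideal input profile.
#'
#' @param h1,h2 Non-negative numeric vectors of equal length, each summing to
#'   1 (within 1e-9).
#' @return The Jensen-Shannon distance, a number in \[0, 1\].
#' @export
jsd_qc <- function(h1, h2) {
  stopifnot(length(h1) == length(h2))
  if (any(h1 < 0) || any(h2 < 0)) stop("histogram bins must be non-negative")
  if (abs(sum(h1) - 1) > 1e-9 || abs(sum(h2) - 1) > 1e-9) {
    stop("histograms must each sum to 1")
  }
  m <- (h1 + h2) / 2
  kl <- function(p, q) {
    i <- p > 0
    sum(p[i] * log2(p[i] / q[i]))
  }
  jsd <- kl(h1, m) / 2 + kl(h2, m) / 2
  sqrt(max(jsd, 0))
}
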