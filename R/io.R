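#' Read a BED file of genomic intervals
#'
#' Parses BED3-BED6 into a tibble of 0-based half-open intervals. Columns
#' beyond the first three (name, score, strand) are filled with defaults
#' (`"."`, `0`, `"."`) when absent. Lines starting with `#`, and `track` /
#' `browser` lines, are skipped.
#'
#' @param path Path to a tab-separated BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`. Coordinates are 0-based half-open (`start` inclusive, `end`
#'   exclusive).
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fld <- lengths(fields)
  if (any(n_fld < 3L)) {
    bad <- line_no[which(n_fld < 3L)[1]]
    stop("BED parse error at line ", bad, ": fewer than 3 tab-separated columns")
  }
  get_col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start_chr <- get_col(2L, NA_character_)
  end_chr <- get_col(3L, NA_character_)
  start <- suppressWarnings(as.numeric(start_chr))
  end <- suppressWarnings(as.numeric(end_chr))
  bad_num <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad_num)) {
    stop("BED parse error at line ", line_no[which(bad_num)[1]],
         ": non-integer coordinates")
  }
  bad_iv <- start < 0 | end <= start
  if (any(bad_iv)) {
    stop("BED parse error at line ", line_no[which(bad_iv)[1]],
         ": invalid interval (need 0 <= start < end)")
  }
  score <- suppressWarnings(as.numeric(get_col(5L, "0")))
  score[is.na(score)] <- 0
  strand <- get_col(6L, ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  tibble::tibble(
    chrom = get_col(1L, NA_character_),
    start = as.integer(start),
    end = as.integer(end),
    name = get_col(4L, "."),
    score = score,
    strand = strand
  )
}

empty_intervals <- function() {
  tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = numeric(), strand = character()
  )
}

#' Write intervals as BED6
#'
#' Inverse of [read_bed()]: `read_bed(write_bed(x, f))` reproduces `x`
#' field-for-field.
#'
#' @param intervals Tibble with columns `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand` default to `"."`, `0`, `"."`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  x <- tibble::as_tibble(intervals)
  if (!"name" %in% names(x)) x$name <- "."
  if (!"score" %in% names(x)) x$score <- 0
  if (!"strand" %in% names(x)) x$strand <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                   x$chrom, as.integer(x$start), as.integer(x$end),
                   x$name, x$score, x$strand)
  readr::write_lines(lines, path)
  invisible(path)
}

validate_intervals <- function(intervals) {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(intervals))
  if (length(miss) > 0) {
    stop("interval table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(intervals) == 0) return(invisible(TRUE))
  if (any(intervals$start < 0)) stop("interval start < 0")
  if (any(intervals$end <= intervals$start)) stop("interval with end <= start")
  if (any(!nzchar(intervals$chrom))) stop("empty chrom name")
  invisible(TRUE)
}

#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes
#' within a set are collapsed; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (unique gene IDs per set).
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fld <- lengths(fields)
  if (any(n_fld < 3L)) {
    stop("GMT parse error at line ", which(n_fld < 3L)[1],
         ": fewer than 3 fields (name, description, >=1 gene)")
  }
  nms <- vapply(fields, `[`, character(1), 1L)
  dup <- duplicated(nms)
  if (any(dup)) stop("duplicate gene-set name in GMT: ", nms[which(dup)[1]])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  sets
}

#' Write a named list of gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)), !anyDuplicated(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a header-ed TSV with schema validation
#'
#' Comment lines (starting `#`) are skipped. Missing required columns raise an
#' error naming the column.
#'
#' @param path Path to a TSV file with a header row.
#' @param required Character vector of column names that must be present.
#' @return A tibble.
#' @export
read_table_tsv <- function(path, required = character()) {
  stopifnot(file.exists(path))
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  miss <- setdiff(required, names(tb))
  if (length(miss) > 0) {
    stop("table ", path, " missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  tb
}

#' Read a genes-by-samples count matrix from TSV
#'
#' First column is the gene ID; remaining columns are samples.
#'
#' @param path Path to a TSV file (header = sample IDs).
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  tb <- read_table_tsv(path)
  m <- as.matrix(tb[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tb[[1]])
  m
}

#' Write a genes-by-samples matrix as TSV
#'
#' @param mat Numeric matrix with rownames (gene IDs).
#' @param path Output file path.
#' @param id_col Name for the gene-ID column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(mat, path, id_col = "gene_id") {
  tb <- tibble::as_tibble(mat, rownames = id_col)
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}
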