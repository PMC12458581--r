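#' Construct a gene signature
#'
#' A gene signature is a named pair of disjoint gene sets: genes that go up
#' and genes that go down in a contrast (an aging interval, an exposure vs
#' vehicle comparison, a disease endotype).
#'
#' @param name Signature name.
#' @param up Character vector of up-regulated gene IDs.
#' @param down Character vector of down-regulated gene IDs.
#' @return An object of class `gene_signature`: a list with elements `name`,
#'   `up`, `down`.
#' @export
gene_signature <- function(name, up = character(), down = character()) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  common <- intersect(up, down)
  if (length(common) > 0) {
    stop("gene_signature '", name, "': up and down sets overlap (",
         paste(utils::head(common, 3), collapse = ", "), ")")
  }
  structure(list(name = name, up = up, down = down),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature> ", x$name, ": ", length(x$up), " up, ",
      length(x$down), " down\n", sep = "")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$up) + length(x$down)

#' All genes in a signature
#' @param signature A [gene_signature()].
#' @return Character vector of gene IDs (up then down).
#' @export
signature_genes <- function(signature) {
  c(signature$up, signature$down)
}

#' Per-gene direction table of a signature
#' @param signature A [gene_signature()].
#' @return Tibble with columns `gene_id`, `direction` (`"up"`/`"down"`),
#'   `source` (the signature name).
#' @export
signature_table <- function(signature) {
  tibble::tibble(
    gene_id = c(signature$up, signature$down),
    direction = c(rep("up", length(signature$up)),
                  rep("down", length(signature$down))),
    source = signature$name
  )
}

#' Derive a signature from a differential table
#'
#' Takes the `direction` calls of a differential table (see [call_degs()])
#' and splits them into an up set and a down set; `ns` genes are excluded.
#'
#' @param diff_table Tibble with columns `feature_id` and `direction`.
#' @param name Name for the resulting signature.
#' @return A [gene_signature()].
#' @export
derive_signature <- function(diff_table, name) {
  stopifnot(all(c("feature_id", "direction") %in% names(diff_table)))
  up <- diff_table$feature_id[diff_table$direction == "up"]
  down <- diff_table$feature_id[diff_table$direction == "down"]
  if (length(up) + length(down) == 0) {
    warning("derive_signature('", name, "'): no differential genes; ",
            "signature is empty")
  }
  gene_signature(name, up = up, down = down)
}

#' Flip a signature's direction
#' @param signature A [gene_signature()].
#' @return The signature with up and down sets swapped.
#' @export
flip_signature <- function(signature) {
  gene_signature(paste0(signature$name, ".flipped"),
                 up = signature$down, down = signature$up)
}
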