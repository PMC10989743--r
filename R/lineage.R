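#' Taxonomic lineages
#'
#' A lineage is an ordered vector of taxon names over the fixed rank order
#' domain, phylum, class, order, family, genus, species. Truncation from
#' the right is allowed (a genus-level lineage has six entries); gaps are
#' not. Reference FASTA descriptions carry lineages in the semicolon
#' rank-prefixed form `d__...;p__...;c__...;o__...;f__...;g__...;s__...`.
#'
#' @name lineage
NULL

LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family",
                   "genus", "species")
LINEAGE_PREFIXES <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Parse a semicolon rank-prefixed lineage string
#'
#' @param x A string like `"d__Bacteria;p__Firmicutes;...;s__..."`; rank
#'   prefixes are required and must appear in the fixed order with no gaps.
#' @return A named character vector (names are rank names), class
#'   `lineage`.
#' @export
parse_lineage <- function(x) {
  if (is.na(x) || !nzchar(x)) return(structure(character(), class = "lineage"))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  prefixes <- substr(parts, 1, 3)
  expected <- LINEAGE_PREFIXES[seq_along(parts)]
  if (length(parts) > length(LINEAGE_RANKS) || any(prefixes != expected))
    stop("malformed lineage string: ", x)
  structure(setNames(substring(parts, 4), LINEAGE_RANKS[seq_along(parts)]),
            class = "lineage")
}

#' Format a lineage back to its semicolon rank-prefixed form
#' @param x A `lineage`.
#' @param ... Unused.
#' @return A single string (empty string for an empty lineage).
#' @export
format.lineage <- function(x, ...) {
  if (length(x) == 0L) return("")
  paste0(LINEAGE_PREFIXES[seq_along(x)], unname(x), collapse = ";")
}

#' @export
print.lineage <- function(x, ...) {
  cat(if (length(x)) format(x) else "<unclassified>", "\n")
  invisible(x)
}

#' Lowest common ancestor of several lineages
#'
#' Truncates to the longest rank prefix on which all lineages agree; used
#' when tied best hits disagree below some rank.
#'
#' @param lineages A list of `lineage` vectors.
#' @return The common-prefix `lineage` (possibly empty).
#' @export
lineage_lca <- function(lineages) {
  if (length(lineages) == 0L) return(structure(character(), class = "lineage"))
  depth <- min(vapply(lineages, length, 1L))
  keep <- 0L
  for (i in seq_len(depth)) {
    vals <- vapply(lineages, function(l) unname(l[[i]]), "")
    if (length(unique(vals)) == 1L) keep <- i else break
  }
  structure(lineages[[1]][seq_len(keep)], class = "lineage")
}
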