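#' Alignment-free SNP discovery and phylogeny
#'
#' SNPs are discovered without alignment or a reference genome by
#' grouping canonical k-mers on their flanking context: k-mers identical
#' except at the central base expose one SNP locus. An optional reference
#' mode anchors loci to unique reference positions. Downstream, loci
#' become a SNP matrix, p-distances, and a neighbor-joining tree.
#'
#' @name snp_tracking
NULL

# Canonical (context, allele) pairs of all k-mers of one sequence, with
# 1-based central-base positions on the forward strand. K-mers containing
# non-ACGT characters are skipped.
.kmer_contexts <- function(seq, k) {
  L <- nchar(seq)
  h <- (k - 1L) %/% 2L
  if (L < k)
    return(data.table::data.table(context = character(),
                                  allele = character(), pos = integer()))
  pos <- seq_len(L - k + 1L)
  kf <- substring(seq, pos, pos + k - 1L)
  rcs <- reverse_complement(seq)
  rstart <- L - pos - k + 2L
  kr <- substring(rcs, rstart, rstart + k - 1L)
  canon <- ifelse(kf <= kr, kf, kr)
  ok <- !grepl("[^ACGT]", canon)
  canon <- canon[ok]
  dt <- data.table::data.table(
    context = paste0(substr(canon, 1L, h), ".",
                     substr(canon, h + 2L, k)),
    allele = substr(canon, h + 1L, h + 1L),
    pos = pos[ok] + h)
  dt
}

.genome_string <- function(g) {
  if (inherits(g, "seq_record")) return(g$sequence)
  if (is.character(g) && length(g) == 1L && file.exists(g))
    return(paste(vapply(read_fasta(g), `[[`, "", "sequence"), collapse = ""))
  if (is.character(g)) return(toupper(g))
  if (is.list(g)) return(paste(vapply(g, `[[`, "", "sequence"),
                               collapse = ""))
  stop("cannot interpret genome input")
}

#' Discover SNP loci from k-mer contexts across genomes
#'
#' Every k-mer of every genome is put in canonical orientation (the
#' lexicographically smaller of the k-mer and its reverse complement, so
#' discovery is strand-independent); k-mers sharing their flanking
#' context but differing at the central base expose a SNP locus. A
#' context yields a locus only if at least two distinct central alleles
#' exist across genomes; a genome presenting two different alleles for
#' one context (a repeat) is dropped from that locus, and loci left with
#' fewer than two alleles are discarded.
#'
#' @param genomes Named list of genomes ([seq_record]s, contig lists,
#'   plain sequences, or FASTA paths); at least 2, unique names.
#' @param k Odd k-mer size in `[9, 31]` (default 19).
#' @return An object of class `snp_loci`: a list with `contexts` (sorted
#'   character vector), `alleles` (character matrix loci x genomes, `NA`
#'   where a genome lacks the context), `ref_position` (integer vector,
#'   `NA` until [map_to_reference]), and `k`.
#' @export
discover_snps <- function(genomes, k = 19L) {
  if (k %% 2L == 0L) stop("k must be odd")
  if (k < 9L || k > 31L) stop("k must lie in [9, 31]")
  ids <- names(genomes)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("genomes must have unique non-empty names")
  if (length(genomes) < 2L) stop("need at least 2 genomes")
  per_genome <- lapply(ids, function(id) {
    dt <- .kmer_contexts(.genome_string(genomes[[id]]), k)
    dt <- unique(dt[, c("context", "allele")])
    # a genome showing two alleles at one context is dropped locus-wise
    n_all <- NULL; context <- NULL   # NSE notes
    conflicts <- dt[, list(n_all = length(unique(allele))),
                    by = "context"][n_all > 1L, context]
    dt <- dt[!dt$context %in% conflicts, ]
    dt$genome <- id
    dt
  })
  all_dt <- data.table::rbindlist(per_genome)
  if (nrow(all_dt) == 0L)
    return(structure(list(contexts = character(),
                          alleles = matrix(character(), 0L, length(ids),
                                           dimnames = list(NULL, ids)),
                          ref_position = integer(), k = k),
                     class = "snp_loci"))
  counts <- all_dt[, list(n_all = length(unique(allele))), by = "context"]
  keep <- counts$context[counts$n_all >= 2L]
  all_dt <- all_dt[all_dt$context %in% keep, ]
  contexts <- sort(unique(all_dt$context))
  alleles <- matrix(NA_character_, length(contexts), length(ids),
                    dimnames = list(contexts, ids))
  alleles[cbind(match(all_dt$context, contexts),
                match(all_dt$genome, ids))] <- all_dt$allele
  structure(list(contexts = contexts, alleles = unname(alleles),
                 genome_ids = ids,
                 ref_position = rep(NA_integer_, length(contexts)), k = k),
            class = "snp_loci")
}

#' @export
print.snp_loci <- function(x, ...) {
  cat(sprintf("snp_loci: %d loci x %d genomes (k = %d)%s\n",
              length(x$contexts), length(x$genome_ids), x$k,
              if (any(!is.na(x$ref_position))) ", reference-anchored" else ""))
  invisible(x)
}

#' Anchor SNP loci to a reference genome
#'
#' A locus is retained only when its context occurs exactly once in the
#' reference (counting both strands via canonical orientation);
#' `ref_position` becomes the 1-based forward-strand coordinate of the
#' central base, and the reference allele is recorded as genome `"REF"`.
#'
#' @param loci An `snp_loci` object.
#' @param reference A single reference genome ([seq_record], plain
#'   sequence, or FASTA path).
#' @return The filtered, position-annotated `snp_loci` with an added
#'   `"REF"` genome column.
#' @export
map_to_reference <- function(loci, reference) {
  ref <- .genome_string(reference)
  dt <- .kmer_contexts(ref, loci$k)
  occ <- dt[, list(n = .N, pos = pos[1L], allele = allele[1L]),
            by = "context"]
  occ <- occ[occ$n == 1L, ]
  hit <- match(loci$contexts, occ$context)
  keep <- !is.na(hit)
  alleles <- cbind(loci$alleles[keep, , drop = FALSE],
                   occ$allele[hit[keep]])
  structure(list(contexts = loci$contexts[keep], alleles = alleles,
                 genome_ids = c(loci$genome_ids, "REF"),
                 ref_position = occ$pos[hit[keep]], k = loci$k),
            class = "snp_loci")
}

#' Build a SNP call matrix
#'
#' Loci are ordered lexicographically by context; a genome without the
#' context gets `'-'`. `core_only` keeps loci called in every genome.
#' Columns that lose allelic variation under the chosen genome subset are
#' dropped.
#'
#' @param loci An `snp_loci` object.
#' @param genome_ids Genomes to include (default: all in `loci`).
#' @param core_only Keep only gap-free loci (default `FALSE`).
#' @return An object of class `snp_matrix`: list with `genome_ids`,
#'   `contexts`, `ref_position`, and `calls` (named character vector of
#'   call strings over `{A,C,G,T,-}`, one per genome, one character per
#'   locus).
#' @export
build_snp_matrix <- function(loci, genome_ids = loci$genome_ids,
                             core_only = FALSE) {
  sel <- match(genome_ids, loci$genome_ids)
  if (anyNA(sel)) stop("unknown genome id(s)")
  ord <- order(loci$contexts)
  mat <- loci$alleles[ord, sel, drop = FALSE]
  contexts <- loci$contexts[ord]
  refpos <- loci$ref_position[ord]
  mat[is.na(mat)] <- "-"
  n_distinct <- apply(mat, 1L, function(r) length(unique(r[r != "-"])))
  keep <- n_distinct >= 2L
  if (core_only) keep <- keep & apply(mat, 1L, function(r) all(r != "-"))
  mat <- mat[keep, , drop = FALSE]
  structure(list(genome_ids = genome_ids, contexts = contexts[keep],
                 ref_position = refpos[keep],
                 calls = setNames(apply(mat, 2L, paste, collapse = ""),
                                  genome_ids)),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d genomes x %d loci\n",
              length(x$genome_ids), length(x$contexts)))
  invisible(x)
}

#' Pairwise p-distances from a SNP matrix
#'
#' `d(i, j)` is the fraction of loci, among those called (non-gap) in
#' both genomes, where the alleles differ; 0 with a `"no_overlap"` flag
#' when the pair shares no called locus.
#'
#' @param matrix An `snp_matrix`.
#' @return A symmetric numeric matrix with zero diagonal and genome ids
#'   as dimnames; attribute `no_overlap` lists flagged pairs.
#' @export
pairwise_distances <- function(matrix) {
  ids <- matrix$genome_ids
  n <- length(ids)
  if (n < 2L) stop("need at least 2 genomes")
  chars <- do.call(rbind, lapply(matrix$calls, function(s)
    strsplit(s, "")[[1]]))
  if (is.null(dim(chars)))
    chars <- base::matrix(chars, nrow = n)
  d <- base::matrix(0, n, n, dimnames = list(ids, ids))
  flagged <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- chars[i, ] != "-" & chars[j, ] != "-"
      nb <- sum(both)
      if (nb == 0L) {
        flagged <- c(flagged, paste(ids[i], ids[j], sep = ":"))
        dij <- 0
      } else {
        dij <- sum(chars[i, both] != chars[j, both]) / nb
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  attr(d, "no_overlap") <- flagged
  d
}

# Clamp negative branch lengths to 0, moving the excess to the sister
# branch (the other edge sharing the parent node).
.clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1L]
    parent <- tree$edge[e, 1L]
    sisters <- setdiff(which(tree$edge[, 1L] == parent), e)
    excess <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sisters))
      tree$edge.length[sisters[1L]] <-
        tree$edge.length[sisters[1L]] + excess
  }
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (via \code{ape::nj}) with taxa presented in
#' sorted name order for deterministic tie-breaking; negative branch
#' lengths are clamped to 0 with the excess moved to the sister branch.
#' Two taxa give a single-edge tree; one taxon is an error.
#'
#' @param distances Symmetric numeric matrix with taxon dimnames (e.g.
#'   from [pairwise_distances]).
#' @return A list of class `phylo_tree` with `newick` (string with branch
#'   lengths) and `tree` (an `ape` phylo object; `NULL` for 2 taxa).
#' @export
nj_tree <- function(distances) {
  distances <- as.matrix(distances)
  ids <- rownames(distances)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    h <- distances[1L, 2L] / 2
    nwk <- sprintf("(%s:%g,%s:%g);", ids[1L], h, ids[2L], h)
    return(structure(list(newick = nwk, tree = ape::read.tree(text = nwk)),
                     class = "phylo_tree"))
  }
  ord <- order(ids)
  tree <- ape::nj(stats::as.dist(distances[ord, ord]))
  tree <- .clamp_negative_edges(tree)
  structure(list(newick = ape::write.tree(tree), tree = tree),
            class = "phylo_tree")
}

#' @export
print.phylo_tree <- function(x, ...) {
  cat(x$newick, "\n")
  invisible(x)
}

#' Write SNP matrix outputs
#'
#' Writes the call matrix as a TSV (context, reference position, one
#' column per genome) and as a relaxed-PHYLIP alignment of the call
#' strings.
#'
#' @param matrix An `snp_matrix`.
#' @param tsv_path,phylip_path Output paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
write_snp_matrix <- function(matrix, tsv_path = NULL, phylip_path = NULL) {
  if (!is.null(tsv_path)) {
    chars <- lapply(matrix$calls, function(s) strsplit(s, "")[[1]])
    df <- data.frame(context = matrix$contexts,
                     ref_position = matrix$ref_position)
    for (id in matrix$genome_ids) df[[id]] <- chars[[id]]
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(phylip_path)) {
    con <- file(phylip_path, "wb")
    writeLines(sprintf("%d %d", length(matrix$genome_ids),
                       length(matrix$contexts)), con)
    for (id in matrix$genome_ids)
      writeLines(paste(id, matrix$calls[[id]]), con)
    close(con)
  }
  invisible(c(tsv_path, phylip_path))
}
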