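#' Whole-genome identification pipeline
#'
#' Identifies an assembled genome by single-copy housekeeping-gene voting
#' followed by fragment-based average nucleotide identity (ANI), types it
#' by MLST, and annotates its proteins by best hit.
#'
#' @name wgs
NULL

#' The 31 single-copy housekeeping genes
#'
#' The closed set of universal single-copy marker genes used for species
#' voting.
#' @return Character vector of the 31 gene names.
#' @export
hk_gene_names <- function() {
  c("dnaG", "frr", "infC", "nusA", "pgk", "pyrG", "rplA", "rplB", "rplC",
    "rplD", "rplE", "rplF", "rplK", "rplL", "rplM", "rplN", "rplP", "rplS",
    "rplT", "rpmA", "rpoB", "rpsB", "rpsC", "rpsE", "rpsI", "rpsJ", "rpsK",
    "rpsM", "rpsS", "smpB", "tsf")
}

# Codon -> amino acid lookup for the bacterial genetic code (table 11).
.genetic_code_11 <- local({
  code <- NULL
  function() {
    if (is.null(code)) {
      gc11 <- Biostrings::getGeneticCode("11")
      names(gc11) <- chartr("U", "T", names(gc11))
      code <<- gc11
    }
    code
  }
})

#' Translate a coding sequence (genetic code 11), dropping the stop
#' @param cds Nucleotide string whose length is divisible by 3, ending in
#'   a stop codon.
#' @return Amino-acid string (stop removed). Codons with ambiguous bases
#'   translate to `X`.
#' @export
translate_cds <- function(cds) {
  L <- nchar(cds)
  if (L %% 3L != 0L) stop("coding sequence length not divisible by 3")
  starts <- seq(1L, L, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- .genetic_code_11()[codons]
  aa[is.na(aa)] <- "X"
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# ORFs on one strand of one contig sequence; returns a data.frame with
# 0-based half-open coordinates on THAT strand.
.orfs_one_strand <- function(seq, min_aa) {
  L <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    n_codons <- (L - f) %/% 3L
    if (n_codons < 2L) next
    starts_nt <- f + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(seq, starts_nt, starts_nt + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_start <- codons %in% START_CODONS
    prev_stop <- 0L
    for (si in which(is_stop)) {
      if (si - 1L >= prev_stop + 1L) {
        seg <- (prev_stop + 1L):(si - 1L)
        starts_in_seg <- seg[is_start[seg]]
        if (length(starts_in_seg)) {
          a <- starts_in_seg[1L]
          n_aa <- si - a                # codons before the stop
          if (n_aa >= min_aa) {
            start0 <- f + 3L * (a - 1L)
            end0 <- f + 3L * si
            out[[length(out) + 1L]] <- data.frame(
              start = start0, end = end0,
              aa = translate_cds(substr(seq, start0 + 1L, end0)))
          }
        }
      }
      prev_stop <- si
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(), aa = character()))
  do.call(rbind, out)
}

#' Find open reading frames on both strands
#'
#' All maximal ATG/GTG/TTG-to-stop frames of at least `min_aa` codons, on
#' both strands, with coordinates reported 0-based half-open on the
#' forward axis of each contig; deterministic order (contig, start,
#' strand). A naive finder: the earliest start codon per stop-bounded
#' segment defines the maximal ORF; overlapping ORFs from different
#' frames or strands are all reported.
#'
#' @param genome A [seq_record] or list of contig [seq_record]s.
#' @param min_aa Minimum protein length in amino acids (default 60).
#' @return A data.frame with columns `contig_id`, `start`, `end`,
#'   `strand`, `aa` (stop codon removed from `aa`; `end - start`
#'   divisible by 3).
#' @export
find_orfs <- function(genome, min_aa = 60L) {
  contigs <- if (inherits(genome, "seq_record")) list(genome) else genome
  out <- list()
  for (ct in contigs) {
    L <- nchar(ct$sequence)
    fwd <- .orfs_one_strand(ct$sequence, min_aa)
    if (nrow(fwd)) {
      fwd$contig_id <- ct$id; fwd$strand <- "+"
      out[[length(out) + 1L]] <- fwd
    }
    rev <- .orfs_one_strand(reverse_complement(ct$sequence), min_aa)
    if (nrow(rev)) {
      tmp <- rev$start
      rev$start <- L - rev$end
      rev$end <- L - tmp
      rev$contig_id <- ct$id; rev$strand <- "-"
      out[[length(out) + 1L]] <- rev
    }
  }
  if (length(out) == 0L)
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      aa = character()))
  df <- do.call(rbind, out)
  df <- df[order(df$contig_id, df$start, df$strand),
           c("contig_id", "start", "end", "strand", "aa")]
  rownames(df) <- NULL
  df
}

#' Read a housekeeping-gene protein database FASTA
#'
#' Headers are `>species|strain|gene`; species names may contain spaces.
#' Gene names must come from the 31-name closed set.
#'
#' @param path FASTA path.
#' @return A data.frame with columns `species`, `strain`, `hk_gene`,
#'   `aa`.
#' @export
read_hk_db <- function(path) {
  records <- read_fasta(path)
  header <- vapply(records, function(r)
    if (nzchar(r$description)) paste(r$id, r$description) else r$id, "")
  parts <- strsplit(header, "|", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("housekeeping database headers must be 'species|strain|gene'")
  df <- data.frame(species = vapply(parts, `[`, "", 1L),
                   strain = vapply(parts, `[`, "", 2L),
                   hk_gene = vapply(parts, `[`, "", 3L),
                   aa = vapply(records, `[[`, "", "sequence"))
  bad <- setdiff(unique(df$hk_gene), hk_gene_names())
  if (length(bad))
    stop("unknown housekeeping gene name(s): ", paste(bad, collapse = ", "))
  df
}

#' Extract the housekeeping genes of a genome from its predicted proteins
#'
#' For each of the 31 genes, the single best-scoring predicted protein
#' against that gene's exemplar set (protein local alignment) is kept,
#' provided its e-value passes the cutoff; genes with no qualifying hit
#' are absent from the result.
#'
#' @param proteins A data.frame from [find_orfs].
#' @param exemplars A housekeeping database data.frame ([read_hk_db]),
#'   covering at least one sequence per gene of interest.
#' @param max_evalue E-value cutoff (default 1e-5).
#' @return A named list, gene name -> list(protein_index, aa, score,
#'   evalue).
#' @export
detect_hk_genes <- function(proteins, exemplars, max_evalue = 1e-5) {
  out <- list()
  if (nrow(proteins) == 0L || nrow(exemplars) == 0L) return(out)
  space <- sum(nchar(exemplars$aa))
  best <- list()
  for (pi in seq_len(nrow(proteins))) {
    df <- align_one_vs_many(proteins$aa[pi], exemplars$aa, mode = "protein",
                            search_space = nchar(proteins$aa[pi]) * space)
    df$gene <- exemplars$hk_gene
    ok <- df[df$evalue <= max_evalue, , drop = FALSE]
    if (nrow(ok) == 0L) next
    for (g in unique(ok$gene)) {
      sc <- max(ok$score[ok$gene == g])
      if (is.null(best[[g]]) || sc > best[[g]]$score)
        best[[g]] <- list(protein_index = pi, aa = proteins$aa[pi],
                          score = sc,
                          evalue = min(ok$evalue[ok$gene == g]))
    }
  }
  best[order(names(best))]
}

#' Rank database hits for one housekeeping-gene query
#'
#' Hits passing the e-value cutoff are sorted by score (descending), then
#' identity (descending), then species name; the list is cut at `top_n`
#' but extended through every entry tied with the rank-`top_n` entry on
#' both score and identity.
#'
#' @param query_aa Protein sequence of the query gene.
#' @param db Housekeeping database data.frame ([read_hk_db]).
#' @param top_n Hit-list size before tie extension (default 200).
#' @param max_evalue E-value cutoff (default 1e-5).
#' @return A data.frame `species`, `strain`, `hk_gene`, `score`,
#'   `identity`, `evalue`, ordered as described.
#' @export
rank_hits_per_gene <- function(query_aa, db, top_n = 200L,
                               max_evalue = 1e-5) {
  if (nrow(db) == 0L) stop("empty housekeeping database")
  df <- align_one_vs_many(query_aa, db$aa, mode = "protein",
                          search_space = nchar(query_aa) * sum(nchar(db$aa)))
  hits <- data.frame(species = db$species, strain = db$strain,
                     hk_gene = db$hk_gene, score = df$score,
                     identity = df$identity, evalue = df$evalue)
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  hits <- hits[order(-hits$score, -hits$identity, hits$species, hits$strain,
                     hits$hk_gene), , drop = FALSE]
  rownames(hits) <- NULL
  if (nrow(hits) > top_n) {
    thr_s <- hits$score[top_n]
    thr_i <- hits$identity[top_n]
    keep <- hits$score > thr_s |
      (hits$score == thr_s & hits$identity >= thr_i)
    hits <- hits[keep, , drop = FALSE]
  }
  hits
}

#' Vote species from per-gene hit lists
#'
#' For each species, counts the housekeeping genes whose hit list contains
#' at least one entry of that species; species below `min_genes` are
#' removed; survivors are sorted by gene count, then total best-hit
#' score, then name.
#'
#' @param per_gene_hits Named list, gene -> hit data.frame (needs
#'   `species` and `score` columns).
#' @param min_genes Minimum supporting genes (default 15).
#' @return A data.frame `species`, `n_hk_genes`, `total_score`, with a
#'   list-column `supporting_genes`.
#' @export
vote_species <- function(per_gene_hits, min_genes = 15L) {
  empty <- data.frame(species = character(), n_hk_genes = integer(),
                      total_score = numeric())
  if (length(per_gene_hits) == 0L) {
    empty$supporting_genes <- list()
    return(empty)
  }
  support <- list()   # species -> named numeric vector gene -> best score
  for (g in names(per_gene_hits)) {
    h <- per_gene_hits[[g]]
    if (is.null(h) || nrow(h) == 0L) next
    for (sp in unique(h$species)) {
      sc <- max(h$score[h$species == sp])
      support[[sp]] <- c(support[[sp]], setNames(sc, g))
    }
  }
  if (length(support) == 0L) {
    empty$supporting_genes <- list()
    return(empty)
  }
  out <- data.frame(species = names(support),
                    n_hk_genes = vapply(support, length, 1L),
                    total_score = vapply(support, sum, 1))
  out$supporting_genes <- lapply(support, names)
  out <- out[out$n_hk_genes >= min_genes, , drop = FALSE]
  out <- out[order(-out$n_hk_genes, -out$total_score, out$species), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fragment-based average nucleotide identity
#'
#' The query is cut into consecutive non-overlapping windows of
#' `fragment_len` bases (the last partial window dropped); each fragment
#' is locally aligned to the reference on both strands (exact-seed
#' anchoring selects the candidate reference window, then full local
#' alignment within it). Fragments reaching `min_identity` percent
#' identity over at least `min_cover` of their length are "used"; ANI is
#' the mean identity of used fragments and is flagged undefined when none
#' qualify.
#'
#' @param query,reference [seq_record]s or lists of contig records.
#' @param fragment_len Fragment window size (default 1020).
#' @param min_identity Minimum percent identity for a used fragment
#'   (default 30).
#' @param min_cover Minimum aligned fraction of a fragment (default 0.7).
#' @return A list with `ani` (percent, `NA` when undefined), `defined`,
#'   `fragments_used`, `fragments_total`.
#' @export
compute_ani <- function(query, reference, fragment_len = 1020L,
                        min_identity = 30, min_cover = 0.7) {
  qc <- if (inherits(query, "seq_record")) list(query) else query
  rc <- if (inherits(reference, "seq_record")) list(reference) else reference
  if (length(qc) == 0L || length(rc) == 0L) stop("empty genome")
  ref_seq <- paste(vapply(rc, `[[`, "", "sequence"),
                   collapse = strrep("N", 30L))
  ref_len <- nchar(ref_seq)
  idx <- kmer_table(ref_seq, 15L)
  data.table::setkey(idx, kmer)
  fragments <- character(0)
  for (ct in qc) {
    L <- nchar(ct$sequence)
    n_frag <- L %/% fragment_len
    if (n_frag == 0L) next
    starts <- (seq_len(n_frag) - 1L) * fragment_len + 1L
    fragments <- c(fragments,
                   substring(ct$sequence, starts, starts + fragment_len - 1L))
  }
  total <- length(fragments)
  # anchor every fragment on both strands, then batch-align all candidates
  patt <- character(0); subj <- character(0); frag_id <- integer(0)
  for (i in seq_along(fragments)) {
    for (strand_seq in c(fragments[i], reverse_complement(fragments[i]))) {
      win <- anchor_window(strand_seq, idx, ref_len)
      if (is.null(win)) next
      patt <- c(patt, strand_seq)
      subj <- c(subj, substr(ref_seq, win[1L], win[2L]))
      frag_id <- c(frag_id, i)
    }
  }
  used <- 0L
  ids <- numeric(0)
  if (length(patt)) {
    df <- align_pairs(patt, subj, mode = "nucleotide", type = "local")
    for (i in unique(frag_id)) {
      rows <- which(frag_id == i)
      b <- rows[which.max(df$score[rows])]
      if (df$identity[b] >= min_identity && df$query_cover[b] >= min_cover) {
        used <- used + 1L
        ids <- c(ids, df$identity[b])
      }
    }
  }
  list(ani = if (used > 0L) mean(ids) else NA_real_,
       defined = used > 0L, fragments_used = used, fragments_total = total)
}

#' Identify a genome by housekeeping-gene voting plus ANI
#'
#' Orchestrates [find_orfs], [detect_hk_genes], [rank_hits_per_gene] and
#' [vote_species]; for every species surviving the vote, ANI is computed
#' against up to `max_strains` of its database genomes (selected in
#' lexicographic strain order) and only the maximum per species is
#' reported. All surviving species are reported (mixed or contaminated
#' samples keep every supported candidate), sorted by maximum ANI.
#'
#' @param genome A [seq_record], list of contig records, or FASTA path.
#' @param hk_db Housekeeping database data.frame ([read_hk_db]) or FASTA
#'   path.
#' @param genome_db Manifest data.frame with columns `species`, `strain`,
#'   `path` (FASTA per strain), or the path of such a TSV.
#' @param min_genes Vote threshold (default 15).
#' @param max_strains Per-species cap on ANI computations (default 1000).
#' @param top_n,max_evalue Hit-list parameters (defaults 200, 1e-5).
#' @param min_aa Minimum ORF length in amino acids (default 60).
#' @return A list with `status` (`"ok"` or `"no_candidates"`),
#'   `candidates` (data.frame species / n_hk_genes / max_ani /
#'   best_strain / fragments_used / fragments_total, sorted by max ANI
#'   descending), `votes`, `hk_genes_found`, `n_orfs`.
#' @export
identify_genome <- function(genome, hk_db, genome_db, min_genes = 15L,
                            max_strains = 1000L, top_n = 200L,
                            max_evalue = 1e-5, min_aa = 60L) {
  if (is.character(genome)) genome <- read_fasta(genome)
  if (is.character(hk_db)) hk_db <- read_hk_db(hk_db)
  if (is.character(genome_db))
    genome_db <- utils::read.delim(genome_db, stringsAsFactors = FALSE)
  orfs <- find_orfs(genome, min_aa = min_aa)
  hk <- detect_hk_genes(orfs, hk_db, max_evalue = max_evalue)
  per_gene <- lapply(hk, function(h)
    rank_hits_per_gene(h$aa, db = hk_db, top_n = top_n,
                       max_evalue = max_evalue))
  votes <- vote_species(per_gene, min_genes = min_genes)
  candidates <- data.frame(species = character(), n_hk_genes = integer(),
                           max_ani = numeric(), best_strain = character(),
                           fragments_used = integer(),
                           fragments_total = integer())
  if (nrow(votes) == 0L) {
    warning("no species reached the vote threshold of ", min_genes, " genes")
    return(list(status = "no_candidates", candidates = candidates,
                votes = votes, hk_genes_found = names(hk),
                n_orfs = nrow(orfs)))
  }
  for (sp in votes$species) {
    rows <- genome_db[genome_db$species == sp, , drop = FALSE]
    rows <- rows[order(rows$strain), , drop = FALSE]
    rows <- utils::head(rows, max_strains)
    best <- list(ani = NA_real_, strain = NA_character_, used = 0L,
                 total = 0L)
    for (ri in seq_len(nrow(rows))) {
      res <- compute_ani(genome, read_fasta(rows$path[ri]))
      if (res$defined && (is.na(best$ani) || res$ani > best$ani))
        best <- list(ani = res$ani, strain = rows$strain[ri],
                     used = res$fragments_used, total = res$fragments_total)
    }
    candidates[nrow(candidates) + 1L, ] <-
      list(sp, votes$n_hk_genes[votes$species == sp], best$ani,
           best$strain, best$used, best$total)
  }
  candidates <- candidates[order(-ifelse(is.na(candidates$max_ani), -Inf,
                                         candidates$max_ani)), , drop = FALSE]
  rownames(candidates) <- NULL
  list(status = "ok", candidates = candidates, votes = votes,
       hk_genes_found = names(hk), n_orfs = nrow(orfs))
}

#' Read an MLST scheme directory
#'
#' The de-facto public-scheme layout: one FASTA per locus with headers
#' `>locus_allelenumber`, plus `profiles.tsv` whose columns are `ST` and
#' one column per locus.
#'
#' @param dir Scheme directory.
#' @return A list with `name`, `loci` (named list of named allele
#'   vectors), `profiles`.
#' @export
read_mlst_scheme <- function(dir) {
  profile_path <- file.path(dir, "profiles.tsv")
  if (!file.exists(profile_path)) stop("no profiles.tsv in ", dir)
  profiles <- utils::read.delim(profile_path, stringsAsFactors = FALSE)
  locus_names <- setdiff(colnames(profiles), "ST")
  loci <- list()
  for (locus in locus_names) {
    recs <- read_fasta(file.path(dir, paste0(locus, ".fasta")))
    nums <- sub(paste0("^", locus, "_"), "", vapply(recs, `[[`, "", "id"))
    loci[[locus]] <- setNames(vapply(recs, `[[`, "", "sequence"), nums)
  }
  list(name = basename(normalizePath(dir)), loci = loci, profiles = profiles)
}

#' MLST typing by exact allele matching
#'
#' Per locus, both strands of the genome are searched for an exact
#' full-length allele substring: exactly one matching allele gives its
#' number; no exact match but a best allele at >= 90 percent identity
#' gives `"novel"`; otherwise `"missing"`. The sequence type (ST) is
#' looked up in the profile table when every locus has a numeric allele;
#' any novel or missing locus, or an allele combination absent from the
#' table, leaves the ST `"unknown"`. Exact matches of two different
#' alleles at one locus raise an ambiguity error naming the locus.
#'
#' @param genome A [seq_record], list of contig records, or FASTA path.
#' @param scheme A scheme list ([read_mlst_scheme] or
#'   [build_toy_mlst_scheme]).
#' @return A list with `scheme_name`, `allele_calls` (named character),
#'   `st` (integer or `"unknown"`).
#' @export
mlst_type <- function(genome, scheme) {
  if (is.character(genome)) genome <- read_fasta(genome)
  contigs <- if (inherits(genome, "seq_record")) list(genome) else genome
  seqs <- vapply(contigs, `[[`, "", "sequence")
  both <- c(seqs, vapply(seqs, reverse_complement, ""))
  calls <- character(0)
  for (locus in names(scheme$loci)) {
    alleles <- scheme$loci[[locus]]
    exact <- names(alleles)[vapply(alleles, function(a)
      any(vapply(both, function(s) grepl(a, s, fixed = TRUE), TRUE)), TRUE)]
    if (length(exact) > 1L)
      stop("ambiguous exact matches at locus ", locus, ": alleles ",
           paste(exact, collapse = ", "))
    if (length(exact) == 1L) {
      calls[locus] <- exact
      next
    }
    if (is.null(attr(scheme, "contig_idx"))) {
      # cache one k-mer index per contig for novel-allele location
      idx_list <- lapply(seqs, function(s) {
        idx <- kmer_table(s, 15L)
        data.table::setkey(idx, kmer)
        idx
      })
      attr(scheme, "contig_idx") <- idx_list
    }
    idx_list <- attr(scheme, "contig_idx")
    best <- 0
    for (a in alleles) {
      for (ci in seq_along(seqs)) {
        for (strand_seq in c(a, reverse_complement(a))) {
          win <- anchor_window(strand_seq, idx_list[[ci]], nchar(seqs[ci]))
          if (is.null(win)) next
          best <- max(best, glocal_identity(strand_seq,
                                            substr(seqs[ci], win[1L],
                                                   win[2L])))
        }
      }
    }
    calls[locus] <- if (best >= 90) "novel" else "missing"
  }
  st <- "unknown"
  if (all(calls %in% unlist(lapply(scheme$loci, names)))) {
    prof <- scheme$profiles
    hit <- rep(TRUE, nrow(prof))
    for (locus in names(scheme$loci))
      hit <- hit & prof[[locus]] == as.integer(calls[locus])
    if (sum(hit) == 1L) st <- prof$ST[hit]
  }
  list(scheme_name = scheme$name %||% "scheme", allele_calls = calls,
       st = st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Best-hit functional annotation of proteins
#'
#' Each protein is aligned (protein mode) against a labeled protein
#' database; the best hit passing the e-value cutoff provides the label.
#' Proteins with no qualifying hit are omitted.
#'
#' @param proteins A data.frame from [find_orfs] (needs an `aa` column).
#' @param annotation_db List of [seq_record]s whose descriptions are the
#'   functional labels, or a FASTA path.
#' @param max_evalue E-value cutoff (default 1e-5).
#' @return A list with `table` (data.frame protein_index / gene /
#'   best_label / score / evalue) and `summary` (counts per label).
#' @export
annotate_proteins <- function(proteins, annotation_db, max_evalue = 1e-5) {
  if (is.character(annotation_db)) annotation_db <- read_fasta(annotation_db)
  empty <- data.frame(protein_index = integer(), gene = character(),
                      best_label = character(), score = numeric(),
                      evalue = numeric())
  if (length(annotation_db) == 0L || nrow(proteins) == 0L)
    return(list(table = empty, summary = table(character())))
  db_aa <- vapply(annotation_db, `[[`, "", "sequence")
  db_label <- vapply(annotation_db, function(r)
    if (nzchar(r$description)) r$description else r$id, "")
  space_n <- sum(nchar(db_aa))
  out <- empty
  for (pi in seq_len(nrow(proteins))) {
    df <- align_one_vs_many(proteins$aa[pi], db_aa, mode = "protein",
                            search_space = nchar(proteins$aa[pi]) * space_n)
    ok <- which(df$evalue <= max_evalue)
    if (length(ok) == 0L) next
    b <- ok[order(-df$score[ok], db_label[ok])][1L]
    out[nrow(out) + 1L, ] <- list(pi,
                                  vapply(annotation_db, `[[`, "", "id")[b],
                                  db_label[b], df$score[b], df$evalue[b])
  }
  list(table = out, summary = table(out$best_label))
}
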