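#' Deterministic synthetic data generators
#'
#' Every generator takes an explicit seed and restores the caller's RNG
#' state, so fixed seeds give byte-identical outputs, and every generator
#' returns machine-readable ground truth alongside the data.
#'
#' @name fixtures
NULL

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.random_bases <- function(n, gc = 0.5) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Random genome with controlled GC content
#'
#' I.i.d. bases with `P(G) + P(C) = gc_content`, split evenly between the
#' two bases of each pair.
#'
#' @param length Genome length in bases (>= 1).
#' @param gc_content GC fraction in `[0, 1]` (default 0.5).
#' @param seed Integer seed.
#' @param id Record id (default `"genome"`).
#' @return A [seq_record].
#' @export
random_genome <- function(length, gc_content = 0.5, seed = 1L,
                          id = "genome") {
  if (length < 1L) stop("length must be >= 1")
  if (gc_content < 0 || gc_content > 1) stop("gc_content must lie in [0, 1]")
  seq <- with_seed(seed, paste(.random_bases(length, gc_content),
                               collapse = ""))
  seq_record(id, seq, sprintf("synthetic gc=%g seed=%d", gc_content, seed))
}

#' Point-mutate a genome at a given substitution rate
#'
#' Without `min_spacing`, every position is substituted independently with
#' probability `substitution_rate` (to a uniformly chosen different
#' base). With `min_spacing`, exactly `ceiling(rate * length)`
#' substitutions are placed at least `min_spacing` bases apart, which
#' makes the returned truth positions directly usable as exact SNP truth.
#'
#' @param genome A [seq_record] (or plain sequence).
#' @param substitution_rate Per-base substitution probability, `< 0.5`.
#' @param seed Integer seed.
#' @param min_spacing Optional minimum distance between substitutions.
#' @return A list with `record` (the mutated [seq_record]) and
#'   `positions` (sorted 1-based positions of the planted substitutions).
#' @export
mutate_genome <- function(genome, substitution_rate, seed = 1L,
                          min_spacing = NULL) {
  if (substitution_rate >= 0.5) stop("substitution_rate must be < 0.5")
  s <- .as_string(genome)
  L <- nchar(s)
  id <- paste0(.rec_id(genome, "genome"), "_mut")
  with_seed(seed, {
    if (is.null(min_spacing)) {
      pos <- which(stats::runif(L) < substitution_rate)
    } else {
      n_target <- ceiling(substitution_rate * L)
      cand <- sample.int(L)
      blocked <- logical(L)
      pos <- integer(0)
      for (p in cand) {
        if (blocked[p]) next
        pos <- c(pos, p)
        if (length(pos) == n_target) break
        blocked[max(1L, p - min_spacing + 1L):min(L, p + min_spacing - 1L)] <- TRUE
      }
      if (length(pos) < n_target)
        stop("cannot place ", n_target, " substitutions ", min_spacing,
             " bases apart in ", L, " bases")
      pos <- sort(pos)
    }
    ch <- strsplit(s, "")[[1]]
    bases <- c("A", "C", "G", "T")
    for (p in pos) {
      alt <- setdiff(bases, ch[p])
      ch[p] <- alt[sample.int(length(alt), 1L)]
    }
    list(record = seq_record(id, paste(ch, collapse = ""),
                             sprintf("mutated rate=%g seed=%d",
                                     substitution_rate, seed)),
         positions = pos)
  })
}

#' Built-in amplicon region primer pairs
#'
#' Standard published 16S primers: V3-V4 = 341F/805R, V4 = 515F/806R,
#' V4-V5 = 515F/926R (IUPAC codes included).
#'
#' @param region `"V3V4"`, `"V4"`, or `"V4V5"`.
#' @return A list with `fwd` and `rev` primer sequences.
#' @export
region_primers <- function(region = c("V3V4", "V4", "V4V5")) {
  region <- match.arg(region)
  switch(region,
         V3V4 = list(fwd = "CCTACGGGNGGCWGCAG",
                     rev = "GACTACHVGGGTATCTAATCC"),
         V4   = list(fwd = "GTGYCAGCMGCCGCGGTAA",
                     rev = "GGACTACNVGGGTWTCTAAT"),
         V4V5 = list(fwd = "GTGYCAGCMGCCGCGGTAA",
                     rev = "CCGYCAATTYMTTTRAGTTT"))
}

# One concrete realization of an IUPAC primer (first base of each set).
iupac_realize <- function(primer) {
  paste(vapply(.primer_sets(primer), `[`, "", 1L), collapse = "")
}

# Concrete 805R/806R binding site on the forward strand: contains the
# reverse complement of an 805R realization at offset 0 and of an 806R
# realization at offset 2 (the two primers overlap on real 16S).
S806_SITE <- "GGATTAGATACCCTGGTAGTCC"

#' Synthetic taxonomy-annotated 16S-like references
#'
#' Builds compact synthetic marker sequences that carry the real V3-V4 /
#' V4 / V4-V5 primer binding sites around random inter-primer regions
#' (about 90-130 bases; deliberately shorter than biological regions so
#' that desk-scale read counts give every taxon solid duplicate support).
#' Each taxon gets its own genus, so genus-level truth equals the taxon.
#'
#' @param n_taxa Number of reference taxa (default 20).
#' @param seed Integer seed.
#' @return A list with `records`, `lineages`, and `truth`
#'   (data.frame taxon_id / genus / species).
#' @export
make_toy_16s_refs <- function(n_taxa = 20L, seed = 1L) {
  f341 <- iupac_realize(region_primers("V3V4")$fwd)
  f515 <- iupac_realize(region_primers("V4")$fwd)
  r926site <- reverse_complement(iupac_realize(region_primers("V4V5")$rev))
  with_seed(seed, {
    records <- vector("list", n_taxa)
    lineages <- vector("list", n_taxa)
    truth <- data.frame(taxon_id = character(n_taxa), genus = character(n_taxa),
                        species = character(n_taxa))
    for (i in seq_len(n_taxa)) {
      seg <- function(n) paste(.random_bases(n), collapse = "")
      seqi <- paste0(seg(40), f341, seg(20), f515, seg(90), S806_SITE,
                     seg(20), r926site, seg(40))
      id <- sprintf("ref%03d", i)
      genus <- sprintf("Genus%02d", i)
      species <- sprintf("%s toyspecies%02d", genus, i)
      lineages[[i]] <- parse_lineage(sprintf(
        "d__Bacteria;p__Phylum%02d;c__Class%02d;o__Order%02d;f__Family%02d;g__%s;s__%s",
        (i - 1L) %% 4L + 1L, (i - 1L) %% 4L + 1L, (i - 1L) %% 6L + 1L,
        (i - 1L) %% 8L + 1L, genus, species))
      records[[i]] <- seq_record(id, seqi, format(lineages[[i]]))
      truth[i, ] <- list(id, genus, species)
    }
    list(records = records, lineages = lineages, truth = truth)
  })
}

# Locate an IUPAC primer site (exact, 0 mismatches) on the forward strand;
# returns c(start, end) 1-based or NULL.
.find_site <- function(seq, primer) {
  sets <- .primer_sets(primer)
  m <- length(sets)
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  if (m > L) return(NULL)
  mm <- .primer_mismatches(ch, sets, seq_len(L - m + 1L))
  at <- which(mm == 0L)
  if (length(at) == 0L) return(NULL)
  c(at[1L], at[1L] + m - 1L)
}

# Read qualities: constant Q38 with linear decay to Q20 over the final 20%.
.read_qualities <- function(len) {
  q <- rep(38L, len)
  tail_len <- max(1L, floor(len * 0.2))
  from <- len - tail_len + 1L
  q[from:len] <- as.integer(round(seq(38, 20, length.out = tail_len)))
  q
}

.apply_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  bases <- c("A", "C", "G", "T")
  for (p in hit) {
    alt <- setdiff(bases, ch[p])
    ch[p] <- alt[sample.int(3L, 1L)]
  }
  paste(ch, collapse = "")
}

#' Simulate paired amplicon reads from labeled references
#'
#' Extracts the primer-delimited region of the chosen variable region
#' from each reference, synthesizes overlapping read pairs with the
#' primers attached, applies independent per-base substitution errors,
#' and assigns plausible qualities (Q38 with a decaying tail). References
#' in which a primer site cannot be found are skipped with a warning.
#'
#' @param refs A list as returned by [make_toy_16s_refs] (`records`,
#'   `lineages`, `truth`), or any list of records plus parallel truth.
#' @param region `"V3V4"`, `"V4"`, or `"V4V5"`.
#' @param n_reads_per_taxon Read pairs per reference taxon (default 50).
#' @param base_error_rate Per-base substitution error probability
#'   (default 0.01).
#' @param read_length Read length in bases (default 100; capped at the
#'   amplicon length).
#' @param seed Integer seed.
#' @param out_dir Directory for the FASTQ files (created if needed).
#' @return A list with `fwd_path`, `rev_path`, `truth` (data.frame
#'   read_id / taxon_id / genus), and `n_pairs`.
#' @export
simulate_amplicon_reads <- function(refs, region = c("V3V4", "V4", "V4V5"),
                                    n_reads_per_taxon = 50L,
                                    base_error_rate = 0.01,
                                    read_length = 100L, seed = 1L,
                                    out_dir = tempfile("amplicon_sim_")) {
  region <- match.arg(region)
  primers <- region_primers(region)
  rc_rev <- reverse_complement(primers$rev)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fwd_recs <- list(); rev_recs <- list()
  truth <- data.frame(read_id = character(), taxon_id = character(),
                      genus = character())
  with_seed(seed, {
    for (i in seq_along(refs$records)) {
      ref <- refs$records[[i]]
      fs <- .find_site(ref$sequence, primers$fwd)
      # the reverse site is the rightmost occurrence of rc(rev_primer)
      rs <- .find_site(reverse_complement(ref$sequence), primers$rev)
      if (is.null(fs) || is.null(rs)) {
        warning("primer site not found in ", ref$id, "; taxon skipped")
        next
      }
      L <- nchar(ref$sequence)
      r_end <- L - rs[1L] + 1L
      r_start <- L - rs[2L] + 1L
      if (r_start <= fs[2L]) {
        warning("primer sites overlap in ", ref$id, "; taxon skipped")
        next
      }
      amplicon <- substr(ref$sequence, fs[1L], r_end)
      rlen <- min(read_length, nchar(amplicon))
      f_tmpl <- substr(amplicon, 1L, rlen)
      r_tmpl <- reverse_complement(substr(amplicon,
                                          nchar(amplicon) - rlen + 1L,
                                          nchar(amplicon)))
      genus <- refs$truth$genus[i]
      for (n in seq_len(n_reads_per_taxon)) {
        rid <- sprintf("sim_%s_%s_%04d", region, ref$id, n)
        fseq <- .apply_errors(f_tmpl, base_error_rate)
        rseq <- .apply_errors(r_tmpl, base_error_rate)
        fwd_recs[[length(fwd_recs) + 1L]] <-
          seq_record(paste0(rid, "/1"), fseq, "", .read_qualities(rlen))
        rev_recs[[length(rev_recs) + 1L]] <-
          seq_record(paste0(rid, "/2"), rseq, "", .read_qualities(rlen))
        truth[nrow(truth) + 1L, ] <- list(rid, ref$id, genus)
      }
    }
  })
  fwd_path <- file.path(out_dir, sprintf("%s_R1.fastq", region))
  rev_path <- file.path(out_dir, sprintf("%s_R2.fastq", region))
  write_records(fwd_recs, fwd_path, "fastq")
  write_records(rev_recs, rev_path, "fastq")
  list(fwd_path = fwd_path, rev_path = rev_path, truth = truth,
       n_pairs = length(fwd_recs))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

# Random ORF: ATG + (n_codons - 2) non-stop codons + TAA.
.random_orf <- function(n_codons) {
  all_codons <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                                c("A", "C", "G", "T"),
                                                paste0)),
                                c("A", "C", "G", "T"), paste0))
  sense <- setdiff(all_codons, STOP_CODONS)
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

# Mutate an ORF at a per-site rate while preserving the reading frame:
# start and stop codons untouched, substitutions that would create an
# in-frame stop re-drawn (or skipped).
.mutate_orf <- function(orf, rate) {
  ch <- strsplit(orf, "")[[1]]
  L <- length(ch)
  pos <- which(stats::runif(L) < rate)
  pos <- pos[pos > 3L & pos <= L - 3L]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    ci <- ((p - 1L) %/% 3L) * 3L + 1L
    for (b in sample(setdiff(bases, ch[p]))) {
      trial <- ch
      trial[p] <- b
      if (!(paste(trial[ci:(ci + 2L)], collapse = "") %in% STOP_CODONS)) {
        ch <- trial
        break
      }
    }
  }
  paste(ch, collapse = "")
}

#' Build a toy housekeeping-gene database with matching genomes
#'
#' Generates one ancestral nucleotide ORF per housekeeping gene, diverges
#' it per species at `inter_species_divergence` (frame-preserving), adds
#' small per-strain divergence, writes the protein database FASTA
#' (headers `>species|strain|gene`), one genome FASTA per strain with the
#' genes embedded in random background (every fifth gene on the minus
#' strand), and a manifest TSV (species, strain, path).
#'
#' @param n_species Number of species (default 3).
#' @param n_strains_per_species Strains per species (default 2).
#' @param inter_species_divergence Per-site nucleotide divergence between
#'   species, in `(0, 0.3)` (default 0.1).
#' @param seed Integer seed.
#' @param out_dir Output directory (created).
#' @param n_codons Gene length in codons (default 150).
#' @param strain_divergence Per-site divergence between strains of one
#'   species (default 0.005).
#' @return A list with `hk_fasta`, `manifest_path`, `manifest`
#'   (data.frame species/strain/path), `truth` (data.frame
#'   genome/species), and `species`.
#' @export
build_toy_hk_db <- function(n_species = 3L, n_strains_per_species = 2L,
                            inter_species_divergence = 0.1, seed = 1L,
                            out_dir = tempfile("toy_hk_"),
                            n_codons = 150L, strain_divergence = 0.005) {
  if (inter_species_divergence <= 0 || inter_species_divergence >= 0.3)
    stop("inter_species_divergence must lie in (0, 0.3)")
  genes <- hk_gene_names()
  dir.create(file.path(out_dir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)
  with_seed(seed, {
    ancestral <- setNames(lapply(genes, function(g) .random_orf(n_codons)),
                          genes)
    species <- sprintf("Toybacterium %s", letters[seq_len(n_species)])
    hk_records <- list()
    manifest <- data.frame(species = character(), strain = character(),
                           path = character())
    truth <- data.frame(genome = character(), species = character())
    for (si in seq_len(n_species)) {
      sp_genes <- lapply(ancestral, .mutate_orf, rate = inter_species_divergence)
      for (st in seq_len(n_strains_per_species)) {
        strain <- sprintf("strain%02d", st)
        st_genes <- lapply(sp_genes, .mutate_orf, rate = strain_divergence)
        parts <- character(0)
        for (gi in seq_along(genes)) {
          parts <- c(parts, paste(.random_bases(150L), collapse = ""),
                     if (gi %% 5L == 0L) reverse_complement(st_genes[[gi]])
                     else st_genes[[gi]])
          aa <- translate_cds(st_genes[[gi]])
          hk_records[[length(hk_records) + 1L]] <- seq_record(
            "hk", aa, "", NULL)
          # header carried separately; see write below
          attr(hk_records[[length(hk_records)]], "header") <-
            sprintf("%s|%s|%s", species[si], strain, genes[gi])
        }
        parts <- c(parts, paste(.random_bases(150L), collapse = ""))
        gseq <- paste(parts, collapse = "")
        gname <- sprintf("%s_%s", gsub(" ", "_", species[si]), strain)
        gpath <- file.path(out_dir, "genomes", paste0(gname, ".fasta"))
        write_records(list(seq_record(gname, gseq)), gpath, "fasta")
        manifest[nrow(manifest) + 1L, ] <- list(species[si], strain, gpath)
        truth[nrow(truth) + 1L, ] <- list(gpath, species[si])
      }
    }
    hk_fasta <- file.path(out_dir, "hk_db.fasta")
    con <- file(hk_fasta, "wb")
    for (r in hk_records)
      writeLines(c(paste0(">", attr(r, "header")), r$sequence), con, sep = "\n")
    close(con)
    manifest_path <- file.path(out_dir, "manifest.tsv")
    utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(hk_fasta = hk_fasta, manifest_path = manifest_path,
         manifest = manifest, truth = truth, species = species)
  })
}

#' Build a toy MLST scheme
#'
#' Per-locus allele FASTAs (alleles pairwise at Hamming distance >= 2), a
#' profile table, and (via [mlst_genome_for_profile]) genomes realizing
#' any chosen sequence type.
#'
#' @param n_loci Number of loci (default 7).
#' @param n_alleles_per_locus Alleles per locus (default 5).
#' @param n_profiles Rows of the profile table (default 10).
#' @param seed Integer seed.
#' @param out_dir Output directory (created).
#' @param allele_len Allele length in bases (default 400).
#' @return A list with `dir`, `loci` (named list: locus -> named character
#'   vector of allele sequences), `profiles` (data.frame with ST and one
#'   column per locus), and `profile_path`.
#' @export
build_toy_mlst_scheme <- function(n_loci = 7L, n_alleles_per_locus = 5L,
                                  n_profiles = 10L, seed = 1L,
                                  out_dir = tempfile("toy_mlst_"),
                                  allele_len = 400L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    loci <- list()
    for (li in seq_len(n_loci)) {
      locus <- sprintf("loc%d", li)
      base <- strsplit(paste(.random_bases(allele_len), collapse = ""), "")[[1]]
      alleles <- character(n_alleles_per_locus)
      bases <- c("A", "C", "G", "T")
      for (a in seq_len(n_alleles_per_locus)) {
        ch <- base
        for (p in c(2L * a - 1L, 2L * a)) {           # unique position pair
          ch[p] <- setdiff(bases, ch[p])[sample.int(3L, 1L)]
        }
        alleles[a] <- paste(ch, collapse = "")
      }
      names(alleles) <- as.character(seq_len(n_alleles_per_locus))
      loci[[locus]] <- alleles
      con <- file(file.path(out_dir, paste0(locus, ".fasta")), "wb")
      for (a in names(alleles))
        writeLines(c(sprintf(">%s_%s", locus, a), alleles[[a]]), con,
                   sep = "\n")
      close(con)
    }
    combos <- unique(t(replicate(n_profiles * 4L,
                                 sample.int(n_alleles_per_locus, n_loci,
                                            replace = TRUE))))
    combos <- combos[seq_len(min(n_profiles, nrow(combos))), , drop = FALSE]
    profiles <- data.frame(ST = seq_len(nrow(combos)))
    for (li in seq_len(n_loci)) profiles[[names(loci)[li]]] <- combos[, li]
    profile_path <- file.path(out_dir, "profiles.tsv")
    utils::write.table(profiles, profile_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(dir = out_dir, loci = loci, profiles = profiles,
         profile_path = profile_path)
  })
}

#' Synthesize a genome realizing one profile row of a toy MLST scheme
#'
#' @param scheme A scheme list from [build_toy_mlst_scheme] (or
#'   [read_mlst_scheme]).
#' @param st Sequence type (row of the profile table) to realize.
#' @param seed Integer seed for the spacer sequence.
#' @return A [seq_record] containing every allele of that profile row
#'   separated by random spacers.
#' @export
mlst_genome_for_profile <- function(scheme, st, seed = 1L) {
  row <- scheme$profiles[scheme$profiles$ST == st, , drop = FALSE]
  if (nrow(row) != 1L) stop("no profile row with ST ", st)
  with_seed(seed, {
    parts <- character(0)
    for (locus in names(scheme$loci)) {
      allele <- scheme$loci[[locus]][[as.character(row[[locus]])]]
      parts <- c(parts, paste(.random_bases(100L), collapse = ""), allele)
    }
    parts <- c(parts, paste(.random_bases(100L), collapse = ""))
    seq_record(sprintf("st%d_genome", st), paste(parts, collapse = ""))
  })
}
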