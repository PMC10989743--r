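#' Amplicon identification pipeline
#'
#' From paired FASTQ reads to denoised amplicon sequence variants (ASVs)
#' with best-hit taxonomy: sliding-window quality trimming, length and
#' ambiguity filtering, pair merging, IUPAC-aware primer removal,
#' dereplication, error-profile denoising, and best-hit assignment with
#' lowest-common-ancestor truncation on ties.
#'
#' @name amplicon
NULL

#' Sliding-window quality trimming
#'
#' Scans windows of `window` bases left to right with step 1 and truncates
#' the read at the start of the first window whose mean Phred quality
#' falls below `min_mean_q`. Reads shorter than the window are kept
#' unchanged if their overall mean quality reaches the threshold and
#' dropped otherwise.
#'
#' @param record A [seq_record] with qualities.
#' @param window Window width in bases (default 50).
#' @param min_mean_q Minimum mean quality per window (default 20).
#' @return The (possibly truncated) record, or `NULL` when nothing
#'   survives.
#' @export
sliding_window_trim <- function(record, window = 50L, min_mean_q = 20) {
  if (is.null(record$qualities)) stop("sliding_window_trim needs qualities")
  if (window < 1L) stop("window must be >= 1")
  q <- record$qualities
  L <- length(q)
  if (L < window) {
    return(if (mean(q) >= min_mean_q) record else NULL)
  }
  cs <- c(0, cumsum(q))
  means <- (cs[(window + 1L):(L + 1L)] - cs[1L:(L - window + 1L)]) / window
  bad <- which(means < min_mean_q)
  if (length(bad) == 0L) return(record)
  keep <- bad[1L] - 1L
  if (keep == 0L) return(NULL)
  seq_record(record$id, substr(record$sequence, 1L, keep),
             record$description, q[seq_len(keep)])
}

#' Length and ambiguity filter
#'
#' @param record A [seq_record].
#' @param min_len Minimum length kept, inclusive (a read of exactly
#'   `min_len` bases passes).
#' @return A list with `keep` (logical) and `reason` (`NA`, `"short"` or
#'   `"ambiguous"`).
#' @export
quality_filter <- function(record, min_len = 50L) {
  if (nchar(record$sequence) < min_len)
    return(list(keep = FALSE, reason = "short"))
  if (grepl("[^ACGT]", record$sequence))
    return(list(keep = FALSE, reason = "ambiguous"))
  list(keep = TRUE, reason = NA_character_)
}

#' Merge a read pair over its best ungapped overlap
#'
#' The reverse mate is reverse-complemented, then every ungapped overlap
#' placement of at least `min_overlap` bases is scored; the placement
#' with the most matching bases whose mismatch fraction does not exceed
#' `max_mismatch_frac` wins (ties resolved toward the longer overlap).
#' Merged qualities: where the mates agree, the larger of the two scores;
#' where they conflict, the higher-quality base wins and gets the
#' difference of the two scores (the forward base on an exact tie).
#'
#' @param forward,reverse Mate [seq_record]s with qualities.
#' @param min_overlap Minimum overlap length (default 10).
#' @param max_mismatch_frac Maximum mismatch fraction inside the overlap
#'   (default 0.1).
#' @return The merged [seq_record], or `NULL` when no placement
#'   qualifies.
#' @export
merge_pair <- function(forward, reverse, min_overlap = 10L,
                       max_mismatch_frac = 0.1) {
  f <- forward$sequence
  r <- reverse_complement(reverse$sequence)
  fq <- forward$qualities
  rq <- rev(reverse$qualities)
  if (is.null(fq) || is.null(rq)) stop("merge_pair needs qualities")
  fr <- utf8ToInt(f); rr <- utf8ToInt(r)
  Lf <- length(fr); Lr <- length(rr)
  best <- NULL
  for (d in 0:(Lf - min_overlap)) {
    o <- min(Lf - d, Lr)
    if (o < min_overlap) break
    fi <- (d + 1L):(d + o)
    mism <- sum(fr[fi] != rr[seq_len(o)])
    if (mism / o > max_mismatch_frac) next
    sc <- o - mism
    if (is.null(best) || sc > best$sc) best <- list(d = d, o = o, sc = sc)
  }
  if (is.null(best)) return(NULL)
  d <- best$d; o <- best$o
  fi <- (d + 1L):(d + o)
  ov_f <- fr[fi]; ov_r <- rr[seq_len(o)]
  qf <- fq[fi]; qr <- rq[seq_len(o)]
  agree <- ov_f == ov_r
  take_f <- agree | (qf >= qr)
  ov_base <- ifelse(take_f, ov_f, ov_r)
  ov_q <- ifelse(agree, pmax(qf, qr), abs(qf - qr))
  merged_seq <- intToUtf8(c(fr[seq_len(d)], ov_base,
                            if (o < Lr) rr[(o + 1L):Lr] else integer()))
  merged_q <- c(fq[seq_len(d)], as.integer(ov_q),
                if (o < Lr) rq[(o + 1L):Lr] else integer())
  seq_record(sub("(/[12]|[._][12])$", "", forward$id), merged_seq,
             forward$description, merged_q)
}

# Count IUPAC-aware mismatches of `primer` against `seq` at 1-based
# offsets `starts`; returns an integer vector (NA where primer overruns).
.primer_mismatches <- function(seq_chars, primer_sets, starts) {
  m <- length(primer_sets)
  vapply(starts, function(p) {
    idx <- p:(p + m - 1L)
    if (idx[m] > length(seq_chars)) return(NA_integer_)
    sum(!mapply(function(set, b) b %in% set, primer_sets, seq_chars[idx]))
  }, integer(1))
}

.primer_sets <- function(primer) {
  ch <- strsplit(toupper(primer), "")[[1]]
  unknown <- setdiff(ch, names(IUPAC_SETS))
  if (length(unknown)) stop("non-IUPAC character in primer: ", unknown[1])
  IUPAC_SETS[ch]
}

#' Locate and remove the primer pair from a merged read
#'
#' The forward primer is searched (IUPAC-aware, up to `max_mismatch`
#' mismatches) within the first `len(primer) + max_mismatch + 5` bases and
#' the reverse complement of the reverse primer within the same span at
#' the 3' end. Both primer copies and everything outside them are
#' removed. Reads missing either primer, or shorter than a primer, are
#' dropped.
#'
#' @param record Merged [seq_record] (qualities optional).
#' @param fwd_primer,rev_primer Primer sequences; IUPAC codes allowed,
#'   `rev_primer` given in its own 5'->3' orientation.
#' @param max_mismatch Maximum mismatches per primer (default 2).
#' @return The insert [seq_record], or `NULL` when dropped.
#' @export
trim_primers <- function(record, fwd_primer, rev_primer, max_mismatch = 2L) {
  s <- record$sequence
  L <- nchar(s)
  fsets <- .primer_sets(fwd_primer)
  rsets <- .primer_sets(reverse_complement(rev_primer))
  mf <- length(fsets); mr <- length(rsets)
  if (mf > L || mr > L) return(NULL)
  ch <- strsplit(s, "")[[1]]
  f_starts <- seq_len(min(max_mismatch + 6L, L - mf + 1L))
  fm <- .primer_mismatches(ch, fsets, f_starts)
  f_ok <- which(!is.na(fm) & fm <= max_mismatch)
  if (length(f_ok) == 0L) return(NULL)
  f_at <- f_starts[f_ok[which.min(fm[f_ok])]]
  r_from <- max(1L, L - (mr + max_mismatch + 5L) + 1L)
  r_starts <- r_from:(L - mr + 1L)
  rm_ <- .primer_mismatches(ch, rsets, r_starts)
  r_ok <- which(!is.na(rm_) & rm_ <= max_mismatch)
  if (length(r_ok) == 0L) return(NULL)
  r_at <- r_starts[r_ok[which.max(-rm_[r_ok])]]
  ins_from <- f_at + mf
  ins_to <- r_at - 1L
  if (ins_to < ins_from) return(NULL)
  seq_record(record$id, substr(s, ins_from, ins_to), record$description,
             if (!is.null(record$qualities)) record$qualities[ins_from:ins_to])
}

#' Exact dereplication
#'
#' Groups identical sequences and counts them; output is sorted by count
#' descending with ties broken lexicographically by sequence. The counts
#' sum to the input length.
#'
#' @param seqs Character vector of sequences.
#' @return A data.frame with columns `sequence` and `count`.
#' @export
dereplicate <- function(seqs) {
  if (length(seqs) == 0L)
    return(data.frame(sequence = character(), count = integer()))
  tab <- table(seqs)
  df <- data.frame(sequence = names(tab), count = as.integer(tab))
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Default per-distance error profile for denoising
#'
#' Fraction of a parent's reads expected to appear as neighbors at
#' Hamming distance d (index d of the vector), following the published
#' defaults of greedy-subtraction denoisers.
#' @return Numeric vector for distances 1..11.
#' @export
default_error_profile <- function() {
  c(0.06, 0.02, 0.02, 0.01, 0.005, 0.005, 0.005, 0.001, 0.001, 0.001, 0.0005)
}

# 32-bit FNV-1a content hash, for order-independent ASV ids.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- h %% 256                      # xor touches only the low byte
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # h * 16777619 mod 2^32; 16777619 = 403 + 2^24, kept exact in doubles
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  hex <- character(8)
  for (i in 8:1) {
    hex[i] <- substr("0123456789abcdef", h %% 16 + 1, h %% 16 + 1)
    h <- h %/% 16
  }
  paste0("asv_", paste(hex, collapse = ""))
}

#' Greedy error-profile denoising into ASVs
#'
#' Sequences are visited in decreasing abundance. For the current
#' sequence with remaining count c, every other sequence at Hamming
#' distance d within the profile has `c * error_profile[d]` subtracted
#' from its remaining count. Sequences whose remaining count has dropped
#' below `min_count` are removed (and do not subtract in their turn);
#' survivors become ASVs carrying their original counts. Sequences are
#' padded/trimmed to the abundance-weighted modal length first.
#'
#' @param uniques A data.frame from [dereplicate] (sequence, count),
#'   sorted by count descending.
#' @param error_profile Numeric vector; entry d is the error fraction at
#'   Hamming distance d. Must be non-empty.
#' @param min_count Minimum surviving count (default 2).
#' @return A data.frame with columns `id` (content hash), `sequence`, and
#'   `count`.
#' @export
denoise <- function(uniques, error_profile = default_error_profile(),
                    min_count = 2L) {
  if (length(error_profile) == 0L) stop("error profile must be non-empty")
  n <- nrow(uniques)
  if (n == 0L)
    return(data.frame(id = character(), sequence = character(),
                      count = integer()))
  lens <- nchar(uniques$sequence)
  wtab <- tapply(uniques$count, lens, sum)
  modal <- as.integer(names(wtab)[which.max(wtab)])
  norm <- vapply(uniques$sequence, function(s) {
    if (nchar(s) >= modal) substr(s, 1L, modal)
    else paste0(s, strrep("N", modal - nchar(s)))
  }, "", USE.NAMES = FALSE)
  D <- as.matrix(Biostrings::stringDist(Biostrings::BStringSet(norm),
                                        method = "hamming"))
  remaining <- as.numeric(uniques$count)
  maxd <- length(error_profile)
  for (i in seq_len(n)) {
    if (remaining[i] < min_count) next
    d <- D[i, ]
    hit <- which(d >= 1 & d <= maxd)
    hit <- hit[hit != i]
    if (length(hit))
      remaining[hit] <- remaining[hit] - remaining[i] * error_profile[d[hit]]
  }
  keep <- remaining >= min_count
  out <- data.frame(
    id = vapply(norm[keep], fnv1a32, "", USE.NAMES = FALSE),
    sequence = norm[keep],
    count = uniques$count[keep])
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best-hit taxonomy assignment with LCA tie truncation
#'
#' The ASV is aligned end-to-end against its best-matching window of each
#' reference (references are typically full-length marker sequences while
#' ASVs are primer-delimited sub-regions). The best hit sets the lineage;
#' exact identity ties between references that disagree truncate the
#' lineage to their lowest common ancestor; a best identity below
#' `min_identity` leaves the ASV unclassified (empty lineage).
#'
#' @param asv One row of the [denoise] output (list or data.frame row
#'   with `id` and `sequence`), or a plain sequence string.
#' @param ref_records List of reference [seq_record]s.
#' @param ref_lineages List of `lineage` objects, parallel to
#'   `ref_records`.
#' @param min_identity Minimum percent identity for classification
#'   (default 80).
#' @return A list with `asv_id`, `lineage`, `best_hit_accession`,
#'   `identity`, and `n_tied_hits`.
#' @export
assign_taxonomy <- function(asv, ref_records, ref_lineages,
                            min_identity = 80) {
  if (length(ref_records) == 0L) stop("reference database is empty")
  seqv <- if (is.character(asv)) asv else asv$sequence
  asv_id <- if (is.character(asv)) fnv1a32(asv) else asv$id
  ids <- vapply(ref_records, `[[`, "", "id")
  identities <- glocal_identity(seqv, vapply(ref_records, `[[`, "", "sequence"))
  best <- max(identities)
  tied <- which(identities == best)
  tied <- tied[order(ids[tied])]
  lineage <-
    if (best < min_identity) structure(character(), class = "lineage")
    else if (length(tied) == 1L) ref_lineages[[tied]]
    else lineage_lca(ref_lineages[tied])
  list(asv_id = asv_id, lineage = lineage,
       best_hit_accession = ids[tied[1L]],
       identity = best, n_tied_hits = length(tied))
}

#' Read a taxonomy-annotated reference FASTA
#'
#' Headers are `>accession<TAB>d__...;p__...;...` (semicolon lineage with
#' rank prefixes).
#' @param path FASTA path.
#' @return A list with `records` and `lineages`.
#' @export
read_taxonomy_fasta <- function(path) {
  records <- read_fasta(path)
  lineages <- lapply(records, function(r) parse_lineage(r$description))
  list(records = records, lineages = lineages)
}

#' Write a taxonomy-annotated reference FASTA
#' @param records List of [seq_record]s.
#' @param lineages Parallel list of `lineage` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_fasta <- function(records, lineages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(c(paste0(">", records[[i]]$id, "\t", format(lineages[[i]])),
                 records[[i]]$sequence), con, sep = "\n")
  }
  invisible(path)
}

# Strip a mate suffix (/1, /2, .1, _2, ...) from a read id.
strip_mate_suffix <- function(id) sub("(/[12]|[._][12])$", "", id)

#' Run the amplicon pipeline end to end
#'
#' Quality control (sliding-window trimming, length/ambiguity filter),
#' pair merging, primer removal, dereplication, denoising, and taxonomy
#' assignment, with a per-stage read-count summary.
#'
#' @param fwd,rev Paths to paired FASTQ files (or lists of [seq_record]s).
#' @param refdb Path to a taxonomy reference FASTA, or the list returned
#'   by [read_taxonomy_fasta].
#' @param fwd_primer,rev_primer Primer sequences (IUPAC allowed).
#' @param window,min_mean_q,min_len,min_overlap,max_mismatch_frac,
#'   max_primer_mismatch,error_profile,min_count,min_identity Stage
#'   parameters; see the individual stage functions.
#' @return A list with `asvs` (data.frame id/sequence/count),
#'   `assignments` (data.frame asv_id/count/identity/lineage/n_tied_hits/
#'   best_hit_accession), and `summary` (data.frame stage/reads_in/
#'   reads_out).
#' @export
run_amplicon_pipeline <- function(fwd, rev, refdb, fwd_primer, rev_primer,
                                  window = 50L, min_mean_q = 20,
                                  min_len = 50L, min_overlap = 10L,
                                  max_mismatch_frac = 0.1,
                                  max_primer_mismatch = 2L,
                                  error_profile = default_error_profile(),
                                  min_count = 2L, min_identity = 80) {
  fwd_reads <- if (is.character(fwd)) read_fastq(fwd) else fwd
  rev_reads <- if (is.character(rev)) read_fastq(rev) else rev
  if (length(fwd_reads) != length(rev_reads))
    stop("forward and reverse files differ in read count")
  db <- if (is.character(refdb)) read_taxonomy_fasta(refdb) else refdb
  n_in <- length(fwd_reads)
  summary <- data.frame(stage = character(), reads_in = integer(),
                        reads_out = integer())
  log_stage <- function(stage, n_i, n_o) {
    summary[nrow(summary) + 1L, ] <<- list(stage, n_i, n_o)
  }
  # quality control: trim + filter each mate, keep complete pairs
  pairs <- vector("list", n_in)
  kept <- 0L
  for (i in seq_len(n_in)) {
    if (strip_mate_suffix(fwd_reads[[i]]$id) !=
        strip_mate_suffix(rev_reads[[i]]$id))
      stop("mate ids do not match at pair ", i)
    f <- sliding_window_trim(fwd_reads[[i]], window, min_mean_q)
    r <- sliding_window_trim(rev_reads[[i]], window, min_mean_q)
    if (is.null(f) || is.null(r)) next
    if (!quality_filter(f, min_len)$keep || !quality_filter(r, min_len)$keep)
      next
    kept <- kept + 1L
    pairs[[kept]] <- list(f = f, r = r)
  }
  pairs <- pairs[seq_len(kept)]
  log_stage("quality_control", n_in, kept)
  merged <- list()
  for (p in pairs) {
    m <- merge_pair(p$f, p$r, min_overlap, max_mismatch_frac)
    if (!is.null(m)) merged[[length(merged) + 1L]] <- m
  }
  log_stage("merge", kept, length(merged))
  inserts <- list()
  for (m in merged) {
    t <- trim_primers(m, fwd_primer, rev_primer, max_primer_mismatch)
    if (!is.null(t) && nzchar(t$sequence))
      inserts[[length(inserts) + 1L]] <- t
  }
  log_stage("primer_removal", length(merged), length(inserts))
  uniq <- dereplicate(vapply(inserts, `[[`, "", "sequence"))
  log_stage("dereplicate", length(inserts), nrow(uniq))
  asvs <- denoise(uniq, error_profile, min_count)
  log_stage("denoise", nrow(uniq), nrow(asvs))
  assignments <- do.call(rbind, lapply(seq_len(nrow(asvs)), function(i) {
    a <- assign_taxonomy(asvs[i, ], db$records, db$lineages, min_identity)
    data.frame(asv_id = a$asv_id, count = asvs$count[i],
               identity = a$identity,
               lineage = if (length(a$lineage)) format(a$lineage)
                         else "unclassified",
               n_tied_hits = a$n_tied_hits,
               best_hit_accession = a$best_hit_accession)
  }))
  if (is.null(assignments))
    assignments <- data.frame(asv_id = character(), count = integer(),
                              identity = numeric(), lineage = character(),
                              n_tied_hits = integer(),
                              best_hit_accession = character())
  log_stage("annotation", nrow(asvs), nrow(assignments))
  list(asvs = asvs, assignments = assignments, summary = summary)
}
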