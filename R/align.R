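#' @importFrom Biostrings pairwiseAlignment nucleotideSubstitutionMatrix
NULL

# Default scoring, mirroring the common gapped search-tool defaults:
# nucleotide match +2 / mismatch -3, gap open 5 / extend 2;
# protein BLOSUM62, gap open 11 / extend 1.
# Karlin-Altschul gapped constants for the same schemes.
ALIGN_DEFAULTS <- list(
  nucleotide = list(gap_open = 5, gap_extend = 2, K = 0.41, lambda = 0.625),
  protein    = list(gap_open = 11, gap_extend = 1, K = 0.041, lambda = 0.267)
)

.subst_matrix <- function(mode) {
  if (mode == "nucleotide") {
    Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                             baseOnly = FALSE)
  } else {
    data_env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
    data_env$BLOSUM62
  }
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * S)` with the configured gapped constants.
#' The search-space size `m * n` (query length times total database
#' residues) is supplied explicitly by the caller, so the same raw score
#' yields a calibrated e-value whatever the database size. Monotonically
#' decreasing in the score for fixed lengths.
#'
#' @param score Raw alignment score.
#' @param search_space `m * n`, query length times total subject residues.
#' @param mode `"nucleotide"` or `"protein"` (selects `K` and `lambda`).
#' @param K,lambda Override the packaged constants.
#' @return The expectation value (vectorized over `score`).
#' @export
karlin_altschul_evalue <- function(score, search_space,
                                   mode = c("nucleotide", "protein"),
                                   K = NULL, lambda = NULL) {
  mode <- match.arg(mode)
  if (is.null(K)) K <- ALIGN_DEFAULTS[[mode]]$K
  if (is.null(lambda)) lambda <- ALIGN_DEFAULTS[[mode]]$lambda
  K * search_space * exp(-lambda * score)
}

.as_string <- function(x) {
  if (inherits(x, "seq_record")) x$sequence else toupper(as.character(x))
}
.rec_id <- function(x, default) if (inherits(x, "seq_record")) x$id else default

# Vectorized elementwise alignment of parallel pattern/subject vectors.
# Returns a data.frame(score, identity, query_cover, evalue, q_start, q_end,
# s_start, s_end) with one row per pair; coordinates 0-based half-open.
align_pairs <- function(patterns, subjects, mode = "nucleotide",
                        type = "local", search_space = NULL) {
  mat <- .subst_matrix(mode)
  pars <- ALIGN_DEFAULTS[[mode]]
  set_cls <- if (mode == "nucleotide") Biostrings::DNAStringSet else Biostrings::AAStringSet
  aln <- Biostrings::pairwiseAlignment(set_cls(patterns), set_cls(subjects),
                                       type = type,
                                       substitutionMatrix = mat,
                                       gapOpening = pars$gap_open,
                                       gapExtension = pars$gap_extend)
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  cols <- nchar(as.character(p))                 # alignment columns incl. gaps
  matches <- Biostrings::nmatch(aln)
  qlen <- nchar(patterns)
  q_start <- Biostrings::start(p); q_end <- Biostrings::end(p)
  identity <- ifelse(cols > 0, 100 * matches / cols, 0)
  cover <- (q_end - q_start + 1) / qlen
  if (is.null(search_space))
    search_space <- qlen * sum(nchar(unique(subjects)))
  data.frame(score = Biostrings::score(aln),
             identity = identity,
             query_cover = cover,
             evalue = karlin_altschul_evalue(Biostrings::score(aln),
                                             search_space, mode),
             q_start = q_start - 1L, q_end = q_end,
             s_start = Biostrings::start(s) - 1L, s_end = Biostrings::end(s))
}

# One query against many subjects.
align_one_vs_many <- function(query, subjects, mode = "nucleotide",
                              type = "local", search_space = NULL) {
  if (is.null(search_space)) search_space <- nchar(query) * sum(nchar(subjects))
  align_pairs(rep(query, length(subjects)), subjects, mode = mode,
              type = type, search_space = search_space)
}

#' Optimal local alignment (Smith-Waterman)
#'
#' Affine-gap Smith-Waterman between two sequences, with percent identity
#' and query coverage computed from the traceback and an expectation value
#' from [karlin_altschul_evalue]. Coordinates in the result are 0-based
#' half-open; user-facing report writers add 1 to starts.
#'
#' @param query,subject [seq_record] objects or plain character sequences;
#'   both non-empty and of the same alphabet class.
#' @param mode `"nucleotide"` (match +2 / mismatch -3, gap 5/2) or
#'   `"protein"` (BLOSUM62, gap 11/1).
#' @param search_space Explicit `m * n` for the e-value; defaults to
#'   `nchar(query) * nchar(subject)`.
#' @return A list of class `alignment_result` with fields `score`,
#'   `identity` (0-100), `query_cover` (0-1), `evalue`, `query_id`,
#'   `subject_id`, and `coordinates` (`q_start`, `q_end`, `s_start`,
#'   `s_end`; 0-based half-open).
#' @export
local_align <- function(query, subject, mode = c("nucleotide", "protein"),
                        search_space = NULL) {
  mode <- match.arg(mode)
  q <- .as_string(query); s <- .as_string(subject)
  if (!nzchar(q) || !nzchar(s)) stop("empty sequence in local_align")
  df <- align_one_vs_many(q, s, mode = mode, search_space = search_space)
  structure(list(score = df$score, identity = df$identity,
                 query_cover = df$query_cover, evalue = df$evalue,
                 query_id = .rec_id(query, "query"),
                 subject_id = .rec_id(subject, "subject"),
                 coordinates = list(q_start = df$q_start, q_end = df$q_end,
                                    s_start = df$s_start, s_end = df$s_end)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "alignment %s vs %s: score %.1f, identity %.1f%%, cover %.2f, E = %.3g\n",
    x$query_id, x$subject_id, x$score, x$identity, x$query_cover, x$evalue))
  cat(sprintf("  query %d-%d, subject %d-%d (1-based inclusive)\n",
              x$coordinates$q_start + 1L, x$coordinates$q_end,
              x$coordinates$s_start + 1L, x$coordinates$s_end))
  invisible(x)
}

#' Global (end-to-end) percent identity
#'
#' Needleman-Wunsch alignment of two nucleotide sequences under the
#' default nucleotide scoring; identity is
#' `matches / alignment columns * 100` where columns include gap columns.
#'
#' @param a,b Non-empty nucleotide sequences (or [seq_record]s).
#' @return Percent identity in `[0, 100]`.
#' @export
global_identity <- function(a, b) {
  a <- .as_string(a); b <- .as_string(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence in global_identity")
  df <- align_one_vs_many(a, b, mode = "nucleotide", type = "global")
  df$identity
}

# Query-global / subject-local percent identity: the query is aligned
# end-to-end against its best-matching window of the subject. Used for
# taxonomy assignment, where ASVs are sub-regions of full-length
# reference records.
glocal_identity <- function(query, subjects) {
  df <- align_one_vs_many(query, subjects, mode = "nucleotide",
                          type = "global-local")
  df$identity
}

# --- exact-seed anchoring -------------------------------------------------

# Positions (1-based) of all k-mers of `seq`; returns data.table(kmer, pos).
kmer_table <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(data.table::data.table(kmer = character(), pos = integer()))
  pos <- seq_len(L - k + 1L)
  data.table::data.table(kmer = substring(seq, pos, pos + k - 1L), pos = pos)
}

# Locate the window of `subject` that a (near-)copy of `query` occupies,
# by exact k-mer seeds on the given strand only. Returns c(start, end)
# (1-based inclusive, padded) or NULL when no seed matches.
anchor_window <- function(query, subject_index, subject_len, k = 15L,
                          stride = 8L, pad = 60L) {
  qlen <- nchar(query)
  if (qlen < k) return(NULL)
  qpos <- unique(c(seq(1L, qlen - k + 1L, by = stride), qlen - k + 1L))
  seeds <- data.table::data.table(kmer = substring(query, qpos, qpos + k - 1L),
                                  qpos = qpos)
  hits <- subject_index[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(NULL)
  diag <- hits$pos - hits$qpos          # offset of query start - 1 on subject
  d <- as.integer(names(sort(table(diag), decreasing = TRUE))[1L])
  start <- max(1L, d + 1L - pad)
  end <- min(subject_len, d + qlen + pad)
  c(start, end)
}
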