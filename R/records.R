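#' Sequence records
#'
#' A `seq_record` is the package's unit of sequence data: a named sequence
#' with an optional free-text description and optional per-base Phred
#' quality scores. It is a plain list with class `"seq_record"` so that
#' pipeline code can build and inspect records without any heavyweight
#' container; conversion helpers to/from Biostrings objects are internal.
#'
#' @param id Record identifier; a non-empty token without whitespace.
#' @param sequence Character scalar over the nucleotide alphabet (including
#'   IUPAC ambiguity codes, used for primers) or the amino-acid alphabet.
#' @param description Free-text description (may be empty).
#' @param qualities Optional integer vector of Phred scores, one per base,
#'   each in \code{[0, 93]}.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, sequence, description = "", qualities = NULL) {
  if (length(id) != 1L || is.na(id) || !nzchar(id) || grepl("[[:space:]]", id))
    stop("record id must be a non-empty token without whitespace")
  sequence <- toupper(as.character(sequence))
  if (!is.null(qualities)) {
    qualities <- as.integer(qualities)
    if (length(qualities) != nchar(sequence))
      stop(sprintf("record '%s': %d quality scores for %d bases",
                   id, length(qualities), nchar(sequence)))
    if (any(qualities < 0L | qualities > 93L))
      stop(sprintf("record '%s': Phred scores must lie in [0, 93]", id))
  }
  structure(list(id = id, description = as.character(description),
                 sequence = sequence, qualities = qualities),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  s <- x$sequence
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(sprintf("seq_record %s [%d %s]%s\n  %s\n", x$id, nchar(x$sequence),
              if (is.null(x$qualities)) "bases" else "bases+qual",
              if (nzchar(x$description)) paste0(" ", x$description) else "",
              s))
  invisible(x)
}

# Split a FASTA/FASTQ header into id (first token) and description (rest).
split_header <- function(h) {
  id <- sub("[ \t].*$", "", h)
  desc <- if (nchar(h) > nchar(id)) sub("^[ \t]+", "", substr(h, nchar(id) + 1L, nchar(h))) else ""
  list(id = id, description = desc)
}

#' Read a FASTA file
#'
#' Reads all records from a FASTA file. Sequences wrapped over several
#' lines are concatenated and uppercased; record order is preserved. The
#' header's first whitespace-delimited token becomes the record id and the
#' remainder its description (taxonomy reference files put a tab-separated
#' lineage string there).
#'
#' @param path Path to an existing FASTA file.
#' @return A list of [seq_record] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("no records in ", path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  lapply(seq_along(set), function(i) {
    h <- split_header(headers[[i]])
    seq_record(h$id, seqs[[i]], h$description)
  })
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to a 4-line-per-record FASTQ file with Phred+33
#'   quality encoding; qualities decode as `ord(char) - 33`.
#' @return A list of [seq_record] objects with qualities attached.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) stop("no records in ", path)
  if (n %% 4L != 0L) stop("FASTQ file is not made of 4-line records: ", path)
  idx <- seq(1L, n, by = 4L)
  lapply(idx, function(i) {
    h <- lines[[i]]
    if (!startsWith(h, "@")) stop("malformed FASTQ header at line ", i)
    h <- split_header(substring(h, 2L))
    seq <- toupper(lines[[i + 1L]])
    qual <- lines[[i + 3L]]
    if (nchar(qual) != nchar(seq))
      stop(sprintf("record '%s': quality string length %d != sequence length %d",
                   h$id, nchar(qual), nchar(seq)))
    seq_record(h$id, seq, h$description,
               qualities = as.integer(utf8ToInt(qual)) - 33L)
  })
}

#' Write sequence records to FASTA or FASTQ
#'
#' Byte-deterministic for fixed input: FASTA is wrapped at 80 columns,
#' FASTQ is unwrapped. FASTQ output requires qualities on every record.
#' An empty record list yields an empty file.
#'
#' @param records List of [seq_record] objects.
#' @param path Output file path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    if (format == "fasta") {
      wrapped <- substring(r$sequence,
                           seq(1L, max(nchar(r$sequence), 1L), by = 80L),
                           pmin(seq(80L, max(nchar(r$sequence), 1L) + 79L, by = 80L),
                                nchar(r$sequence)))
      writeLines(c(paste0(">", header), wrapped), con, sep = "\n")
    } else {
      if (is.null(r$qualities))
        stop("fastq output requires qualities on every record (missing on '",
             r$id, "')")
      writeLines(c(paste0("@", header), r$sequence, "+",
                   intToUtf8(r$qualities + 33L)), con, sep = "\n")
    }
  }
  invisible(path)
}

# IUPAC nucleotide complement table (uppercase).
IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", V = "B", D = "H", H = "D", N = "N")

# IUPAC code -> set of concrete bases it denotes.
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

#' Reverse complement (IUPAC-aware)
#'
#' Complements every base, including ambiguity codes (R<->Y, K<->M, ...),
#' and reverses the sequence. An involution: `reverse_complement(
#' reverse_complement(s)) == s`.
#'
#' @param sequence Nucleotide character scalar (IUPAC codes allowed).
#' @return The reverse-complemented sequence.
#' @export
reverse_complement <- function(sequence) {
  sequence <- toupper(sequence)
  if (grepl(sprintf("[^%s]", paste(names(IUPAC_COMPLEMENT), collapse = "")),
            sequence))
    stop("non-IUPAC character in sequence")
  comp <- chartr("ACGTURYSWKMBVDHN", "TGCAAYRSWMKVBHDN", sequence)
  # reverse by bytes (sequences are ASCII)
  intToUtf8(rev(utf8ToInt(comp)))
}

# Does concrete base `b` satisfy IUPAC code `code`?  Vectorized over both.
iupac_matches <- function(code, b) {
  mapply(function(cd, bb) bb %in% IUPAC_SETS[[cd]], code, b, USE.NAMES = FALSE)
}
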