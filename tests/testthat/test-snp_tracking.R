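planted_pair <- function(len = 20000, n_snps = 25, spacing = 31,
                         seed = 61) {
  g <- random_genome(len, seed = seed, id = "A")
  mut <- mutate_genome(g, n_snps / len, seed = seed + 1,
                       min_spacing = spacing)
  list(a = g, b = mut$record, positions = mut$positions)
}

test_that("identical genomes yield no SNP loci and even k errors out", {
  g <- random_genome(5000, seed = 62)
  expect_length(discover_snps(list(A = g, B = g))$contexts, 0)
  expect_error(discover_snps(list(A = g, B = g), k = 20), "odd")
  expect_error(discover_snps(list(A = g)), "at least 2")
})

test_that("isolated planted substitutions are recovered exactly for several k", {
  fix <- planted_pair()
  for (k in c(15L, 19L, 25L)) {
    loci <- discover_snps(list(A = fix$a, B = fix$b), k = k)
    expect_length(loci$contexts, 25)
    anchored <- map_to_reference(loci, fix$a)
    expect_setequal(anchored$ref_position, fix$positions)
  }
})

test_that("discovery is invariant under reverse-complementing an input genome", {
  fix <- planted_pair(len = 8000, n_snps = 10, seed = 63)
  loci <- discover_snps(list(A = fix$a, B = fix$b))
  loci_rc <- discover_snps(list(
    A = fix$a,
    B = seq_record("B", reverse_complement(fix$b$sequence))))
  expect_equal(loci$contexts, loci_rc$contexts)
  expect_equal(loci$alleles, loci_rc$alleles)
})

test_that("adjacent substitutions closer than the flank are not recovered", {
  set.seed(64)
  g <- random_genome(4000, seed = 64)
  s <- g$sequence
  k <- 19L
  bases <- c("A", "C", "G", "T")
  for (p in c(2000L, 2005L)) {     # within (k-1)/2 of each other
    substr(s, p, p) <- setdiff(bases, substr(s, p, p))[1]
  }
  loci <- discover_snps(list(A = g, B = seq_record("B", s)), k = k)
  anchored <- map_to_reference(loci, g)
  expect_false(any(anchored$ref_position %in% c(2000L, 2005L)))
})

test_that("reference anchoring keeps unique contexts only and records REF", {
  fix <- planted_pair(len = 6000, n_snps = 8, seed = 65)
  loci <- discover_snps(list(A = fix$a, B = fix$b))
  anchored <- map_to_reference(loci, fix$a)
  expect_setequal(anchored$ref_position, fix$positions)
  expect_true("REF" %in% anchored$genome_ids)
  # REF alleles equal genome A's alleles (the reference is genome A)
  ai <- match("A", anchored$genome_ids)
  ri <- match("REF", anchored$genome_ids)
  expect_equal(anchored$alleles[, ai], anchored$alleles[, ri])
  # a context absent from the reference is dropped
  other <- random_genome(6000, seed = 66, id = "other")
  expect_length(map_to_reference(loci, other)$contexts, 0)
  # reference-mode loci are a subset of reference-free loci
  expect_true(all(anchored$contexts %in% loci$contexts))
})

test_that("a duplicated context in the reference is dropped as ambiguous", {
  set.seed(67)
  core <- random_dna(19)
  flank_l <- random_dna(60); flank_r <- random_dna(60)
  g_a <- seq_record("A", paste0(flank_l, core, flank_r))
  alt <- core
  substr(alt, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(core, 10, 10))[1]
  g_b <- seq_record("B", paste0(flank_l, alt, flank_r))
  loci <- discover_snps(list(A = g_a, B = g_b), k = 19)
  expect_length(loci$contexts, 1)
  # context unique in the reference: anchored at the variant position
  expect_equal(map_to_reference(loci, g_a)$ref_position, 70L)
  # same context planted twice: ambiguous, locus dropped
  dup <- seq_record("R", paste0(flank_l, core, random_dna(30), core,
                                flank_r))
  expect_length(map_to_reference(loci, dup)$contexts, 0)
})

test_that("the SNP matrix marks absences and supports core filtering", {
  fix <- planted_pair(len = 6000, n_snps = 6, seed = 68)
  third <- mutate_genome(fix$a, 4 / 6000, seed = 70,
                         min_spacing = 31)$record
  loci <- discover_snps(list(A = fix$a, B = fix$b, C = third))
  m <- build_snp_matrix(loci)
  expect_equal(sort(m$genome_ids), c("A", "B", "C"))
  expect_true(all(nchar(m$calls) == length(m$contexts)))
  core <- build_snp_matrix(loci, core_only = TRUE)
  expect_lte(length(core$contexts), length(m$contexts))
  expect_false(any(grepl("-", core$calls, fixed = TRUE)))
})

test_that("pairwise p-distances count differing shared positions", {
  m <- structure(list(genome_ids = c("A", "B", "C"),
                      contexts = paste0("ctx", 1:10),
                      ref_position = rep(NA_integer_, 10),
                      calls = c(A = "AAAAAAAAAA",
                                B = "AAAATTTTAA",
                                C = "AAAAAAAA--")),
                 class = "snp_matrix")
  d <- pairwise_distances(m)
  expect_equal(d["A", "B"], 0.4)
  expect_equal(d["A", "C"], 0)
  expect_equal(d["B", "C"], 4 / 8)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 3))

  # brute-force recount on random matrices
  set.seed(71)
  for (trial in 1:20) {
    n <- sample(3:6, 1); L <- sample(5:30, 1)
    calls <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T", "-"), L, replace = TRUE,
                   prob = c(rep(0.22, 4), 0.12)), collapse = ""), "")
    ids <- paste0("g", seq_len(n))
    mm <- structure(list(genome_ids = ids, contexts = paste0("c", 1:L),
                         ref_position = rep(NA_integer_, L),
                         calls = setNames(calls, ids)),
                    class = "snp_matrix")
    d <- pairwise_distances(mm)
    ch <- do.call(rbind, strsplit(calls, ""))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      both <- ch[i, ] != "-" & ch[j, ] != "-"
      want <- if (sum(both) == 0) 0 else
        sum(ch[i, both] != ch[j, both]) / sum(both)
      expect_equal(d[i, j], want)
    }
  }
})

test_that("neighbor joining recovers known topologies deterministically", {
  # additive 4-taxon matrix for ((A,B),(C,D))
  d <- matrix(c(0, 2, 6, 6,
                2, 0, 6, 6,
                6, 6, 0, 2,
                6, 6, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  t <- nj_tree(d)
  expect_s3_class(t$tree, "phylo")
  pairs <- ape::cophenetic.phylo(t$tree)
  expect_lt(pairs["A", "B"], pairs["A", "C"])
  expect_lt(pairs["C", "D"], pairs["B", "C"])
  expect_equal(sort(t$tree$tip.label), c("A", "B", "C", "D"))

  # equidistant 3 taxa: all terminal branch lengths equal
  d3 <- matrix(1, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(d3) <- 0
  t3 <- nj_tree(d3)
  expect_equal(length(unique(round(t3$tree$edge.length, 10))), 1L)
  expect_true(all(t3$tree$edge.length >= 0))

  # 2 taxa: single edge; 1 taxon: error
  t2 <- nj_tree(matrix(c(0, 0.3, 0.3, 0), 2, 2,
                       dimnames = list(c("p", "q"), c("p", "q"))))
  expect_match(t2$newick, "p")
  expect_error(nj_tree(matrix(0, 1, 1, dimnames = list("a", "a"))),
               "at least 2")

  # newick parses round-trip
  back <- ape::read.tree(text = t$newick)
  expect_setequal(back$tip.label, c("A", "B", "C", "D"))
})

test_that("a nested mutation ladder produces a ladder topology", {
  a <- random_genome(8000, seed = 72, id = "A")
  b <- mutate_genome(a, 10 / 8000, seed = 73, min_spacing = 31)$record
  c_ <- mutate_genome(b, 10 / 8000, seed = 74, min_spacing = 31)$record
  d_ <- mutate_genome(c_, 10 / 8000, seed = 75, min_spacing = 31)$record
  b$id <- "B"; c_$id <- "C"; d_$id <- "D"
  loci <- discover_snps(list(A = a, B = b, C = c_, D = d_))
  m <- build_snp_matrix(loci)
  t <- nj_tree(pairwise_distances(m))
  coph <- ape::cophenetic.phylo(t$tree)
  expect_lt(coph["A", "B"], coph["A", "C"])
  expect_lt(coph["A", "C"], coph["A", "D"])
  expect_lt(coph["C", "D"], coph["B", "D"])
})

test_that("matrix writers emit TSV and relaxed PHYLIP", {
  fix <- planted_pair(len = 5000, n_snps = 5, seed = 76)
  loci <- discover_snps(list(A = fix$a, B = fix$b))
  m <- build_snp_matrix(loci)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  phy <- withr::local_tempfile(fileext = ".phy")
  write_snp_matrix(m, tsv, phy)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), length(m$contexts))
  lines <- readLines(phy)
  expect_equal(lines[1], sprintf("2 %d", length(m$contexts)))
  expect_length(lines, 3)
})
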