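# stop-dense spacer with no start codons on either strand
SPACER <- strrep("TTAATTAGTTAGCTAACTAATAG", 3)

test_that("ORF finding reports maximal start-to-stop frames on both strands", {
  set.seed(51)
  orf <- paste0("ATG", paste(sample(setdiff(
    as.vector(outer(as.vector(outer(c("A","C","G","T"), c("A","C","G","T"),
                                    paste0)), c("A","C","G","T"), paste0)),
    c("TAA", "TAG", "TGA")), 99, replace = TRUE), collapse = ""), "TAA")
  contig <- seq_record("c1", paste0(SPACER, orf, SPACER))
  got <- find_orfs(contig, min_aa = 60)
  plus <- got[got$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, nchar(SPACER))
  expect_equal(plus$end, nchar(SPACER) + nchar(orf))
  expect_equal((plus$end - plus$start) %% 3, 0)
  expect_equal(nchar(plus$aa), (plus$end - plus$start) / 3 - 1)

  # same ORF on the minus strand: forward-axis coordinates
  contig2 <- seq_record("c1", paste0(SPACER, reverse_complement(orf), SPACER))
  got2 <- find_orfs(contig2, min_aa = 60)
  minus <- got2[got2$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$start, nchar(SPACER))
  expect_equal(minus$end, nchar(SPACER) + nchar(orf))
  expect_equal(minus$aa, plus$aa)

  expect_equal(nrow(find_orfs(list(), min_aa = 60)), 0L)
})

test_that("twenty planted ORFs are recovered exactly", {
  # genes built from TTA/CTA codons: their shifted frames contain no
  # start codons and their reverse complements are stop codons, so the
  # only ORFs in the genome are the planted ones
  set.seed(52)
  orfs <- vapply(1:20, function(i)
    paste0("ATG", paste(sample(c("TTA", "CTA"), 80, replace = TRUE),
                        collapse = ""), "TAA"), "")
  genome <- seq_record("g", paste0(SPACER,
                                   paste(orfs, collapse = SPACER), SPACER))
  got <- find_orfs(genome, min_aa = 60)
  expect_equal(nrow(got), 20L)
  expect_true(all(got$strand == "+"))
  lens <- nchar(orfs)
  want_start <- nchar(SPACER) + c(0, cumsum(lens[-20] + nchar(SPACER)))
  expect_equal(got$start, want_start)
  expect_equal(got$end, want_start + lens)
})

test_that("housekeeping genes are detected from exemplars, even mutated", {
  db <- toy_hk_fixture()
  hk <- read_hk_db(db$hk_fasta)
  expect_equal(nrow(hk), 31 * 6)
  self <- hk[hk$strain == "strain01" & hk$species == db$species[1], ]
  proteins <- data.frame(contig_id = "x", start = 0, end = 3,
                         strand = "+", aa = self$aa)
  got <- detect_hk_genes(proteins, hk)
  expect_length(got, 31)
  expect_setequal(names(got), hk_gene_names())
  # the best hit per gene must be the protein of that gene
  for (g in names(got))
    expect_equal(got[[g]]$aa, self$aa[self$hk_gene == g])

  no_rpob <- proteins[self$hk_gene != "rpoB", ]
  got <- detect_hk_genes(no_rpob, hk)
  expect_false("rpoB" %in% names(got))
  expect_lte(length(got), 30)
})

test_that("hit ranking cuts at top_n but extends through boundary ties", {
  db <- toy_hk_fixture()
  hk <- read_hk_db(db$hk_fasta)
  q <- hk$aa[hk$hk_gene == "rpoB"][1]
  got <- rank_hits_per_gene(q, hk[hk$hk_gene == "rpoB", ][1:3, ])
  expect_equal(nrow(got), 3L)
  expect_true(all(diff(got$score) <= 0))

  # constructed tie block across the cut boundary: 12 identical entries
  # spanning rank 5 of a top_n = 5 cut -> all 12 kept
  base <- hk[hk$hk_gene == "rpoB", ][1, ]
  tied <- base[rep(1, 12), ]
  tied$species <- sprintf("Tie sp%02d", 1:12)
  strong <- hk[hk$hk_gene == "rpoB", ][1:4, ]
  strong$species <- sprintf("Strong sp%02d", 1:4)
  # make the 4 strong entries distinct-and-stronger by querying their own seq
  got <- rank_hits_per_gene(tied$aa[1], rbind(strong, tied), top_n = 5)
  expect_equal(sum(startsWith(got$species, "Tie")), 12L)

  # e-value filtering: an unrelated sequence does not qualify
  set.seed(53)
  junk <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 360,
                       replace = TRUE), collapse = "")
  got <- rank_hits_per_gene(junk, hk[1:10, ], max_evalue = 1e-5)
  expect_equal(nrow(got), 0L)
})

test_that("species voting matches an exhaustive recount and applies the threshold", {
  # boundary: 14 supporting genes excluded, 15 retained at defaults
  genes <- hk_gene_names()
  mk_hits <- function(n_genes, sp) {
    h <- lapply(genes, function(g) data.frame(species = character(),
                                              score = numeric()))
    names(h) <- genes
    for (g in genes[seq_len(n_genes)])
      h[[g]] <- data.frame(species = sp, score = 100)
    h
  }
  v14 <- vote_species(mk_hits(14, "Borderline sp"))
  expect_false("Borderline sp" %in% v14$species)
  v15 <- vote_species(mk_hits(15, "Borderline sp"))
  expect_true("Borderline sp" %in% v15$species)
  expect_equal(v15$n_hk_genes[v15$species == "Borderline sp"], 15L)

  # randomized trials against the recount oracle
  set.seed(54)
  species <- c("Alpha sp", "Beta sp", "Gamma sp")
  for (trial in 1:25) {
    hits <- lapply(genes, function(g) {
      present <- species[runif(3) < 0.7]
      data.frame(species = present,
                 score = round(runif(length(present), 50, 500)))
    })
    names(hits) <- genes
    got <- vote_species(hits, min_genes = 1)
    oracle <- vote_oracle(hits)
    expect_setequal(got$species, names(oracle))
    expect_equal(setNames(got$n_hk_genes, got$species)[names(oracle)],
                 oracle)
    expect_true(all(got$n_hk_genes <= 31))
  }
  expect_equal(nrow(vote_species(list())), 0L)
})

test_that("ANI is exactly 100 on self and undefined without homology", {
  g <- random_genome(8000, seed = 55)
  a <- compute_ani(g, g)
  expect_equal(a$ani, 100)
  expect_equal(a$fragments_used, a$fragments_total)

  g2 <- random_genome(8000, seed = 56, id = "other")
  a2 <- compute_ani(g, g2)
  expect_true(!a2$defined || a2$fragments_used <= 1)
})

test_that("genome identification ranks the true species first across trials", {
  db <- toy_hk_fixture()
  hk <- read_hk_db(db$hk_fasta)
  set.seed(57)
  wins <- 0L
  n_trials <- 20L
  for (trial in seq_len(n_trials)) {
    row <- sample.int(nrow(db$manifest), 1)
    truth <- db$manifest$species[row]
    g <- read_fasta(db$manifest$path[row])
    rate <- sample(c(0.005, 0.01, 0.02), 1)
    q <- mutate_genome(g[[1]], rate, seed = 1000 + trial)$record
    rep <- identify_genome(q, hk, db$manifest)
    if (rep$status == "ok" && nrow(rep$candidates) > 0 &&
        rep$candidates$species[1] == truth) wins <- wins + 1L
  }
  expect_equal(wins, n_trials)
})

test_that("identification of an exact database strain reports ANI 100", {
  db <- toy_hk_fixture()
  hk <- read_hk_db(db$hk_fasta)
  g <- read_fasta(db$manifest$path[1])
  rep <- identify_genome(g, hk, db$manifest)
  expect_equal(rep$status, "ok")
  expect_equal(rep$candidates$species[1], db$manifest$species[1])
  expect_equal(rep$candidates$max_ani[1], 100)
})

test_that("the per-species ANI strain cap is honored deterministically", {
  db <- toy_hk_fixture()
  hk <- read_hk_db(db$hk_fasta)
  g <- read_fasta(db$manifest$path[1])
  rep <- identify_genome(g, hk, db$manifest, max_strains = 1L)
  # with the cap at 1 only the lexicographically first strain is used
  expect_equal(rep$candidates$best_strain[
    rep$candidates$species == db$manifest$species[1]], "strain01")
})

test_that("MLST typing is exact, flags novel alleles, and detects ambiguity", {
  sch <- toy_mlst_fixture()
  g <- mlst_genome_for_profile(sch, st = 4, seed = 58)
  got <- mlst_type(g, sch)
  expect_equal(got$st, 4)

  # single-base mutation in one allele -> novel, unknown ST
  s <- g$sequence
  allele_num <- sch$profiles$loc2[sch$profiles$ST == 4]
  allele <- sch$loci$loc2[[as.character(allele_num)]]
  at <- regexpr(allele, s, fixed = TRUE)
  p <- at + 200L
  substr(s, p, p) <- if (substr(s, p, p) == "A") "C" else "A"
  got <- mlst_type(seq_record("mut", s), sch)
  expect_equal(unname(got$allele_calls[["loc2"]]), "novel")
  expect_equal(got$st, "unknown")

  # locus absent entirely -> missing
  keep <- setdiff(names(sch$loci), "loc5")
  s2 <- paste(vapply(keep, function(l)
    sch$loci[[l]][[as.character(sch$profiles[[l]][sch$profiles$ST == 4])]],
    ""), collapse = strrep("T", 50))
  got <- mlst_type(seq_record("partial", s2), sch)
  expect_equal(unname(got$allele_calls[["loc5"]]), "missing")
  expect_equal(got$st, "unknown")

  # two different alleles present -> ambiguity naming the locus
  s3 <- paste0(g$sequence, strrep("T", 30), sch$loci$loc1[["3"]],
               strrep("T", 30), sch$loci$loc1[["4"]])
  expect_error(mlst_type(seq_record("amb", s3), sch), "loc1")
})

test_that("protein annotation labels planted family members", {
  set.seed(59)
  aa_alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  families <- lapply(1:5, function(i)
    paste(sample(aa_alpha, 200, replace = TRUE), collapse = ""))
  db <- lapply(seq_along(families), function(i)
    seq_record(sprintf("fam%d", i), families[[i]],
               sprintf("family_%d", i)))
  # planted members: light mutations of family exemplars
  proteins <- do.call(rbind, lapply(1:20, function(j) {
    fam <- (j - 1) %% 5 + 1
    aa <- strsplit(families[[fam]], "")[[1]]
    idx <- sample(200, 10)
    aa[idx] <- sample(aa_alpha, 10, replace = TRUE)
    data.frame(aa = paste(aa, collapse = ""), truth = fam)
  }))
  got <- annotate_proteins(proteins, db)
  expect_equal(nrow(got$table), 20L)
  expect_equal(got$table$best_label,
               sprintf("family_%d", proteins$truth))
  empty <- annotate_proteins(proteins, list())
  expect_equal(nrow(empty$table), 0L)
})
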