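# Session-cached fixtures so expensive synthetic databases are built once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

toy_hk_fixture <- function() {
  cached_fixture("toy_hk", function()
    build_toy_hk_db(n_species = 3, n_strains_per_species = 2,
                    inter_species_divergence = 0.1, seed = 101,
                    n_codons = 120))
}

toy_refs_fixture <- function() {
  cached_fixture("toy_refs", function() make_toy_16s_refs(20, seed = 1))
}

toy_mlst_fixture <- function() {
  cached_fixture("toy_mlst", function()
    build_toy_mlst_scheme(n_loci = 7, n_alleles_per_locus = 5,
                          n_profiles = 10, seed = 7))
}

# True primer-delimited region per taxon, obtained by running the
# pipeline's own QC/merge/trim stages on one error-free read pair per
# taxon (grounded in the simulator truth, not in taxonomy assignment).
true_regions_fixture <- function(region) {
  cached_fixture(paste0("regions_", region), function() {
    refs <- toy_refs_fixture()
    sim <- simulate_amplicon_reads(refs, region, n_reads_per_taxon = 1,
                                   base_error_rate = 0, seed = 999)
    p <- region_primers(region)
    fwd <- read_fastq(sim$fwd_path)
    rev <- read_fastq(sim$rev_path)
    out <- data.frame(taxon_id = character(), genus = character(),
                      region_seq = character())
    for (i in seq_along(fwd)) {
      m <- merge_pair(fwd[[i]], rev[[i]])
      ins <- trim_primers(m, p$fwd, p$rev)
      out[nrow(out) + 1L, ] <- list(sim$truth$taxon_id[i],
                                    sim$truth$genus[i], ins$sequence)
    }
    out
  })
}
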