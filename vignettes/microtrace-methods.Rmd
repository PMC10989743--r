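---
title: "Methods and design of the microtrace pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the microtrace pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

microtrace bundles three desk-scale microbiology pipelines — amplicon-based
identification, whole-genome identification, and SNP-based source
tracking — together with a deterministic synthetic-data generator. This
vignette explains the models each pipeline implements, the parameters
that matter, the numerical choices behind them, and what the synthetic
data does and does not emulate.

## Shared sequence and alignment layer

All pipelines share one alignment layer. Local alignment is affine-gap
Smith–Waterman and global identity is affine-gap Needleman–Wunsch, both
executed by `Biostrings::pairwiseAlignment`; the scoring defaults mirror
the common gapped nucleotide search settings (match +2, mismatch −3, gap
open 5, gap extend 2) and BLOSUM62 with gap open 11 / extend 1 for
proteins. The first base of a gap costs open + extend.

Significance is expressed as a Karlin–Altschul expectation value
$E = K \cdot m \cdot n \cdot e^{-\lambda S}$ with fixed published gapped
constants (nucleotide $K = 0.41$, $\lambda = 0.625$; protein $K = 0.041$,
$\lambda = 0.267$) and an explicit search-space size $m \cdot n$ (query
length × total database residues) supplied by the caller. The pipelines
only threshold e-values (at $10^{-5}$ by default), so any calibrated
monotone transform of the score would serve equally; the constants are
documented and configurable rather than claims about any particular
search engine. Coordinates are 0-based half-open internally and 1-based
inclusive in printed reports.

Where a query must be located inside a much longer subject (ANI
fragments against a genome, MLST novel-allele location), the package
uses seed-and-extend: exact 15-mer seeds index the subject, the modal
seed diagonal selects a candidate window (±60 bases of padding), and the
full local dynamic program runs inside that window only. For homologous
sequences at the divergences these pipelines consider (≤ ~20%), seeds are
abundant and the windowed optimum equals the unrestricted one; a
fragment with no seed at all is treated as unaligned, which is also the
desired behaviour for non-homologous sequence.

## Pipeline 1 — amplicon identification

Stages, in order: quality control, pair merging, primer removal,
dereplication, denoising, taxonomy assignment. A per-stage read-count
table is the pipeline's run summary.

* **Sliding-window trimming** scans 50-base windows (step 1) and
  truncates the read at the start of the first window whose mean Phred
  quality drops below 20. Truncation at the window start is the
  conservative reading of "truncate when a window fails". Reads shorter
  than one window are kept only if their overall mean passes.
* **Filtering** drops reads shorter than 50 bases (a read of exactly 50
  is kept — "shorter than" read literally) or containing any non-ACGT
  character.
* **Merging** reverse-complements the reverse mate and scores every
  ungapped overlap of ≥ 10 bases; the placement with the most matches
  wins provided its mismatch fraction is ≤ 0.1. At agreeing overlap
  positions the merged quality is the larger of the two scores; at
  conflicts the higher-quality base wins and keeps the score
  difference (the forward base on exact ties, with quality 0).
* **Primer removal** is IUPAC-aware (a primer code matches every base it
  denotes), allows 2 mismatches per primer by default, and searches the
  forward primer only within the first `len + mismatches + 5` bases (and
  the reverse complement of the reverse primer within the same span at
  the 3′ end). Reads missing either primer are dropped and counted
  rather than passed through untrimmed.
* **Dereplication** groups exact duplicates, ordered by count then
  sequence, conserving the total read count.
* **Denoising** is greedy error-profile subtraction. Sequences are
  visited in decreasing abundance; the current sequence with remaining
  count $c$ subtracts $c \cdot p_d$ from every sequence at Hamming
  distance $d$, where $p_d$ is the per-distance error profile
  (defaults $p_1 = 0.06$, $p_2 = p_3 = 0.02$, … down to $p_{11} =
  0.0005$, the published defaults of greedy-subtraction denoisers; the
  tool named for this stage publishes no parameters in the source
  method, so the profile is configurable). Sequences whose remaining
  count falls below 2 are removed and do not subtract in their turn;
  survivors become ASVs carrying their original counts, so the total
  count never increases. Sequences are padded/trimmed to the
  abundance-weighted modal length first. ASV ids are a 32-bit FNV-1a
  content hash of the sequence, making results order-independent.
* **Taxonomy assignment** aligns each ASV end-to-end against its
  best-matching window of every reference (query-global /
  subject-local). This deliberately differs from strict end-to-end
  identity: references are full-length marker sequences while ASVs are
  primer-delimited sub-regions, and a global alignment of a 120-base
  region against an 800-base reference would be dominated by terminal
  gaps. `global_identity` remains available as the strict end-to-end
  metric. The best hit sets the lineage; exact ties that disagree are
  truncated to their lowest common ancestor; a best identity below 80%
  leaves the ASV unclassified. A k-mer prefilter is permitted as an
  optimization but is unnecessary at toy database sizes, so none is
  used — the best hit is always computed exactly.

## Pipeline 2 — whole-genome identification

The pipeline ingests assembled contigs (assembly itself is out of
scope) and proceeds in four steps.

1. **Gene prediction** is a naive ORF finder: all maximal ATG/GTG/TTG →
   stop frames of ≥ 60 codons on both strands, translated with the
   bacterial genetic code (table 11). It deliberately replaces a trained
   gene predictor; for the synthetic fixtures, where genes are planted
   ORFs, it is exact.
2. **Housekeeping-gene extraction** aligns every predicted protein
   against exemplar sets of the 31 universal single-copy genes (dnaG,
   frr, infC, nusA, pgk, pyrG, rplA–rplT, rpmA, rpoB, rpsB–rpsS, smpB,
   tsf) and keeps, per gene, the single best-scoring protein passing the
   e-value cutoff. Exemplar alignment stands in for a profile-HMM
   search; exemplars are part of the packaged database format.
3. **Voting** ranks each gene's hits by score, then identity, then
   species, cuts the list at 200 but extends it through entries tied
   with the boundary on both score and identity, then counts, per
   species, how many genes include it. Species supported by fewer than
   15 of the 31 genes are removed (the threshold is user-configurable).
   The printed e-value condition in the source method ("> 1e−5") is
   implemented as its conventional opposite, keep $E \le 10^{-5}$, since
   a lower bound on e-values is nonsensical as a significance filter.
4. **ANI confirmation** computes fragment-based average nucleotide
   identity for every surviving species against up to 1000 of its
   database genomes (lexicographic strain order, for reproducibility),
   reporting only the per-species maximum. The query is cut into
   consecutive 1020-base fragments (last partial fragment dropped), each
   aligned to the reference on both strands via seed-and-extend;
   fragments with ≥ 30% identity over ≥ 70% of their length count as
   used, and ANI is the mean identity of used fragments (flagged
   undefined when none qualify). The 1020/30%/70% triple is the
   classical fragment-ANI parameterization; ANI is directional (query
   fragments against the reference), with no symmetrization. All
   surviving species are reported, so contaminated or mixed samples
   retain every supported candidate.

**MLST** searches both strands for exact full-length allele substrings:
exactly one match gives the allele number, no exact match but a located
hit at ≥ 90% identity gives "novel", otherwise "missing"; exact matches
of two different alleles at one locus raise an ambiguity error. The
sequence type comes from the profile table only when every locus is
numeric. **Protein annotation** is best-hit labeling against any labeled
protein FASTA at the same e-value cutoff.

## Pipeline 3 — SNP source tracking

Reference-free discovery enumerates every k-mer (default $k = 19$, odd,
9–31) of every genome in canonical orientation — the lexicographic
minimum of the k-mer and its reverse complement, which complements the
central base consistently and makes discovery strand-independent. K-mers
sharing their flanking context (the $(k-1)/2$ bases each side) but
differing at the central base expose a SNP locus. A context qualifies
only if at least two distinct central alleles exist across genomes; a
genome presenting two different alleles at one context (a repeat) is
excluded from that locus only, and loci left with fewer than two alleles
are discarded. Two substitutions closer than $(k-1)/2$ bases destroy
each other's shared context and are not recovered; this is documented
behaviour, inherent to context matching.

Reference mode is context-unique anchoring: a locus is kept only when
its context occurs exactly once in the reference (both strands, via
canonical orientation), its position becomes the 1-based forward-strand
coordinate of the central base, and the reference allele joins the locus
as genome `REF`. This is a deliberate simplification of
consensus-alignment reference pipelines; reference-mode loci are by
construction a subset of reference-free loci. The default $k = 19$
balances context specificity against sensitivity at the 10–100 kb scale
of the packaged fixtures; it is a flag, as are the core-SNP policy and
the reference.

Downstream, the SNP matrix (loci in lexicographic context order, `-`
for absent contexts, optional core-only filtering) yields p-distances
(differing shared positions / shared positions; pairs sharing no
position are flagged), and neighbor joining builds the tree. NJ is the
canonical algorithm (`ape::nj`) with taxa presented in sorted name order
for deterministic tie-breaking; negative branch lengths are clamped to
zero with the excess moved to the sister branch. Maximum-likelihood
trees are out of scope; the Newick output feeds external ML tools.

## Synthetic data: what it emulates, what it does not

Generators take explicit seeds, restore the caller's RNG state, and
return machine-readable ground truth next to the data.

* `random_genome` / `mutate_genome`: i.i.d. bases with controlled GC;
  independent substitutions at a given rate, or — with `min_spacing` —
  exactly $\lceil \text{rate} \cdot L \rceil$ substitutions placed at
  least that far apart, so the returned positions are exact SNP truth.
* `make_toy_16s_refs` builds synthetic marker sequences that carry the
  real published primer sites (341F/805R, 515F/806R, 515F/926R,
  including the overlap of the 805R and 806R sites on the forward
  strand) around random inter-primer regions of roughly 90–130 bases.
  The regions are deliberately shorter than the biological 250–430 base
  regions: with 50 read pairs per taxon at 1% per-base error, the
  expected number of error-free merged copies per taxon stays in the
  double digits, so denoising retains every taxon's true sequence at
  desk scale. The references are synthetic throughout — no public
  database records are copied — which keeps the package license-clean
  and download-free.
* `simulate_amplicon_reads` extracts the primer-delimited region,
  synthesizes overlapping pairs with primers attached, applies
  independent per-base substitution errors, and assigns qualities as
  constant Q38 decaying linearly to Q20 over the final 20% of the read —
  simple, but sufficient to exercise the Q20/50-base trimmer. Errors are
  independent of the quality track; instrument-specific error profiles,
  chimeras and indel errors are not modeled.
* `build_toy_hk_db` plants frame-preserving diverged copies of 31
  ancestral ORFs (start/stop untouched, substitutions re-drawn if they
  would create an in-frame stop) into random backgrounds, one genome per
  strain, every fifth gene on the minus strand.
* `build_toy_mlst_scheme` emits per-locus allele FASTAs (alleles
  pairwise ≥ 2 mismatches apart), a profile table, and genomes realizing
  any chosen profile row.

Because inter-taxon regions are random sequence, taxonomy assignment on
the fixtures is an easier problem than on real amplicons, where related
genera differ at a handful of positions; passing the end-to-end checks
demonstrates the plumbing and the assignment logic, not the resolution
limits of short amplicons on real taxa. Similarly, toy housekeeping
databases with three species cannot probe the discrimination limits of
the 15-gene vote threshold at real database scale.

## Problem sizes and determinism

The packaged checks run at deliberate desk scale: 100 kb genomes for ANI
rate recovery (5 seeds per rate), 20 kb genomes with 25 planted
substitutions for SNP recovery, 20 taxa × 50 read pairs per amplicon
region, 50 random additive trees of 4–8 taxa for NJ, and 500 randomized
reads for the trimmer oracle. Every stochastic step is seeded; the
command-line layer echoes its effective configuration and rewrites
byte-identical outputs for identical inputs, config and seed.

## Known limitations

* The e-value calibration is a documented stand-in, not a fitted model
  of any particular search tool; only its monotonicity and rough scale
  matter to the pipelines.
* The ORF finder has no model of translation initiation context and
  will happily report every qualifying frame, including nested
  out-of-frame ORFs within real genes.
* Fragment ANI by seed-and-extend can miss homologous fragments whose
  every 15-mer is disrupted at very high divergence (~> 25%); such
  genome pairs are far outside the species boundary the statistic is
  used to test.
* SNP discovery cannot separate paralogous repeats from SNPs; it drops
  conflicted loci instead.
* Base-call (BCL) input is unsupported; convert to FASTQ upstream.
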