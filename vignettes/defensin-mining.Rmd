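---
title: "Mining beta-defensin gene families: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining beta-defensin gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defmine)
```

## The problem

Beta-defensins are small cationic antimicrobial peptides found across
vertebrates. Family members are highly divergent at the sequence level, but
two structural signatures are strongly conserved: a six-cysteine motif with
fixed spacing in the mature peptide, written

    C-X6-C-X4-C-X9-C-X6-C-C

(six cysteines separated by exactly 6, 4, 9, 6 and 0 intervening residues,
a 31-residue span), and a two-exon gene architecture in which exon 1
encodes the signal/leader domain and exon 2 the mature peptide. Because
profile-based gene finders under-represent the family's diversity, a
productive mining strategy is homology search with permissive thresholds,
followed by motif-constrained ORF validation, cDNA-guided exon-intron
determination under the GT-AG splice rule, phylogeny-based ortholog naming,
synteny comparison across species, and population-level characterization of
coding SNPs in the mature-peptide exon. `defmine` implements that whole
chain as composable, tibble-centric functions, together with a seeded
synthetic-data generator so every stage can be validated against known
ground truth without any external downloads.

## Discovery model

`find_candidate_orfs()` translates contigs in all six frames, extracts
maximal stop-free stretches, and keeps ORFs of at least `min_orf_aa`
residues (default 30 — comfortably below the ~38-residue mature domain but
above background ORF noise) whose translation contains the six-cysteine
motif. `scan_six_cys_motif()` reports all, possibly overlapping, matches;
spacing is a parameter (a list of five min/max pairs) with the canonical
fixed spacing as default. Ambiguous bases translate to `X`, and `X` never
satisfies a cysteine anchor — a conservative choice that can only cost
sensitivity, never specificity.

`homology_screen()` aligns a candidate against each reference cDNA with a
local affine-gap alignment (match 2, mismatch −2, gap open 5, extend 2).
Since the source analysis did not define how identity and coverage were
computed, we declare the convention explicitly so tests can be exact:

* percent identity = matching columns / aligned columns × 100, internal
  gap columns counted, terminal gap columns excluded;
* coverage = percent of the *query* included in the alignment;
* `pass` requires identity > 70 **and** coverage > 50, both strict, per
  the published wording;
* `rescued` captures the published low-coverage/high-identity manual
  inclusions (coverage ≤ 50 but identity ≥ 80; the threshold 80 is chosen
  so both printed rescue cases, 81% and 86%, qualify under a rule rather
  than ad-hoc judgment).

`build_gene_model()` determines exon-intron structure. With a guide cDNA
(the cDNA/EST-guided route), exons are co-linear exact-match blocks whose
gaps are GT..AG introns within `intron_bounds`; the boundary search
backtracks a few bases from the maximal match because an intron's first
bases can coincidentally extend the exon match. Without a guide, donor/
acceptor (GT/AG) pairs within bounds are enumerated and the junction set
maximizing the ATG-initiated, motif-containing ORF is chosen — by
construction this honors the GT-AG rule but, in random sequence, may
prefer a longer spurious ORF over a planted one; guided mode is therefore
the default route whenever a cDNA is available, matching practice.
Intron bounds default to 60–10,000 bp: no figure was published, so the
bounds are set generously around typical mammalian defensin introns and
are configurable. Models are classified `intact` (full exon set, no
internal stop, motif present), `three_exon` (the variant with an extra
intron in exon 2, as in the 105-orthologs), `partial_psi` (exon 1 absent —
the pseudogene/partial class), or `rejected` with a recorded reason.

Coordinates are 1-based inclusive on the forward strand (GFF3 convention)
everywhere; motif offsets are 0-based within peptides. This is declared
once to avoid off-by-one drift between modules.

## Phylogeny and naming

Prepropeptides are aligned pairwise with Needleman-Wunsch under the Gonnet
(1992) matrix with gap open 7 and extension 0.2 — the ClustalW-style
parameterization used for this family. A full progressive multiple aligner
is deliberately not re-implemented: distance and consensus machinery only
need pairwise alignments or a pre-made multiple alignment, and the
contribution here is not the aligner.

Distances are maximum-likelihood estimates under the JTT model:
`jtt_distance()` builds the normalized rate matrix from the published JTT
exchangeabilities and frequencies, computes P(t) by symmetric
eigendecomposition, and maximizes the likelihood of the ungapped columns
by bracketed one-dimensional search on [1e-8, 5], capping at 5
substitutions/site ("JTT matrix-based" is otherwise underspecified, so the
estimator is pinned down this way and verified against a dense grid search
and an independent implementation in tests).

`nj_tree()` is a standard neighbor-joining agglomeration with two pinned
details: Q-criterion ties break at the lowest (row, column) index pair for
determinism, and negative branch estimates are clamped to zero with the
deficit transferred to the sibling branch so the joined pair's path length
is preserved. `bootstrap_consensus()` resamples alignment columns
(default 1,000 replicates), builds an NJ tree per replicate, and returns
the majority-rule consensus with percent supports; branches under the
collapse threshold (default 50%) become polytomies. Taxa are ordered
canonically before resampling, making supports invariant to input order;
the seed is an explicit argument (default 42).

`assign_ortholog_name()` names a candidate `pBD<n>` after the nearest
human reference `DEFB<n>` by percent identity, cross-checked against clade
membership in the bootstrap tree when one is supplied. Two safeguards
mirror how such namings are adjudicated: a legacy table keeps the
established names of pBD1–4 (whose nearest human references are DEFB4, -1,
-103 and -110) because renaming well-studied genes would cause confusion,
and candidates whose top two references lie within 0.5 identity points are
flagged ambiguous rather than named silently — the historical cases were
decided manually, and flagging is safer than guessing.

## Synteny comparison

`build_clusters()` groups genes per chromosome into runs separated by more
than `max_gap` (default 2 Mb — defensin clusters are sub-megabase, so the
default is permissive) and labels each cluster by its flanking anchor
markers where an anchor pair brackets it. The anchor fixture stores both
printed upstream candidates for the SSC17 cluster (ZCCHC3 and TRIB3) and
accepts either; the SSC14 cluster is bounded by its own defensin genes, as
published. Genes without a chromosome assignment (pBD3, whose inferred
position is SSC15 via its human orthologs; and pBD108/pBD125, which appear
in the 29-gene catalog but in none of the printed cluster lists) are
reported as `unplaced` with a note, never silently placed — this is why
the pig fixture yields exactly the printed cluster memberships
(5 + 3 + 6 + 12).

`match_orthologs_across_species()` matches genes by number after stripping
species prefixes (DEFB/BBD/pBD), dropping duplication suffixes (103A →
103) and mapping pig legacy names through the naming table.
`compare_cluster_architecture()` then emits `conserved` (same shared genes,
same order — whole-cluster reversal counts as conserved since it is a
strand flip), `order_change`, `split` (one cluster's orthologs spread over
two or more clusters in the other species, e.g. the human chromosome 8
cluster split across SSC15 and SSC14), `duplication`, and `unplaced`
events.

## Variants, RFLP and in-silico PCR

`call_snps()` compares per-animal exon-2 amplicon sequences to a reference
column by column. Heterozygotes are represented as IUPAC ambiguity codes
in the input (two alleles observed per animal — direct Sanger sequencing
of a genomic PCR product), and each animal contributes two chromosomes per
column. Only biallelic columns become records; columns with three or more
alleles are flagged and excluded, since the analysis this emulates reports
biallelic SNPs only.

`annotate_consequence()` works at frame offset 0 — position 1 of exon 2 is
the first base of a codon. The offset is never stated in the source
tables, but it is the unique offset consistent with every published row
(position 65 at codon position 2 giving R/K; 144 giving Q/H at a third
position; every synonymous row at a position divisible by 3); the fixture
test asserts this consistency. Position p lies in codon ⌈p/3⌉ at codon
position ((p−1) mod 3)+1; the reference and alternate codons are
translated and compared. Because `major`/`minor` are frequency-ranked, the
codon swap is oriented by the reference base (a SNP near MAF 0.5 can
realize its reference allele as the sample minor).

`estimate_maf()` folds the frequency at 0.5 and counts only non-missing
chromosomes. `design_rflp_assay()` scans every recognition-site window
overlapping the SNP in both allele sequences with IUPAC-expanded matching
and reports an enzyme when the allele site patterns differ — equivalent to
a brute-force double digest, which the test suite verifies directly. (A
rule that demanded a site in exactly one allele would miss the corner case
where both alleles gain sites at different positions yet digestion still
distinguishes them; the pattern rule subsumes it.) The packaged enzyme
table carries the three published assay enzymes (BstNI CCWGG, EcoRV
GATATC, PciI ACATGT) plus about twenty common 4–6 bp cutters, so no
external enzyme database is needed. `insilico_pcr()` reports every product
where the forward primer matches the plus strand and the reverse
complement of the reverse primer matches downstream;
`pcr_distinguishable()` compares genomic and spliced-template product
sizes against a 20 bp gel-resolution default.

## The synthetic-data generator

`simulate_genome()` emulates the study conditions: multi-exon defensin
loci with the six-cysteine motif in exon 2, GT..AG introns (length range
500–2,000 bp by default), signal-peptide exon 1 (ATG + 18 codons), random
strand, uniform-ACGT background rejection-sampled to be motif-free in all
six frames (the simplest null with a calculable false-positive rate and a
clean negative control). Mature-peptide spacer residues avoid cysteine so
each planted gene carries exactly one motif — asserted by running the
scanner on every planted peptide. Three-exon loci place the extra intron
in the leading flank of exon 2, emulating an insertion upstream of the
mature-domain core, so the motif stays intact within one exon; psi loci
simply lack exon 1. `simulate_population()` draws each animal's two
alleles binomially at the specified minor allele frequency;
`make_reference_panel()` applies uniform per-site substitution (a
Jukes-Cantor-style single-parameter model — sufficient for exercising
identity thresholds; realistic substitution models are out of scope) at
per-sequence divergences spanning the configured range, so the 70%
threshold is exercised from both sides. Population sizes default to the
emulated study scales: 14 discovery animals, 35 genotyped animals; the
panel can be sized to 57 to mirror the published reference count.

What the generator does *not* emulate: indels (panel divergence is
substitution-only, so coverage variation in tests comes from truncation,
not alignment gaps), sequencing error, paralogous near-duplicates within
the background, GC heterogeneity, and breed structure in the populations
(animals are exchangeable draws). Passing tests therefore demonstrate
algorithmic correctness under clean conditions, not robustness to every
artifact of real survey data.

## Reproducing the published desk-scale numbers

The genome-wide headline results (the 29-gene set from the real assembly,
the 84.38% mean ortholog identity, the full 113-taxon tree) require the
real genome and the authors' sequence set and are not desk-reproducible.
What is reproducible is encoded as plain-text fixtures: the 29-entry
catalog, the 8-row SNP table, the 17-row primer panel, the per-chromosome
gene orders with anchors, and the 57-symbol reference list (recorded
verbatim, including the duplicated DEFB132 — unique symbols sum to 56; the
discrepancy is recorded, not resolved). Reference exon-2 sequences for the
SNP genes are synthetic, constructed so every published row's codon
context is reproduced exactly (alleles, amino-acid changes, and the
differential restriction sites); they are labeled synthetic in the fixture
documentation. `scripts/acceptance.R` recomputes the fixture-level
quantities — 8 cSNPs in 7 genes, 3 nonsynonymous, 4 clusters, 6 members
between AGPAT5 and SPATA4, 12 in the largest cluster — by running the
pipeline stages from scratch.

## Numerical and scale choices

Problem sizes in the default test run are chosen to finish in minutes on
one core while still exercising every property at meaningful scale: the
planted-recovery check uses a 1 Mbp genome with 10 loci (2- and 3-exon,
both strands) and a 1 Mbp motif-free background; oracle-equivalence suites
run 10,000 random peptides against the exhaustive motif oracle, 10,000
consequence cases against a full-translation diff, and 1,000 RFLP cases
against brute-force double digestion; NJ is checked on 100 random additive
matrices of up to 8 taxa; JTT recovery uses 100 replicates of 1,000 sites
at true distance 0.3 (mean within 0.03); MAF convergence uses 10,000
diploid animals (within 0.01). The bootstrap default stays at the
published 1,000 replicates, while tests use 40–100 replicates on small
alignments where the expected supports are provable.

Known limitations: the unguided junction search is quadratic in candidate
donor/acceptor sites and restricted to single-intron models; the rescue
rule can admit short high-identity local alignments against unrelated
sequence (as any identity-threshold rule without an alignment-length or
E-value component can); and ortholog matching is purely number-based, so
it inherits any inconsistency in the underlying nomenclature.
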