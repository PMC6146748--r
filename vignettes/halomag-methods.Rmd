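---
title: "Post-binning MAG analyses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-binning MAG analyses: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halomag)
```

# Scope

`halomag` implements the analyses that sit *downstream* of metagenomic
assembly and binning for studies of hypersaline and soda-lake sediment
communities: quality tiering of metagenome-assembled genomes (MAGs),
fragment-based average nucleotide identity (ANI) with conserved-DNA species
delineation, read-recruitment abundance normalised as RPKG, a rank-based
salinity-preference score, proteome isoelectric-point (pI) profiling, and
KEGG-Orthology (KO) marker screening for pathway presence. Everything
upstream — read trimming, assembly, binning, gene prediction, and the
annotation engines themselves — is out of scope; the package consumes their
tabular and FASTA outputs.

Because the deep-sequenced sediment datasets behind such studies are far too
large for routine testing, the package carries a first-class synthetic-data
module. Its generators produce genomes, divergent genome pairs, community
read sets, proteomes and annotation tables with *known ground truth*, so
every downstream statistic can be checked against the parameters that
generated its input.

# Synthetic data: what it emulates and what it does not

`generate_genome()` draws i.i.d. bases with a target GC content;
`mutate_genome()` substitutes each site independently (uniformly to one of
the three alternative bases — no transition bias, the simplest model
sufficient for ANI recovery) and seeds indel events per site with geometric
lengths of mean 2, insertions and deletions equiprobable so expected length
drift is near zero. With `indel_rate = 0` coordinates are preserved, which
is what allows exact per-site divergence oracles in the tests.
`simulate_reads()` draws each read's source genome with probability
proportional to copy-number weight × genome length (so length-normalised
abundance recovers the weights), uniform start and strand, and i.i.d. base
errors. `generate_proteome()` draws residues i.i.d. with a controlled
Asp+Glu fraction. All generators take one explicit integer seed and leave
the caller's RNG state untouched; `derive_seed()` hashes stage names so one
global seed drives reproducible, independently re-runnable stages.

These generators deliberately omit several features of real data: coverage
bias and GC bias, quality-score error profiles, repeats and mobile elements,
strain mixtures, and chimeric contigs. Passing tests therefore demonstrate
that the *statistics are computed correctly under their own model
assumptions* — not that the thresholds are robust to every pathology of
real sediment metagenomes.

# Fragment-based ANI and conserved DNA

The query genome is cut into consecutive, non-overlapping 1020-b fragments
(fragmentation never crosses a contig boundary; a terminal remainder is kept
only if ≥ 100 b). Each fragment is aligned to the subject genome by an
internal seed-and-extend aligner: exact 15-mer seeds locate candidate
diagonals on both strands, diagonals are clustered within the band width,
and each candidate is extended by banded affine-gap Smith-Waterman
(match +2, mismatch −3, gap open −5, gap extend −2; a length-k gap costs
5 + 2k; band half-width 0.2 × fragment length, minimum 16). These constants
are stated so results are reproducible bit for bit; the test suite verifies
on hundreds of instances that the banded seeded search returns exactly the
score of an exhaustive Smith-Waterman (computed independently by
`Biostrings::pairwiseAlignment`).

* **ANI** is the unweighted mean identity over *qualifying* fragments — best
  alignment with identity ≥ 30% over ≥ 70% of the fragment. Identity is
  matches / aligned columns, so gaps count against identity.
* **Conserved DNA** is the percentage of fragmented query bases lying in
  alignments at ≥ 90% identity. The denominator is the total *fragmented*
  query length (retained fragments), not the raw genome length: with the
  remainder-drop rule a raw-length denominator would make even a
  self-comparison fall short of 100%, breaking the identity
  self-comparison = 100 invariant that anchors the scale.
* **Decision**: ANI ≥ 95 and conDNA ≥ 69 → same species (1); ANI ≥ 95 and
  conDNA < 69 → might be the same species (−1); ANI < 95 and conDNA < 69 →
  different species (0). The remaining quadrant (ANI < 95, conDNA ≥ 69) is
  not covered by the published three-way rule; it maps to 0 with an explicit
  `unspecified_quadrant` flag rather than silently.

Fragment qualification thresholds and the 1020-b fragment length follow the
established fragment-ANI convention; only the 95/69 decision thresholds are
fixed by the delineation rule itself, and all of them are parameters of
`ani_params()`. Fragment-based ANI is directional, so `pairwise_matrices()`
computes every ordered pair; on indel-free mutant pairs the two directions
agree within one point. When no fragment qualifies the pair is flagged
`no_homology` and ANI is reported as 0 — with 1020-b fragments at ≥ 30%
identity over ≥ 70% coverage, unrelated random genomes never produce a
qualifying extension (the expected per-column score is negative), which the
tests confirm.

# Read recruitment and RPKG

Reads are subsampled uniformly without replacement (default 10⁷ per
dataset), then each read is aligned to each MAG with the same seed-and-extend
machinery. A read is recruited iff its best alignment spans ≥ 50 columns at
≥ 95% identity (both parameters of `recruitment_params()`). The default mode
maps reads onto each MAG *independently*, matching the per-MAG recruitment
convention; a competitive best-hit mode (ties to the lexicographically
smaller MAG id) is available but off by default, since which convention the
original mappers used is generally unstated.

RPKG = reads recruited per kilobase of MAG per gigabase of mapped reads:
`count / (mag_length/10³) / (mapped_bases/10⁹)`. "Mapped reads" is
interpreted as the total bases of reads recruited to *at least one* MAG in
that dataset — a per-dataset denominator shared across MAGs, so within-dataset
ratios reflect counts per kilobase; `denominator = "sampled"` switches to
total subsampled bases. With reads simulated at source probability
∝ weight × length, RPKG is proportional to the copy-number weight, and the
acceptance tests verify Spearman ≥ 0.95 between RPKG and the true weights at
50,000 error-free reads over 5 genomes.

# Quality tiers, salinity preference, species averaging

Tiers: near-complete = completeness ≥ 90% and contamination < 5%; medium =
completeness ≥ 50% and contamination < 10%; otherwise fail. The
contamination boundary is strict (`<`) by default — the tier wording uses
"< 10%" while the bin-selection wording uses "≤ 10%"; `contamination_inclusive
= TRUE` switches to `≤` where the other convention is wanted.

The salinity-preference score ranks each MAG twice: a positive score by the
RPKG sum over high-salinity datasets (the largest sum receives +M over M
MAGs, the smallest +1) and a negative score by the sum over
moderate-salinity datasets (largest −M). Their sum places MAGs recruiting
preferentially from high salinity at the positive end. Positive scores are
a permutation of 1..M and negative of −M..−1, so scores always sum to zero,
and any positive rescaling within one group leaves scores unchanged — both
properties are tested. All ranking ties (here, in `top_n_abundant()`, and in
competitive recruitment) break deterministically: descending value, then
ascending id.

For presentation-style summaries, `aggregate_species()` merges MAGs whose
decision codes mark them as the same (1) or likely the same (−1) species —
interpreted as the union of both codes with transitive closure (connected
components) — and averages RPKG arithmetically per cluster and dataset.
`phylogeny_eligibility()` applies the ribosomal-protein filter used for
concatenated MAG phylogenies: markers count only at ≥ 80 aa, a MAG is
eligible with ≥ 8 of the 16-protein panel, and duplicate copies of a marker
count once (the rule concerns presence, not copy number).

# Isoelectric points

Net charge at a given pH follows the Henderson–Hasselbalch model over nine
ionizable groups: N-terminus, C-terminus and the Lys, Arg, His, Asp, Glu,
Cys, Tyr side chains, with Cys and Tyr treated as weak acids and terminal
groups counted once per protein. The packaged pKa set (N-term 8.6, C-term
3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1) ships as an
editable data file (`inst/extdata/pka_default.tsv`) because published pI
figures rarely name their constants; any alternative set can be loaded with
`load_pka_set()`. The charge is strictly decreasing in pH, so the pI is the
unique root, found by bisection on [0, 14] to |charge| < 10⁻⁴ elementary
charges (the returned value satisfies that bound directly; output tables
format to 4 decimals). Ambiguous residues (B, Z, X) are rejected by default
rather than silently approximated; `on_invalid = "skip"` drops them with a
warning.

Profiles histogram pI values in half-open bins of width 0.2 spanning
[0, 14]; the median and the acidic fraction (share of proteins with
pI < 5.5) come from unbinned values. The "pronounced acidic peak" call used
to flag salt-in-type proteomes is operationalised as: modal bin centre
< 5.5 *and* acidic fraction ≥ 0.5. Both thresholds are parameters and are
reported alongside every call, since the visual criterion in published pI
panels is not otherwise operational.

# Pathway screening

Pathway definitions are configuration, not code: a YAML file maps each
pathway to required KOs, optional KOs and a presence threshold (fraction of
required KOs needed for a "present" call). Of the packaged defaults, only
the four single-marker anchors are fixed by the screening literature —
acsB/K14138 (bacterial-type CODH/ACS), cdhC/K00193 (archaeal-type),
nrfA/K03385 and PRK/K00855; the multi-KO sets (Wood-Ljungdahl eastern
branch, EMP glycolysis, PFOR, pta+ack) are best-effort selections from KEGG
modules, flagged as editable in the file's comments. Completeness is
|required ∩ annotated| / |required| with KO multiplicity ignored;
`screen_marker()` adds the product-length floor used for acsB tree building
(≥ 500 aa), excluding hits without length data with a warning.

# Pipeline, formats and determinism

`run_pipeline()` chains quality tiering → recruitment → RPKG → salinity
scores → ANI matrices over the union of top-N abundant MAGs →
species-averaged abundance → pI profiles → pathway matrix, writing each
table as TSV with a provenance comment (tool version, parameters) and a
run log with ISO-8601 timestamps. Genomic coordinates are 0-based
half-open everywhere. Defaults reproduce the standard study parameters:
95%/50 b recruitment cutoffs, 10⁷-read subsample, 1020-b fragments, 95/69
decision thresholds, 0.2 pI bins. A rerun with the same config produces
byte-identical tables; all randomness flows from the config seed through
`derive_seed()`.

`write_demo_data()` builds a complete miniature study — four MAGs including
one same-species pair at 2% divergence, a high- and a moderate-salinity
read set with opposite community compositions, an acid-shifted and a
neutral proteome, planned-completeness annotations and a quality table —
and is the quickest way to see every output format.

# Problem sizes used in the tests

The test suite runs at desk scale, chosen so the statistical envelopes stay
tight (3-standard-error bounds below 10% relative error) while the whole
suite completes in minutes: 100-kb genomes for ANI recovery at substitution
rates 0.01–0.15; 200 random instances ≤ 2 kb for the aligner-vs-oracle
equivalence; a 5-genome community with 50,000 error-free 150-b reads for
abundance recovery; 1,000 random proteins for pI root verification; an
871-MAG synthetic catalog for the rank-score bound. Fragment length,
thresholds and seeds are fixed by the defaults above, not tuned per test.

# Known limitations

* The aligner is exact only within its band and seeded diagonals; alignments
  requiring indel offsets beyond 0.2 × query length, or sharing no exact
  15-mer with the subject, are missed. At the divergences where the 95/69
  rule operates this is immaterial (tests at 15% divergence still find every
  fragment), but ANI between genomes < 70% identical is reported as
  `no_homology` rather than estimated.
* RPKG ignores pairing; reads are treated as singletons.
* pI prediction models unfolded chains: no structural pKa perturbation,
  no phosphorylation, no cysteine crosslinking.
* Pathway calls are presence-based on KO ids; they inherit whatever
  annotation errors the upstream KO assignment made.
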