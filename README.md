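# halomag

Post-binning ecological genomics of metagenome-assembled genomes (MAGs) from
hypersaline and soda-lake sediments, in R.

After a sediment metagenome has been assembled and binned, a study still has
to answer: *which bins are usable genomes, which bins are the same species,
who is abundant where, who prefers which salinity, who runs a "salt-in"
osmotic strategy, and who encodes which pathway?* `halomag` implements that
post-binning layer as tested, reusable functions:

* **Quality tiering** — near-complete (completeness ≥ 90%, contamination
  < 5%) vs medium (≥ 50%, < 10%) vs fail, from CheckM-style estimates.
* **Species delineation** — fragment-based average nucleotide identity (ANI)
  and conserved DNA: 1020-b query fragments locally aligned to the subject
  (seed-and-extend, banded affine-gap Smith-Waterman); ANI = mean identity of
  qualifying fragments, conDNA = % of query bases in alignments ≥ 90%
  identity; decision matrix ANI ≥ 95 & conDNA ≥ 69 → same species (1),
  ANI ≥ 95 & conDNA < 69 → might be (−1), otherwise different (0).
* **Abundance** — read recruitment at ≥ 95% identity over ≥ 50 bases,
  normalised as RPKG = reads per kilobase of MAG per gigabase of mapped
  reads.
* **Salinity preference** — a rank statistic: +rank of the RPKG sum over
  high-salinity datasets (largest = +M over M MAGs) plus −rank over
  moderate-salinity datasets; positive scores mean high-salinity preference.
* **Proteome pI profiling** — Henderson–Hasselbalch net charge, bisection
  for the isoelectric point, 0.2-width histograms, and an acidic-peak call
  (modal bin < 5.5 and ≥ 50% of proteins with pI < 5.5) flagging
  "salt-in"-type acidic proteomes.
* **Pathway screening** — KEGG-KO marker definitions (editable YAML) for
  CODH/ACS (acsB K14138, cdhC K00193), the Wood-Ljungdahl eastern branch,
  EMP glycolysis, PFOR, pta+ack, nrfA, PRK; completeness = fraction of
  required KOs present; product-length screens (e.g. acsB ≥ 500 aa).
* **Synthetic data** — generators for genomes, divergent pairs, community
  read sets, proteomes and KO tables with known ground truth, so the whole
  pipeline is testable offline.

## Worked example

```r
library(halomag)

# a complete miniature study: 4 MAGs (magA/magB are the same species at 2%
# divergence), high- and moderate-salinity read sets, 2 proteomes,
# annotations, quality table
cfg <- write_demo_data("demo", seed = 1)
res <- run_pipeline(cfg)

res$scores
#>   mag  high_sum moderate_sum pos_rank_score neg_rank_score salinity_score
#>  magA 249166.67     60666.67              4             -2              2
#>  magB 245500.00     60166.67              3             -1              2
#>  magD  55166.67     61333.33              2             -3             -1
#>  magC  26333.33    210500.00              1             -4             -3

res$matrices$decision
#>      magA magB magC magD
#> magA    1    1    0    0
#> magB    1    1    0    0
#> magC    0    0    1    0
#> magD    0    0    0    1

res$species
#>    cluster dataset      rpkg n_members
#>  magA;magB highSed 247333.33         2
#>  magA;magB  modSed  60416.67         2
#>       magC highSed  26333.33         1
#>       ...
```

Reading the output: `magA` and `magB` recruit heavily from the high-salinity
dataset (RPKG sums ~249k vs ~61k), so they take the top positive ranks and a
positive salinity score, while `magC` (abundant in the moderate-salinity
dataset) lands at −3. The decision matrix recognises `magA`/`magB` as one
species (code 1), so `aggregate_species()` averages their RPKG into a single
`magA;magB` cluster. The two demo proteomes separate cleanly:

```r
res$pi_profiles
#> pI profile 'magA': 150 proteins, median pI 3.53, 100.0% with pI < 5.5
#> pI profile 'magC': 150 proteins, median pI 7.43, 3.3% with pI < 5.5
```

`magA` (generated at 40% Asp+Glu) shows the acid-shifted profile expected of
a salt-in halophile; `magC` (10%) does not.

Individual steps are plain functions — e.g.

```r
classify_pair(96, 75)$code   # 1  (same species)
classify_pair(90, 50)$code   # 0  (different species)
compute_rpkg(1000, 0.5e9, 2e6)  # 1.0 RPKG
```

A thin command-line wrapper with subcommands
`simulate | ani | recruit | score | pi | pathways | run` is installed at
`system.file("scripts", "halomag.R", package = "halomag")`.

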