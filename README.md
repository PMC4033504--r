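# epivote

Linear epitope mapping for allergen proteins by propensity profiles and
multi-predictor consensus voting.

## What it is for

In-silico allergen characterization pipelines — typified by studies of
house-dust-mite allergens such as Der f 25, a *Dermatophagoides
farinae* triosephosphate isomerase — combine three kinds of analysis:

1. **Physicochemical profiling** of the protein (molecular weight,
   theoretical pI, GRAVY, aliphatic index, instability index) and
   **PROSITE motif scanning** for functional patterns;
2. **Linear B-cell epitope prediction**, where several independent
   tools each emit candidate residue intervals;
3. **MHC class II T-cell epitope prediction**, where binding predictors
   emit 9-mer core intervals per HLA allele.

The step that turns the per-tool and per-allele interval lists into the
final epitope set is a *residue-level k-of-n consensus vote*, and that
vote is the computational core of this package. External predictors are
not wrapped or re-implemented: their outputs enter as plain TSV interval
tables (`source<TAB>start<TAB>end`, 1-based inclusive), and the package
also ships classical sliding-window propensity predictors
(Kolaskar–Tongaonkar antigenicity, Parker/Hopp–Woods hydrophilicity,
Emini surface probability, Karplus–Schulz flexibility) as transparent
in-repo B-cell predictors.

## The consensus model

Each predictor or allele is one *track* of regions on the protein.
Regions within a track are union-merged (so support counts distinct
tracks, not overlapping peptides), per-residue support is the number of
tracks covering the residue, and consensus epitopes are maximal runs
with support ≥ *k*, bridged across gaps ≤ `merge_gap` and filtered to
length ≥ `min_len`. Defaults: *k* = 2-of-3 for B-cell tools, *k* =
3-of-4 alleles per HLA locus, `merge_gap = 0`, `min_len = 4`. Two loci
(HLA-DR, HLA-DQ) combine by region union with elementwise-max support.

## Worked example

The package bundles the predicted-interval tables of a published
Der f 25 epitope study as fixtures. The three-tool B-cell vote:

```r
library(epivote)
tracks <- parse_interval_table(
  system.file("extdata", "table3_bcell.tsv", package = "epivote"))
res <- residue_vote_consensus(tracks, k = 2, min_len = 4, merge_gap = 0,
                              seq_length = 247)
res
#> <consensus_result> k=2, min_len=4, merge_gap=0: 8 region(s)
#>   11-18, 30-35, 68-77, 99-107, 132-139, 173-187, 193-199, 211-225
res$regions
#>      source start end length min_support
#> 1 consensus    11  18      8           2
#> 2 consensus    30  35      6           2
#> 3 consensus    68  77     10           2
#> 4 consensus    99 107      9           2
#> 5 consensus   132 139      8           2
#> 6 consensus   173 187     15           2
#> 7 consensus   193 199      7           2
#> 8 consensus   211 225     15           2
```

Eight consensus B-cell epitopes — the published count. (Four of the
eight boundaries differ from the study's printed consensus intervals by
1–3 residues; no uniform residue-vote rule reproduces those four printed
boundaries from the printed per-tool intervals, so the count and the
membership checks below are the reproducible facts. See the vignette.)

The per-locus allele votes and their combination:

```r
dr <- allele_support_consensus(parse_interval_table(
  system.file("extdata", "table3_dr.tsv", package = "epivote")),
  k = 3, seq_length = 247)
dq <- allele_support_consensus(parse_interval_table(
  system.file("extdata", "table3_dq.tsv", package = "epivote")),
  k = 3, seq_length = 247)
combine_loci(dr, dq)
#> <consensus_result> k=3, min_len=4, merge_gap=0: 10 region(s)
#>   26-34, 37-61, 66-74, 82-85, 117-120, 122-125, 143-150, 158-168, 195-200, 238-247
```

The DR vote emits the published region 26–34 exactly, and the combined
region 37–61 nests the DQ-derived 39–48 inside coverage of 38–54.

Physicochemical profile and motif scan (any protein sequence works; the
`derf25_synthetic_scaffold()` below is a clearly-labelled synthetic
stand-in with the study's printed residues at their printed positions):

```r
physchem_profile("GASPQQAQEVHQKLAYEPVWAIGTGKTASPNNVFGESDQLWKMNGNKTDE")[1:7]
#> $length            50
#> $molecular_weight  5458.9
#> $theoretical_pI    5.13
#> $gravy             -0.946
#> $aliphatic_index   50.8
#> $instability_index 47.26
#> $stability_class   "unstable"

scan_pattern(derf25_synthetic_scaffold(), load_motif_patterns()$PS00171)
#>    source start end        text
#> 1 PS00171   162 172 AYEPVWAIGTG

classify_residues("WKMNGNKT")
#>             W             K             M             N             G             N             K             T
#> "hydrophobic"     "charged" "hydrophobic"       "other"       "other"       "other"     "charged"       "other"
```

The motif scan finds the triosephosphate isomerase active-site pattern
PS00171 at exactly one location, 162–172, matching `AYEPVWAIGTG`.

An end-to-end run (`run_pipeline()`, or the `exec/epivote` command-line
script with subcommands `physchem`, `scan`, `bcell`, `consensus`,
`simulate`, `run`) chains these stages and writes a deterministic JSON
report plus TSV/BED/GFF3 region files.

To analyze the real Der f 25 protein, supply its sequence yourself
(public nucleotide accession KC305500.1) as FASTA, or as a CDS
nucleotide file via `translate_cds()`; network access is deliberately
not part of the package.

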