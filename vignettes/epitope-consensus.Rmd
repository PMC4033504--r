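---
title: "Epitope mapping by propensity profiles and consensus voting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epitope mapping by propensity profiles and consensus voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epivote)
```

## The problem

House-dust-mite allergens such as Der f 25, a triosephosphate isomerase
(TPI) of *Dermatophagoides farinae*, are routinely characterized in
silico before any wet-lab epitope work: global physicochemical
parameters and functional motifs describe the molecule, and candidate
linear B-cell and MHC class II T-cell epitopes are nominated by
combining the outputs of several independent predictors. `epivote`
implements that workflow as a reproducible pipeline. External predictors
(commercial property-combination tools, trained HMMs, neural MHC-II
binding models) are deliberately *not* re-implemented: the package
consumes their outputs as plain interval tables and contributes the part
of the analysis that is actually a defined computation — the residue-level
consensus vote — together with classical propensity-scale predictors
that serve as transparent, fully testable stand-ins for the B-cell
tools.

## Consensus voting

A predictor or HLA allele contributes one *track*: a set of 1-based,
inclusive residue intervals on one protein. The vote proceeds in four
steps:

1. **Per-track union-merge.** Overlapping intervals within one track are
   collapsed. This makes support a count of *distinct tracks*, not of
   reported peptides — two overlapping 9-mer binding cores from one
   allele are one voice, which is the natural reading of "an allele
   shows an epitope".
2. **Support tally.** For each residue, count the tracks covering it.
3. **Thresholding.** Maximal runs of residues with support ≥ *k* become
   candidate regions; runs separated by gaps of at most `merge_gap`
   residues are bridged.
4. **Length filter.** Regions shorter than `min_len` are dropped.

Defaults are *k* = 2 of 3 for the B-cell vote, *k* = 3 of 4 per HLA
locus (the classical "three of four alleles" rule), `merge_gap = 0`
(no published bridging rule exists, so none is invented) and
`min_len = 4` (a consensus shorter than four residues is below any
reported linear epitope length and typically a tally artifact — on the
bundled worked example a single-residue spike at position 168 is
suppressed by exactly this filter). All four parameters are exposed
everywhere, including the command line.

The B-cell threshold deserves a note: with the three bundled predictor
tracks, *k* = 2 yields eight consensus epitopes, *k* = 3 collapses to
far fewer, and *k* = 1 degenerates toward the union. Majority voting
(2 of 3) is therefore both the methodologically standard choice and the
one that reproduces the expected granularity; it is the default, not a
hard-wired rule.

Two loci are combined by `combine_loci()`: the union of the two region
sets with adjacent/overlapping regions merged, and the per-residue
support vector taken as the elementwise maximum. Union (rather than
intersection) is used because DR- and DQ-restricted responses are
complementary routes to T-cell recognition.

Worked example, using the interval tables bundled with the package:

```{r consensus}
tracks <- parse_interval_table(
  system.file("extdata", "table3_bcell.tsv", package = "epivote"))
residue_vote_consensus(tracks, k = 2, min_len = 4, merge_gap = 0,
                       seq_length = 247)
```

Four of these eight boundaries differ by 1–3 residues from the
consensus intervals printed in the study the bundled tracks come from;
no uniform residue-vote rule reproduces those four printed boundaries
from the printed per-tool intervals, so this package documents the
discrepancy and treats the *count* and the membership checks (the DR
region 26–34; the nesting of 39–48 inside the combined T-cell region)
as the reproducible facts.

## Propensity-scale B-cell predictors

The in-repo B-cell predictors are classical sliding-window methods: a
per-residue scale is aggregated over a centered window of odd width and
the score assigned to the center residue. Flanking residues without a
complete window are `NA`, never padded — padding conventions differ
between historical tools, and inventing one would silently shift
boundaries.

* `antigenicity_regions()` implements the average-propensity
  antigenicity rule (Kolaskar–Tongaonkar values, window 7): maximal runs
  of centers scoring above the fixed threshold 1.0, extended by half a
  window on each side, minimum length 8. The fixed threshold (rather
  than the whole-protein-mean variant some servers use) keeps the rule
  deterministic and input-local; both the threshold and the scale are
  arguments.
* `composite_index_regions()` is a DNAStar-style multi-property
  combination: each scale is z-standardized across its 20 values, the
  windowed mean profiles are combined with weights (defaults 0.3
  hydrophilicity, 0.15 accessibility, 0.15 flexibility, 0.4
  antigenicity — the four canonical properties; no published weighting
  exists, so the weights lean toward the two properties most predictive
  in the classical literature and are fully configurable), and regions
  are runs above a percentile of the profile's own distribution.
* The Emini surface-probability convention is product-based; the profile
  is `prod(value / 0.37)` over the window, formulated per-position so it
  is well-defined at any odd window width.

These predictors are honest stand-ins, not replicas of the external
tools; the package reproduces the published worked example through the
consensus stage operating on the external tools' *printed intervals*,
which is the part of the analysis that is a defined computation.

## Physicochemical profile

`physchem_profile()` reproduces the standard ProtParam-style global
parameters: average-mass molecular weight (sum of residue masses plus
one water), theoretical pI, GRAVY (mean Kyte–Doolittle hydropathy),
aliphatic index (`X(A) + 2.9 X(V) + 3.9 (X(I)+X(L))` in mole percent),
and the Guruprasad instability index (`10/L` times the sum of DIWV
dipeptide weights; below 40 is "stable"). Report values are rounded at
the conventional printed precision (MW to 1 decimal, pI to 2, GRAVY to
3, the indices to 2); the underlying functions return full precision.

The charge model behind the pI is the Henderson–Hasselbalch sum over
the Bjellqvist pKa set used by the ProtParam tool, including its
terminal-residue exceptions (the N-terminal amine pKa depends on the
first residue; the C-terminal carboxyl pKa shifts when the last residue
is Asp or Glu). That pKa set — not EMBOSS's or IPC's, which shift pI by
more than 0.05 — is what published "theoretical pI" values computed with
that tool imply. Two numerical points:

* The charge is strictly decreasing in pH, so the pI is a unique root.
  Bisection runs on (0, 14) until the bracket is narrower than 1e-8 pH
  units. A charge-magnitude stopping rule (e.g. stop at |charge| <
  1e-4) is *not* used: near the pI of a peptide with few ionizable
  groups the charge curve is nearly flat and such a rule can stop
  several hundredths of a pH unit from the root.
* Some reference implementations bound their pI search to roughly
  [4.05, 12] and silently return the bound for very acidic or basic
  peptides; this implementation searches the full interval and reports
  the true root of the model.

Unknown residues (`X`) are tolerated in sequences but are a hard error
in any scale arithmetic (MW, GRAVY, instability, profiles): silently
skipping them would corrupt comparisons against printed values in a way
the user cannot detect.

## Motif scanning

`parse_prosite_pattern()` and `scan_pattern()` implement the core
PROSITE pattern grammar (fixed residues, `x`, `[...]`, `{...}`, repeat
counts and ranges, terminal anchors). Every distinct match span is
reported, including overlaps and every achievable length of a ranged
element. `X` in a sequence matches only wildcard (`x`) elements — a
conservative choice that avoids false motif hits on unknown residues.
The bundled pattern file carries the TPI active-site pattern PS00171 and
three classical kinase phosphorylation-site patterns, the latter as
illustrative stand-ins for neural phosphosite predictors, which are out
of scope. PROSITE *profiles* (weight matrices) and ScanProsite's
skip-flag post-processing are not implemented.

## Synthetic data: what it emulates and what it does not

The generators in `planting_design()` / `simulate_predictor_tracks()` /
`simulate_allele_peptides()` reproduce the statistical structure the
consensus vote assumes: planted "true" epitopes; per-predictor Bernoulli
agreement (`agreement_p`); uniform boundary jitter (`boundary_jitter`),
applied independently to start and end and clamped to the sequence, which
is what makes ragged per-tool boundaries like the bundled example's
reproducible; and Poisson-distributed spurious regions (`fp_rate`).
Allele tracks are tilings of fixed-length 9-mer cores with random stride
1–3, the final core pinned to the epitope end.

Default design: a 247-residue sequence (the length of the allergen the
worked example concerns), 4 epitopes of 10–16 residues, 3 predictors,
`agreement_p = 0.9`, jitter 2, one spurious region per predictor —
values chosen once as representative of the Table-level agreement
visible in multi-tool epitope studies. Planted epitopes are separated by
at least `2 * boundary_jitter + 2` residues so that jittered reports of
different epitopes cannot merge; this keeps the analytic expectation of
the recovery experiment exact. Under the default design the sensitivity
of the 2-of-3 vote has the closed form `P(Bin(3, 0.9) >= 2) = 0.972`
(spurious overlaps add a small positive bias), and the test suite checks
the simulated value against it within three standard errors over 200
seeded replicates.

What the generator does **not** emulate: realistic amino-acid
composition (residues are uniform i.i.d.), MHC binding affinities,
correlated errors between predictors, or conformational epitopes.
Passing the recovery tests therefore demonstrates that the voting
machinery is correct and calibrated under its stated noise model — not
that any particular external predictor is accurate on real allergens.

All generators take an explicit seed, pin the RNG kind
(Mersenne-Twister / Rejection sampling) and restore the caller's RNG
state, so results are bit-reproducible across sessions and platforms.

## The synthetic Der f 25 scaffold

The real Der f 25 sequence is distributed through its database accession
and is not bundled (users supply it as a FASTA or nucleotide file;
`translate_cds()` handles a CDS record). For tests and examples the
package ships `derf25_synthetic_scaffold()`: a **synthetic** 247-residue
stand-in that places every residue whose identity and position the
source study prints — the thirteen epitope peptides, the PS00171
undecapeptide at 162–172, the catalytic His94 and the substrate-binding
Asn10/Lys12 — at those positions, with glycine filler elsewhere. It is
clearly labelled synthetic in its identifier and documentation, and it
is used only for structural facts that hold by construction (length,
motif location, residue lookups) and for exercising the end-to-end
pipeline; its global physicochemical values are *not* those of the real
protein and are never presented as such. The physicochemical engine is
instead validated at printed precision against an independent reference
implementation on fixed peptides.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout; the only conversion is
  in the BED writer (0-based half-open), round-trip tested.
* `window_profile()` requires an odd window not exceeding the sequence
  length; even windows are an error rather than a silently shifted
  center.
* Consensus on an empty track table is an error ("no tracks"), and
  `k` greater than the number of supplied tracks is an error rather
  than an empty result — both almost always indicate a malformed input.
* An empty interval TSV parses to an empty track table (a legitimate
  "no predictions" state).
* With `merge_gap > 0`, bridged residues may have support below `k`;
  the per-region `min_support` column makes this visible.
* Ambiguous codons translate to `X` unless all expansions agree; a codon
  that is a stop only under some expansions is `X`, not a stop, so
  translation never terminates on ambiguity.
* Ties at the composite-index percentile cutoff: strictly-greater
  comparison, so cutoff-valued centers are excluded.

## Problem sizes used in the test suite

The property-based suite runs the consensus engine against a
position-by-position tally oracle on 500 random instances (sequences of
30–200 residues, 2–6 tracks, all parameters randomized), the PROSITE
scanner against a regex-enumeration oracle on dozens of random
pattern/sequence pairs, and the synthetic recovery experiment over 200
seeded replicates; these sizes exercise every code path while keeping
the full suite fast enough to run on every change.

## Known limitations

* The consensus reproduces printed *interval* tables; it cannot recover
  boundary conventions a source tool applied internally before
  printing (hence the four documented boundary deviations in the worked
  example).
* Propensity predictors are classical methods; they are not substitutes
  for modern trained predictors when nominating epitopes de novo.
* PROSITE profile entries, conformational epitopes, binding-affinity
  weighting and population-coverage statistics are out of scope.
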