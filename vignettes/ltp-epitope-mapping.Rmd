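---
title: "Allergenicity screening and B-cell epitope mapping for plant lipid transfer proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allergenicity screening and B-cell epitope mapping for plant lipid transfer proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltpepimap)
```

## The problem

Nonspecific lipid transfer proteins (nsLTPs) are small (~9 kDa, ~90–120 aa)
plant proteins stabilised by four disulfide bridges formed by eight
invariant cysteines.  Their heat and protease stability makes them
clinically important panallergens: IgE raised against one family member
(classically peach Pru p 3) frequently cross-reacts with homologous LTPs in
other foods.  Assessing whether an uncharacterised LTP is a plausible
cross-reactive allergen is therefore largely a sequence problem: how
similar is it to known allergens, are its candidate IgE-binding regions
(B-cell epitopes) conserved, and do those regions resemble validated
epitopes in physicochemical terms?

`ltpepimap` implements that assessment as a reproducible local pipeline:

1. **Dual-mode homology screening** against a user-supplied allergen FASTA
   database: full-length global identity and the Codex-style 80-amino-acid
   sliding-window identity.
2. **Multiple alignment, conservation and phylogeny**: a progressive
   protein MSA, Clustal-style per-column symbols (`*`, `:`, `.`), a
   per-residue percent-conservation score, and a neighbor-joining tree on
   uncorrected p-distances.
3. **Consensus linear B-cell epitope prediction** from a panel of
   propensity scales combined by a votes threshold.
4. **Shared-epitope (triad) analysis**: maximal residue motifs common to
   two or three epitope sets, checked against the three experimentally
   validated peach-LTP epitopes.
5. **Property-distance (PD) peptide similarity**: a calibrated distance in
   a five-dimensional physicochemical descriptor space, scanned across the
   allergen database at the conventional PD < 4 threshold.
6. A **synthetic LTP-family generator** that makes every stage testable
   without any network access.

## Homology screening

Both search modes align with BLOSUM62 and affine gap penalties (open 10,
extend 0.5) via `Biostrings::pairwiseAlignment()`.  These defaults are a
widely reproducible stand-in for the FASTA-engine settings used by the
public allergen databases, whose exact parameters are not published; for
the same reason, identity percentages from those services should be treated
as engine-dependent, and this package's values as bounds-compatible rather
than digit-identical.

* **Full-length mode** reports 100 × matches / alignment columns
  (gap columns included — the conservative convention; a
  `denominator = "shorter"` option divides by the shorter de-gapped
  length instead).
* **Window mode** slides every 80-residue query window (step 1; a shorter
  query is one whole-query window) across each subject with local
  alignment, and reports the best window per subject as
  100 × matches / window length.  Dividing by the *window length* rather
  than the local-alignment length is deliberate: Smith–Waterman trims to
  the best-scoring segment, and matches over that short segment would make
  unrelated proteins appear to pass the ≥ 35 % Codex screen.

Percentages are rounded half-up to two decimals, the convention used in
printed identity tables.

## Alignment, conservation and phylogeny

`progressive_msa()` is a self-contained progressive aligner: pairwise
global-identity distances feed a UPGMA guide tree, and profiles are merged
bottom-up by affine-gap global alignment of residue-count profiles using a
mean-of-pairs BLOSUM score (residue-vs-gap −1, gap-vs-gap 0).  It is
deterministic for a fixed input order.  No external MSA binary is invoked,
so column-exact agreement with any particular web tool is not expected;
counts that depend on the engine (e.g. "how many residues are fully
conserved") should be read with a ±2-column allowance.

Per column the profile reports the Clustal symbols: `*` for a gap-free
identical column, `:` when all residues fall in one *strong* Gonnet-PAM250
group (`STA`, `NEQK`, `NHQK`, `NDEQ`, `QHRK`, `MILV`, `MILF`, `HY`,
`FYW`), `.` for one *weak* group, blank otherwise; any gap disqualifies
all three.

`conservation_score()` implements the per-residue percent conservation of a
reference sequence:

\[
\mathrm{score}(X) = \frac{\#\{\text{sequences carrying residue } X \text{ in that column}\} \times 100}{N}
\]

Gaps never count as matches.  Scores are kept at full precision and
*floored* to integer percent for display, so 14 of 15 prints as 93 and
2 of 15 as 13.  When a reference protein is aligned alongside the \(N\)
sequences being scored (e.g. peach against 15 food-crop LTPs),
`exclude_reference = TRUE` uses the reference only as the coordinate
system.

Trees come from Saitou–Nei neighbor joining (`ape::nj()`) on uncorrected
p-distances (`1 −` fractional identity over pairwise-complete columns),
with negative branch lengths clamped to zero — NJ on an additive matrix
reproduces the generating tree exactly, which the tests exploit as an
oracle.

```{r conservation-demo}
fam <- generate_family(family_spec(n = 6, identity = 0.7, seed = 1))
msa <- progressive_msa(fam$records)
prof <- conservation_profile(msa, "d1")
head(prof)
```

## Consensus epitope prediction

Trained webserver predictors (neural networks, SVMs) cannot be reproduced
locally; what *can* be reproduced is the consensus logic they feed.  The
panel here is seven classical propensity scales — Parker hydrophilicity,
Emini surface accessibility, Karplus–Schulz flexibility,
Kolaskar–Tongaonkar antigenicity, Chou–Fasman β-turn propensity, a polarity
scale (negated Ponnuswamy surrounding hydrophobicity) and an exposure scale
(negated Janin transfer energy) — each computed over a sliding window
(default 7, odd, truncated symmetrically at the termini; Emini uses its
published product form, with terminal windows handled through the geometric
mean so flat sequences stay flat).

Each profile is z-normalised over the sequence and calls residues with
z > 0; Kolaskar–Tongaonkar instead uses its published absolute rule
(window mean > 1.0).  A zero-variance profile makes no calls on any scale —
an uninformative predictor should not vote.  Consensus keeps residues
called by at least `min_votes` predictors (default `ceiling(5/8 · n)`,
scaling the classical 5-of-8 webserver rule to the panel size), merges them
into maximal runs, and drops runs shorter than `min_region_length`
(default 6, a minimal plausible linear epitope).

Because this panel is a stand-in, the published consensus regions for the
five legume LTPs are shipped as a fixture
(`load_reported_epitopes()`) and used as *inputs* to the downstream motif
and PD analyses, not as prediction targets.  One fixture row is internally
inconsistent in its source (validated peach epitope 2: a 15-position range
with a 16-residue string); the loader keeps the string as authoritative and
flags the row rather than guessing.

## Shared motifs and triads

`shared_substrings()` finds every *maximal* common substring (length ≥ 4 by
default — the shortest shared epitope regions reported for LTPs are
4-mers) between two epitope collections; `triad_partition()` assigns motifs
to the most specific cell of a three-set Venn partition (a motif common to
all three sets appears only in the three-way cell; two-way cells hold
motifs genuinely absent from the third set), rendering empty cells as
`"0"`.  Matching is exact residue identity; hyphenated notation
(`I-P-Y-K`) is normalised at ingest.  Every reported motif is verifiable by
direct substring search in each listed member, and the tests do exactly
that, alongside a brute-force enumeration oracle.

```{r motifs-demo}
eps <- suppressWarnings(load_reported_epitopes())
chick <- eps[eps$source == "chickpea", ]
peach <- eps[eps$kind == "validated", ]
shared_substrings(chick$residues[2], peach$residues[2])$motif
```

## Property distance

PD maps each residue to a point in the five-dimensional descriptor space of
Venkatarajan & Braun (2001) (the principal-component summary of ~240
physicochemical properties) and scores two equal-length peptides as

\[
\mathrm{PD}(a, b) = c \cdot \frac{1}{n} \sum_{i=1}^{n} \lVert E(a_i) - E(b_i) \rVert_2 .
\]

The published web implementation's exact scaling is not documented, but the
scale's behaviour is: identical peptides at 0, single conservative
substitutions below 4, unrelated random peptides above 10.  The constant
\(c\) is therefore fixed once by `pd_calibrate()` so that the *median* PD
over 10,000 uniformly random 10-mer pairs equals 13 — comfortably above the
"unrelated" landmark while leaving conservative substitutions
(~0.5–2) far below the 4 threshold.  The shipped value (seed 42) is stored
in `inst/extdata/pd_calibration.json` and is never silently recomputed.
`pd_scan()` slides the query over every equal-length window of the database
and reports windows with PD below the threshold (exact matches are always
reported, so a threshold of 0 returns precisely the identity windows).

## The synthetic generator

`generate_family()` emulates what matters about an LTP family for this
pipeline: ~93-residue proteins (a mature 9-kDa LTP1), eight invariant
cysteines at canonical spacing, tunable similarity, and optional planted
motifs shared by chosen members.  Substitutions stay within the residue's
Clustal strong group with probability 0.5 (else uniform), so partial
conservation symbols arise naturally.  Descendants mutate independently
from a common ancestor; the per-site rate is derived from the requested
*pairwise* identity target (two descendants differ at a site when either
lineage mutated, so the rate solves \((1-r)^2 = (t - f)/(1 - f)\) with
\(f\) the invariant-site fraction).  `generate_tree_family()` evolves the
same model down a phylogeny (per-branch mutation probability
\(1 - e^{-\mathrm{rate}\cdot t}\)), giving a ground-truth oracle for NJ
topology recovery.

What the generator does *not* emulate: indels (off by default so Hamming
identity is exact ground truth), real LTP secondary structure, codon-level
processes, or database-scale sequence diversity.  Tests passing on
synthetic families therefore validate the *algorithms*, not the biological
accuracy of any particular prediction on real proteins.

## Numerical and design choices

* Identity percentages: rounded half-up to 2 decimals; conservation scores
  floored to integer percent for display, full precision retained.
* Alignment tie-breaks: profile merge order follows the deterministic
  `hclust` guide tree; DP traceback prefers match over gap states; NJ
  tie-breaking follows `ape::nj`.
* Degenerate inputs: empty sequences, empty keyword lists, empty databases
  and empty epitope sets all return empty results rather than errors where
  the operation is a filter/scan; structural errors (illegal residues,
  mismatched lengths, missing references) fail loudly with the offending
  item named.
* An empty FASTA file is a valid empty database (a screen against it
  reports zero hits and succeeds).
* `run_pipeline()` is deterministic given config + seed; re-runs are
  byte-identical, and a stage failure aborts with the stage name while the
  manifest records completed stages.

Problem sizes used in the shipped tests were chosen to exercise each
algorithm at family scale (6–16 sequences of 90–200 residues, 20-seed
topology-recovery sweeps, 10,000-pair PD samples), which a desk machine
executes in well under a minute per suite.

## Known limitations

* The NCBI accession sets referenced by the original screening study are
  not bundled (sequences are fetched once by
  `inst/scripts/fetch_ncbi_fixtures.R`, which requires network access);
  accession-based checks are inactive until that cache exists.
* The propensity panel approximates, but does not reproduce, trained
  ML epitope predictors; published consensus regions are treated as
  fixtures.
* The internal progressive aligner is not Clustal Omega; engine-dependent
  column counts carry a ±2 allowance.
* PD values match the published *behavioural anchors*, not any web
  service's digits.
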