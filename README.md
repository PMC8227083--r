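# ltpepimap

In silico allergenicity assessment for plant nonspecific lipid transfer
proteins (nsLTPs) — and for any small protein family screened the same
way.

nsLTPs are ~9 kDa plant panallergens with eight invariant cysteines;
IgE raised against one family member (classically peach Pru p 3) often
cross-reacts with homologs in other foods.  Deciding whether a new LTP is
a plausible cross-reactive allergen is a sequence-analysis problem, and
this package implements the standard workflow as a local, reproducible
pipeline for allergen-risk triage:

* **Homology screening**, both conventions used by allergen databases:
  full-length global identity, and the Codex-style 80-amino-acid
  sliding-window identity (flag thresholds: > 70 % full length,
  ≥ 35 % per 80-aa window).
* **Alignment, conservation, phylogeny**: progressive protein MSA,
  Clustal-style `*`/`:`/`.` column symbols (Gonnet-PAM250 strong/weak
  groups), neighbor joining on uncorrected p-distances, and a
  per-residue percent conservation score
  `score(X) = (#sequences carrying X in that column) × 100 / N`,
  floored to integer percent for display (14/15 → 93, 2/15 → 13).
* **Consensus linear B-cell epitope prediction** from a panel of seven
  classical propensity scales (Parker, Emini, Karplus–Schulz,
  Kolaskar–Tongaonkar, Chou–Fasman turns, polarity, exposure), combined
  by a ≥ 5-of-8-style vote rule scaled to the panel size.
* **Shared-epitope (triad) analysis**: maximal common residue motifs
  between epitope sets, three-set Venn partitions, and checks against the
  three experimentally validated peach-LTP epitopes (shipped as a
  fixture together with published legume-LTP consensus regions).
* **Property-distance (PD) similarity**:
  `PD(a,b) = c · mean_i ‖E(a_i) − E(b_i)‖` in the 5-dimensional
  physicochemical descriptor space of Venkatarajan & Braun (2001),
  calibrated so identical peptides score 0, conservative substitutions
  < 4 and unrelated peptides > 10; database scanning at PD < 4.
* A **synthetic LTP-family generator** (invariant cysteine scaffold,
  tunable identity, planted motifs, tree-based evolution) so the entire
  pipeline is testable offline.

See `vignettes/ltp-epitope-mapping.Rmd` for the methods account.

## Worked example

Screen a synthetic query against a small family database in which a
hydrophilic epitope (`NDKSDGTTPDRQAS`) has been planted:

```r
library(ltpepimap)

fam <- generate_family(family_spec(n = 4, identity = 0.85, seed = 13,
  motifs = list(list(motif = "NDKSDGTTPDRQAS", members = 1:4, position = 55))))
write_fasta(fam$records[1, ],  "query.fasta")
write_fasta(fam$records[2:4, ], "db.fasta")

cfg <- pipeline_config("query.fasta", "db.fasta", "out", seed = 1)
run_pipeline(cfg)
```

`out/summary.json` then reads:

```json
{
  "seed": 1,
  "queries": {
    "d1": {
      "homology_flag": true,
      "shared_epitope_flag": true,
      "pd_flag": true,
      "n_epitopes": 2,
      "best_full_length_identity": 86.02,
      "best_window_identity": 87.5
    }
  }
}
```

All three risk flags fire, as they should for a planted homolog: the query
is 86.02 % identical to a database member over its full length (above the
70 % structural-similarity remark) and 87.5 % over its best 80-aa window
(above the 35 % Codex criterion); two consensus epitope regions were
predicted, one of which shares the motif `TTPDRQ` with the second
validated peach epitope; and that region has PD-0 (identical) windows in
the database.  Per-stage tables (`homology_hits.tsv`,
`epitope_regions.tsv`, `shared_motifs.tsv`, `pd_matches.tsv`, aligned
FASTA, Newick tree) sit next to the summary.

The individual stages are plain functions, e.g.:

```r
eps   <- load_reported_epitopes()                  # published consensus regions
chick <- eps[eps$source == "chickpea", ]
peach <- eps[eps$kind == "validated", ]
shared_substrings(chick$residues[2], peach$residues[2])[, c("motif", "length")]
#>    motif length
#> 1 TTPDRQ      6

pd_distance("APCIPYVRGG", "APCIPYVRGG")   # 0        (identical)
pd_distance("APCIPYVRGG", "APCLPYVRGG")   # 0.741    (I->L, conservative)
pd_distance("APCIPYVRGG", "WQHMKENDST")   # 14.497   (unrelated)
```

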