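# oncotherapyr

Variant interpretation for precision oncology, in R. The package covers
the computational core of a molecular-tumor-board workflow, for
bioinformaticians and clinical scientists who need reproducible,
scriptable variant interpretation without a web service:

* **Variant parsing** at DNA (`chr12:g.25245350C>T`), transcript
  (`NM_004985.5:c.35G>A`), and protein level (`KRAS:p.G12D`, `KRAS G12D`,
  `p.Gly12Asp`), plus VCF and MAF file input, variant-type recognition,
  and in-frame determination for gene fusions.
* **Clinical evidence harmonization** from three knowledge-base dialects
  (CIViC-like, OncoKB-like, MetaKB-like) onto one schema: harmonized
  AMP/ASCO/CAP evidence tiers (A–D), response types
  (sensitive/resistant/unknown), OncoTree-style cancer main types via
  exact + fuzzy matching, drug classes, and expansion of "substitutes"
  therapy interactions into single-drug options.
* **Therapy matching** at five specificity levels — exact change, other
  exchange at the same residue, any exchange at the position, same exon,
  whole gene — with cross-source duplicate merging on the normalized key
  (drug, cancer entity, evidence level, response, citation) and sunburst
  hierarchy aggregation.
* **ACMG classification** into the five categories (pathogenic, likely
  pathogenic, VUS, likely benign, benign) by evaluating evidence
  criteria (PVS1, PS1, PM1/2/5, PP3/PP5, BA1, BS1, BP4/BP6) from a
  variant's annotations and combining them under the guideline rules,
  with a full derivation trace.
* **Protein context** for a mutated site from a PDB structure:
  Shrake–Rupley solvent-accessible surface area, relative accessibility
  RSA = ASA / MaxASA, the Cα distance field
  d_i = √((x_i−x_m)² + (y_i−y_m)² + (z_i−z_m)²), three-state secondary
  structure (Kabsch–Sander H-bond detection), substitution
  physicochemistry incl. BLOSUM62, disulfide/salt-bridge candidates, and
  spatial neighbors that are close in 3D but distant in sequence.

Everything runs on deterministic packaged fixture generators; no
downloads or external services are required.

## Worked example

```r
library(oncotherapyr)

# deterministic toy fixtures (knowledge base in three source dialects)
generate_toy_kb("fx/kb", seed = 1)
kb <- load_kb_dir("fx/kb")

v <- parse_query("KRAS:p.G12A")
#>   query       level   gene  ref_aa aa_pos alt_aa variant_type
#> 1 KRAS:p.G12A protein KRAS  G          12 A      SNV

build_treatment_table(v, kb, toy_transcript())
#>   biomarker match_type        amp_tier response  citation_id
#> 1 KRAS G12A same_pos_other_aa A        sensitive PMID:31000001
#> 2 KRAS G12A exact             B        sensitive PMID:30000001
#> 3 KRAS G12A same_pos_other_aa B        sensitive PMID:30000002
#> 4 KRAS G12A same_pos_any      B        resistant PMID:30000003
#> 5 KRAS G12A same_exon         C        sensitive PMID:30000004
#> 6 KRAS G12A gene_level        C        sensitive PMID:30000005
```

Rows are sorted by evidence tier, then response, then match-type
specificity: the exact-match sotorasib study (tier B, sensitive) sits
above the positional and gene-level evidence, and the tier-A record
found one residue-exchange away leads the table. The same evidence
asserted by two sources (here PMID:30000001 from the CIViC-like and
MetaKB-like files) appears once, with both sources recorded.

```r
r <- acmg_classify(annotation_bundle(
  population_af = NA,                      # absent from population databases
  predictor_scores = c(revel_like = 0.93, am_like = 0.88),
  clinical_assertion = "pathogenic",
  known_pathogenic_same_change = TRUE,
  in_hotspot_or_functional_domain = TRUE))
r
#> <acmg_result> pathogenic (5 criteria triggered: PS1, PM1, PM2, PP3, PP5)
glance(r)
#>   label      n_triggered n_pathogenic n_benign
#> 1 pathogenic           5            5        0
```

One strong criterion (PS1) with two moderate (PM1, PM2) satisfies the
pathogenic combining rule; `tidy(r)` lists each criterion with the
annotation and value that triggered it.

```r
st <- generate_synthetic_structure("helix", 20)
ft <- build_feature_tracks(st, 10,
  domain_table = tibble::tibble(start = 5L, end = 15L, label = "kinase-like"),
  predictor_score = 0.9)
#>   res_index aa    asa   rsa calpha_dist ss    domain
#> 1         1 A   120.  0.931        14.7 C     NA
#> 2         2 A    83.9 0.651        12.8 H     NA
attr(ft, "context_summary")
#> residue 10 (A): in domain 'kinase-like', alpha helix, RSA 0.50
#> (below protein average) -> pathogenic-leaning context
```

A buried residue (RSA below the protein average) inside an annotated
domain with a high predictor score reads as a pathogenic-leaning
context; `autoplot(ft)` draws the track stack.

A thin CLI wraps the same functions:

```sh
exec/oncotherapy fixtures  --seed 1 --out fx
exec/oncotherapy annotate  --in fx/toy.vcf --format vcf --kb fx/kb --out out/
exec/oncotherapy treatments --variant RET:p.M918T --kb fx/kb --out ret.json
exec/oncotherapy protein   --structure fx/helix.pdb --variant TOY:p.A8G --out tracks.tsv
```

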