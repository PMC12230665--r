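---
title: "Methods: variant interpretation, evidence harmonization, and protein context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant interpretation, evidence harmonization, and protein context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncotherapyr)
```

This vignette records the models, rules, and numerical choices behind
the package, including the design decisions that were genuinely open and
why they were settled the way they were.

## Variant model

Queries are accepted at three nomenclature levels — genomic
(`chr12:g.25245350C>T`), transcript (`NM_004985.5:c.35G>A`), and protein
(`KRAS:p.G12D`) — detected from the `g.`/`c.`/`p.` markers. Because
clinical knowledge bases print protein biomarkers without the `p.`
prefix ("KRAS G12A"), the space-separated shorthand is accepted too;
three-letter codes are normalized to one-letter at parse time and
parenthesized HGVS predictions (`p.(G12D)`) have their parentheses
stripped. All coordinates are 1-based (VCF/HGVS convention); exon
intervals are 1-based inclusive. The reference genome is carried as a
metadata label (default `hg38`); no sequence-level validation against a
genome FASTA is performed — that would require external sequence data
and is out of scope. When a query resolves to several transcripts the
package exposes all candidates and, where one must be chosen, uses the
lexicographically first rather than guessing a canonical transcript.

**Fusion frame rule.** With the last retained coding base of the 5'
partner at coding position $L$ (strand-aware) and the 3' junction base
at coding position $c$, the fusion is in frame iff
$L \bmod 3 = (c - 1) \bmod 3$: translation continues in the downstream
frame exactly when the retained 5' length ends where the 3' codon phase
expects it to. Breakpoints in UTRs or introns give `undetermined`. The
test suite sweeps every breakpoint pair across a two-exon toy gene pair
(both strands) against an enumeration oracle that walks the coding bases
one by one.

## Evidence harmonization

Three tab-separated dialects are supported, shaped after the public
somatic knowledge bases. Normalization runs in a fixed order — response
type, evidence tier, substitutes splitting, cancer type, drug class —
and is idempotent.

* **Response types.** CIViC-like significance values containing
  "Sensitivity" or "Resistance" map accordingly; OncoKB-like level
  codes `R1`/`R2` are resistant and `1`, `2`, `3A`, `3B` sensitive;
  MetaKB-like descriptive phrases are mapped by keyword stems
  (*sensitiv-*/*respon-* vs *resist-*). Everything else is `unknown`.
* **Evidence tiers.** Source codes map to the harmonized AMP/ASCO/CAP
  tier letters A–D through a flat, user-replaceable configuration file;
  the shipped table follows the published cross-knowledgebase
  harmonization (CIViC A–D/E, OncoKB 1/2/R1 → A, 3A/3B/R2 → B, 4 → D).
  Unmapped codes leave the tier unset with a warning — never an error —
  and the raw source code is always retained alongside, so the mapping
  is lossless.
* **Substitutes.** Therapy records listing interchangeable drugs are
  expanded into one single-drug record each; the drug multiset is
  conserved (a tested invariant).
* **Cancer types.** Exact case-insensitive matching against labels,
  synonyms, and main types always wins; otherwise similarity
  $1 - d_{\mathrm{edit}} / \max(|a|, |b|)$ (Levenshtein distance,
  computed via `utils::adist`; an independent dynamic-programming
  implementation serves as the test oracle) decides, with threshold
  0.85 by default and ties broken by the lexicographically smallest
  main type. The metric and threshold are configuration, not doctrine:
  no published value exists for this step, so the default is a
  documented guess that callers can override.
* **Drugs.** Labels are trimmed, case-folded, and whitespace-collapsed
  before classification lookup; this same normalization underlies the
  duplicate-merge key, which is why it lives in the harmonizer.

## Therapy matching

Five match types in decreasing specificity: exact change; different
exchange at the same residue; positional biomarker ("G12"); same exon;
gene-level ("mutation"). A record matching several rules gets the most
specific label, but broader matches are never suppressed — an exact hit
and a gene-level hit are both reported, as interpretation practice
wants the full evidence picture. Exon matching needs an explicit
transcript annotation (the residue is projected to its codon's genomic
interval and exon indices are compared); when several transcripts
overlap a gene the caller must pick one — the package does not guess.
Duplicate merging collapses records identical on (drug label, cancer
main type, tier, response, citation), unioning their sources. Sunburst
aggregation nests treatments along any ordered subset of
{biomarker, match type, drug class, drug, cancer type, evidence level,
response}; the citation layer is always the leaf, so leaf counts equal
treatment counts under every permutation (a tested invariant).

## ACMG classification

Only criteria computable from the package's annotation inputs are
implemented: PVS1, PS1, PM1, PM2, PM5, PP3, PP5 on the pathogenic side
and BA1, BS1, BP4, BP6 on the benign side. Segregation, de-novo, and
functional-assay criteria have no input channel here and are out of
scope. All numeric cutoffs live in a configuration file with
guideline-cited defaults: BA1 at allele frequency > 0.05, BS1 > 0.01,
PM2 < 1e-4 (or absent), per-predictor deleterious/benign score cutoffs
0.7/0.3, and a 0.75 consensus fraction of available predictors for
PP3/BP4. The combiner implements the guideline's combining rules; any
co-occurrence of pathogenic-side and benign-side evidence that the
rules do not resolve yields VUS, as does no evidence at all. The
combiner is a pure function of the triggered multiset; the test suite
checks all 2^11 criterion subsets against an independently encoded
oracle and verifies that adding pathogenic evidence never moves a label
toward benign. Note one deliberate property of the conflict rule:
adding PS1 to {BA1} moves the label benign → VUS, which is monotone in
the pathogenic direction even though neither side "wins".

Prioritization sorts pathogenic > likely pathogenic > VUS > likely
benign > benign with genomic position as the tie-break; predictor-score
sorts place missing scores last.

## Protein context

**ASA (Shrake–Rupley).** Each heavy atom gets `n_points` quasi-uniform
points (Fibonacci spiral) on its solvent-expanded sphere (van der Waals
radius + probe, probe 1.4 Å); a point is accessible iff outside every
other expanded sphere, and the atom's ASA is the accessible fraction of
4π(r+probe)². Defaults: 960 points, fixed element radii C 1.70, N 1.55,
O 1.52, S 1.80 Å. The implementation is in-repo rather than a wrapper
around an external DSSP binary — self-contained and directly testable;
quadrature accuracy is checked against the analytic sphere (isolated
atom, < 1% at 960 points) and a 10,000-point self-convergence rerun,
with errors measured on the accessible-fraction scale (each atom's own
expanded-sphere area as the unit), which is the scale on which the
quadrature actually operates.

**RSA.** ASA divided by the residue type's maximum reference ASA — the
theoretical Gly-X-Gly scale of Tien et al. (2013), shipped as an
editable table — and clamped to [0, 1]. Whether published tools clamp
is rarely stated; clamping keeps RSA interpretable as a fraction, and
both the scale and the clamp are configuration. Protein-average RSA
comparisons use the unweighted mean over residues with computed ASA.

**Secondary structure.** Three states (H/E/C), not the full 8-state
vocabulary: the feature track needs helix/sheet/coil. The amide
hydrogen is placed 1.01 Å from N along the bisector of the
N→C$_{prev}$ and N→O$_{prev}$ directions; the Kabsch–Sander
electrostatic energy
$E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol defines a hydrogen bond below −0.5 kcal/mol. Helix: runs of at
least two consecutive i→i+4 bonds mark residues i+1..i+4. Sheet:
residues in parallel or antiparallel bridge patterns. Assignment is
rigid-motion invariant (tested under random rotations).

**Bridges.** A disulfide candidate needs an alternate cysteine and
another cysteine's Sγ (or Cβ proxy) within 2.5 Å of the mutated
residue's equivalent atom; a salt-bridge candidate needs an alternate
charged residue and an oppositely charged terminal atom (Asp OD1/2,
Glu OE1/2, Lys NZ, Arg NE/NH1/2, His ND1/NE2) within 4.0 Å. Bridges
lost by removing a charged or cysteine side chain are reported
symmetrically. Both cutoffs are arguments; no published thresholds
exist for this screening step, so round structural-biology values were
chosen once. Histidine is counted as positively charged — the common
convention for salt-bridge screening at pH 7.

**Substitution chemistry.** Average residue masses, formal side-chain
charges, polarity/aromaticity sets, the helix-breaker pair {P, G},
Chou–Fasman β-sheet propensities, and Kyte–Doolittle hydropathy (the
shipped stand-in for unspecified "solubility" scales) come from a
replaceable packaged table; BLOSUM62 ships as a plain-text copy of the
canonical matrix and is cross-checked in the tests against the
Biostrings reference object.

**Context summary rule.** The one-line interpretation mirrors how the
tracks are read by eye: in-domain + buried (RSA below the protein mean)
+ predictor ≥ 0.5 → "pathogenic-leaning context"; no domain + coil +
exposed + predictor < 0.5 → "benign-leaning context"; anything else
indeterminate. It is a deliberately simple, documented heuristic — a
reading aid, not a classifier.

## Synthetic data

The fixture generators define the test conditions:

* `helix` / `strand_pair` / `hairpin` backbones are built by natural
  extension (NeRF) with ideal bond geometry (N–Cα 1.458, Cα–C 1.525,
  C–N 1.329 Å; ω = 180°) and canonical dihedrals: helix φ = −57°,
  ψ = −47°; strand φ = −139°, ψ = +135°; the hairpin turn is a type II'
  β-turn (φ,ψ = 60°,−120° / −80°,0°), which is what folds
  sequence-distant residues into spatial contact. The antiparallel
  strand pair places the second strand by a 180° rotation about an axis
  perpendicular to the strand direction plus a translation; the
  transform constants were derived once from canonical backbone
  geometry by maximizing the number of inter-strand hydrogen bonds at
  the canonical ~2.9 Å N···O register (calibrated on 8-residue strands,
  the fixture's default), then frozen. `cluster` scatters seeded
  single-residue copies around a central residue for burial
  experiments.
* The toy knowledge base (default 10 randomized records per source plus
  the guaranteed cases; ~200 records at `n_per_source = 63`) always
  contains one cross-source duplicate, one substitutes record, all five
  biomarker-specification kinds for a designated gene, one unmapped
  evidence code, and a gene-level RET record (selpercatinib, level 1,
  sensitive) exercising the whole-gene match type.
* Toy annotations give the three known driver loci
  pathogenic-looking bundles (absent population frequency, predictor
  scores 0.8–0.99, pathogenic assertions) and randomize the rest.

What these fixtures emulate is record *shape* and rule coverage, not
biological content: passing tests demonstrate that the parsing,
harmonization, matching, combining, and geometric machinery implements
its rules correctly, not that real-world knowledge-base content is
interpreted clinically correctly — real sources bring free-text
irregularities, assembly mismatches, and licensing-restricted fields
that are deliberately out of scope here.

## Problem sizes and determinism

The default suite runs structures of 8–20 residues (≈ 40–100 heavy
atoms) at 500–960 quadrature points, knowledge bases of up to ~200
records, and the full 2^11 ACMG subset enumeration — sizes chosen so
the whole suite exercises every rule path in well under a quarter hour
on a single core. All randomness is seeded; two runs with the same seed
produce byte-identical fixtures and pipeline outputs (a tested
invariant), and `scripts/acceptance.R --seed N` reproduces its JSON
exactly under a fixed seed.

## Known limitations

* Protein-level input only for therapy matching; DNA-level records
  match only after protein recoding (supplied by annotation tables).
* PDB input only, single chain at a time; no mmCIF.
* Three-state secondary structure; no 8-state parity with DSSP, no
  π-helix/3₁₀ distinction.
* The ACMG subset is the annotation-computable one; a clinical
  deployment would add curated criteria channels.
* Binding-site probabilities are inputs (precomputed tables), never
  predicted in-package.
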