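---
title: "Separating stable from labile insect P450s: methods and design notes"
author: "cypstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating stable from labile insect P450s: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypstab)
```

## The question and the model

Insect cytochrome P450s (CYPs) fall into two broad evolutionary regimes.
Some lineages are *stable*: they persist as one or a few orthologous copies
per genome, and tend to carry essential biosynthetic or developmental
functions (the moulting-hormone "Halloween" genes are the canonical
examples). Others are *labile*: they expand into species-specific
"phylogenetic blooms" of paralogs under environmental selection, notably
insecticide exposure, and are associated with xenobiotic detoxification.

`cypstab` operationalises this split with a simple paralog-count rule on an
ortholog-group table: a gene with $k \le 3$ same-species paralogs in its
group is classed *stable*, a gene with $k \ge 4$ is *labile*. Paralogs are
counted per species within the group by default, because cross-species group
members are orthologs, not duplications; a whole-group scope is available
(`scope = "group"`) for users whose grouping already collapses species.

Around that classifier the package computes, and statistically compares
between classes:

* **gene structure** from GFF3: gene length, exon count, total exon length,
  total intron length (gene length minus exon length), transcript count and
  GC content. For multi-transcript genes the transcript with the largest
  total exon length represents the gene (ties break to the smallest
  transcript id so the choice is reproducible). Coordinates are treated as
  1-based inclusive throughout, so every length is `end - start + 1`.
* **protein physicochemistry** in the Pepstats tradition: length, average
  molecular weight (residue masses plus one water), formal charge
  (D/E $-1$, K/R $+1$, H $+0.5$, B/Z $-0.5$), isoelectric point
  (Henderson–Hasselbalch with the EMBOSS pKa set, solved by bisection on
  pH 0–14 to $|q| < 10^{-4}$), the twenty residue frequencies, and the nine
  overlapping residue categories (Tiny, Small, Aliphatic, Aromatic,
  Non-polar, Polar, Charged, Basic, Acidic).
* **hydrophobicity** as the composition-weighted Kyte–Doolittle sum
  $H = \sum_{aa} f_{aa} \, h_{aa}$, where $f_{aa}$ is the residue frequency
  *in percent*. This makes $H$ exactly $100\times$ the classical GRAVY mean
  hydropathy; typical membrane-anchored P450s land around $-15$ to $-20$ on
  this scale, which is why the percent convention (rather than fractional
  frequency) is the one implemented.
* **signature motifs**: helix C `WxxR`, helix I `GxE/DTT/S`, helix K
  `ExLR`, `PERF` (`PxxFxPE/DRE`) and the haem-binding motif
  (`PFxxGxRxCxG/A`, containing the haem-ligating cysteine). Scanning
  reports every (possibly overlapping) occurrence; a separate anchoring
  step keeps at most one window per motif per protein, enforcing the N-to-C
  order of the five motifs. Conservation is profiled as a position
  frequency matrix with per-column information content
  $IC = \log_2 20 + \sum_r p_r \log_2 p_r$ bits. The haem profiling window
  is 15 columns — the 11-position pattern plus four trailing columns — so
  that a fully conserved labile window spans the entire
  `PFSAGPRNCIGQRFA`-style consensus; the trailing columns are profiled but
  not pattern-constrained.
* **redundancy culling**: pairs above 80% identity (global
  Needleman–Wunsch, BLOSUM62, gap open 10 / extend 0.5; identity =
  matches / alignment length including gap columns) are reduced greedily —
  the highest-identity pair is found and its shorter member removed (ties
  to the lexicographically larger id) until no pair exceeds the threshold.
  This "keep the longer representative" greedy is deterministic and
  idempotent; it is applied per class, after classification.
* **group statistics**: every feature is compared with a two-sided
  Mann–Whitney U test (midranks for ties; exact null distribution when the
  samples are tie-free and $n_x n_y \le 400$, otherwise a tie-corrected
  normal approximation with continuity correction). Families are corrected
  separately per table — 6 genomic features, 13 protein properties, 20
  residues — so the working thresholds at $\alpha = 0.05$ print as 0.0083,
  0.0038 and 0.0025. The *unrounded* $\alpha/m$ drives the decision; the
  4-dp value is display only. A Pearson $\chi^2$ (no Yates correction by
  default) serves for frequency tables such as the exon-count distribution.
* **annotation summaries**: per-term, per-class counts and percentages
  (denominator = class size, rounded half-up to 1 dp, also for per-species
  rows), plus an upper-tail hypergeometric over-representation test with
  Benjamini–Hochberg adjustment across terms. The package deliberately does
  *not* predict annotations; it consumes any gene-to-term table, curated or
  predicted, and reproduces the counting and testing arithmetic.

## The synthetic cohort generator

Because no deposited gene set accompanies the class set-points, the
package ships a seeded generator (`cohort_config()` / `generate_cohort()`)
that emits a complete input bundle — protein FASTA, per-gene contig FASTA,
GFF3, ortholog table, annotation table, truth labels — whose class
contrasts are the published medians:

| quantity | stable | labile |
|---|---|---|
| residue composition (%) | class median vector | class median vector |
| exon count (median) | 4 | 3 |
| total exon length (bp) | 1518 | 1524 |
| total intron length (bp) | 612 | 311 |
| GC (%) | 44.78 | 47.20 |
| haem window | pattern-sampled | fixed consensus `PFSAGPRNCIGQRFA` |
| annotation terms | e.g. development 55.1% | 31.1% |

Gene length is not drawn directly: it is the sum of the exon and intron
totals, matching how the analysis derives intron length. Protein length is
lognormal with mean 520 residues (the class molecular-weight medians around
58 kDa imply ~520–530 residues).

Design choices a user should know about:

* **Within-class variance.** The set-points are medians; no dispersion is
  published. Each drawn length quantity uses a lognormal coefficient of
  variation of 0.3 (user-overridable). Exon and intron *totals* are drawn
  with the CV of a sum of independent per-piece CV-0.3 draws
  ($0.3/\sqrt{n}$) and then split into pieces, which keeps gene length
  decoupled from the exon-count jitter ($\pm 1$ around the class median
  with probabilities 0.25/0.5/0.25). GC gets an absolute per-gene SD of 6
  percentage points — a CV rule is meaningless for a bounded percentage,
  and ~6 points matches the between-gene GC spread of mosquito genomes
  while keeping GC, as in the reference analysis, mostly below the
  corrected significance threshold.
* **Composition planting.** The default `composition_noise = "matched"`
  mode allocates each protein's residue counts from the class target by
  randomized largest-remainder rounding, after deducting the residues
  consumed by the planted motif windows (so the haem policy does not bleed
  into the composition contrast). The alternative `"multinomial"` mode
  draws background residues i.i.d. The matched mode is the default because
  several published class contrasts (e.g. Trp 0.95 vs 1.12%) are smaller
  than i.i.d. multinomial noise at realistic P450 length; a generator
  whose proteins sampled composition i.i.d. could not exhibit the very
  contrast that defines it. The flip side is stated plainly below under
  limitations.
* **Null features.** The transcript count and the residues Ile, Ser and
  Tyr are declared null: their targets are equalised across classes (the
  remaining residues are renormalised per class to sum to 100), giving the
  test suite genuine negative controls.
* **Motif placement.** The five windows sit at fixed fractional offsets
  (10%, 38%, 55%, 78%, 88% of the length), preserving the biological
  N-to-C order with the haem motif near the C-terminus; overlap is
  rejected, and the minimum protein length is clamped at 130 residues so
  the layout always fits.
* **Ortholog structure.** Stable genes are spread round-robin across
  species and grouped into cross-species groups with per-species family
  sizes of 1–4 (so $k \le 3$); labile genes are assigned in single-species
  blocks of 5–8 (species-specific expansion families, $k \ge 4$). The
  labile class therefore needs at least five genes.
* **Annotations** are Bernoulli draws per gene per term at the class
  proportion.
* Protein length is *not* forced to equal CDS length / 3; the analysis
  never cross-checks the two, and coupling them would distort either the
  protein-length or the exon-total set-points.

Everything is a deterministic function of the configuration (including the
seed): the same `cohort_config()` yields byte-identical files.

## What the simulations do and do not show

Two study wrappers drive the headline checks. `run_recovery_study()` (20
cohorts, 50 genes per class by default) asks whether the full
classify → features → compare path flags each designed contrast —
gene length, exon count, intron length, hydrophobicity, aliphatic%,
Cys/Leu/Trp/Arg up in stable, Glu/Lys/Met up in labile — as
corrected-significant with the planted direction, and whether declared null
features stay quiet. `run_null_study()` (200 cohorts with no planted
effect) estimates the per-family probability of *any* significant feature,
which Bonferroni control should keep at or below $\alpha$. Both disable the
culling stage: random-background proteins sit far below the 80% identity
threshold, so culling would be a no-op at considerable alignment cost.
These problem sizes (20 and 200 cohorts of 100 genes) were chosen as the
smallest at which the binomial noise on the reported rates is clearly
smaller than the margins being checked.

Passing these tests shows that the pipeline's arithmetic and decisions are
correct *under the generator's assumptions*. It does not show that real
CYP cohorts would give the same significance pattern: real proteins have
between-protein composition variance far above rounding noise (the matched
mode is optimistic in exactly this respect), real gene structures are not
lognormal with independent pieces, ortholog groups come from an inference
algorithm with its own errors, and annotation tables are biased and
incomplete. The generator emulates the *contrasts*, not the full
generative process, of real data.

## Numerical conventions and degenerate inputs

* Percentages print rounded half-up (so 55.15 → 55.2), thresholds to 4 dp,
  medians to 4 dp; decisions always use unrounded values.
* A constant combined sample yields p = 1 with a warning rather than an
  error; a feature whose groups empty out after NA removal is skipped with
  a warning.
* Ambiguity codes: B and Z participate in category counts and carry
  averaged masses and $-0.5$ charge; they are excluded (with a warning)
  from hydrophobicity and from pI, which have no published index or pKa
  for them. X is tolerated in composition but rejected for molecular
  weight.
* GC is computed over the full gene span, introns included, ambiguous
  bases excluded from numerator and denominator. The reference analysis
  sourced per-gene GC from a genome browser without stating the exact
  window; full-span is the documented approximation here, and the
  generator emits full-span sequence to match.
* An exon set whose total exceeds the gene span floors the intron length
  at zero with a warning instead of failing the whole run.
* Identity denominators: alignment length including gap columns by
  default; `denominator = "shorter"` is available.

## Known limitations

The composition-weighted hydrophobicity ignores folding; it is a
sequence-level proxy only. Motif anchoring takes the first
pattern-compatible window in N-to-C order, which can mis-anchor on
pathological sequences with early spurious pattern hits. The culling greedy
minimises redundancy deterministically but is not guaranteed to find a
*globally* minimum removal set on adversarial identity graphs (it does on
the duplicate structures the tests enumerate exhaustively). Enrichment
requires the user's annotation table; no ontology structure is traversed.
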