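---
title: "Models and methods behind ccvarscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ccvarscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccvarscan)
```

## The problem

Charge clusters are protein segments of 20–75 residues with a high
concentration of like-charged residues — Asp/Glu for negative clusters
(NCCs), Lys/Arg for positive ones (PCCs) — possibly interrupted by
uncharged residues but free of any residue of the opposite charge.
They are enriched in binding interfaces, transcription factors and
intrinsically disordered regions, which makes the genetic variation of
their coding sequence interesting: a substitution that flips or
removes a charge in such a segment is a strong candidate for a
functional change.

`ccvarscan` is a pipeline for asking, on any cohort of proteins, gene
models and variant records: where are the charge clusters; what do
their coding regions look like in the genome; how dense is variation
inside them relative to their gene context; and what kinds of
amino-acid exchanges do those variants cause?

## Cluster detection

### Scoring model

The cluster definition constrains the *shape* of a candidate window
(length in [20, 75], no opposite-charge residue, charged boundaries)
but leaves "high net charge relative to the protein's overall charge
composition" open to a choice of statistic. `ccvarscan` scores each
candidate window by the binomial tail probability of its same-sign
residue count:

$$p = P(X \ge k), \qquad X \sim \mathrm{Binomial}(w,\ p_0),$$

where $w$ is the window length, $k$ the number of same-sign residues
inside it, and $p_0$ the protein-wide frequency of that sign, floored
at `p0_floor = 0.05`. The floor prevents trivially tiny p-values in
charge-poor proteins, where a single short acidic run would otherwise
dominate; 0.05 is roughly the proteome-average frequency of one
charged sign, so the floor makes "enrichment" mean *at least*
enrichment against an average protein. Windows with $p \le \alpha$
(default `alpha = 0.01`) are significant.

### Disjoint selection

Significant windows overlap heavily, so the reported set is the greedy
disjoint selection: repeatedly accept the window with the smallest
p-value — ties broken by longest, then leftmost — and discard every
window overlapping it. This is deterministic, order-independent, and
reproduced exactly by a brute-force oracle in the test suite for
sequences up to 300 aa.

Two consequences of the design are worth stating plainly:

* boundaries are tight — candidate windows must start and end on a
  charged residue, so clusters are never padded by neutral flanks;
* $\alpha$ is a *per-window* level, uncorrected for the $O(L)$
  candidate windows of a protein. On i.i.d. null sequences the
  per-protein discovery rate is therefore a small multiple of
  $\alpha$ (empirically a few per cent at $\alpha = 0.01$); the test
  suite bounds it at $10\alpha$. Detection is a screening step, not a
  family-wise-error-controlled test.

Non-standard residue codes (B, Z, X, U, `*`) score 0 — they never
block a window — and each occurrence is logged as a warning so inputs
can be audited.

## Coordinate projection

Gene models are one transcript per gene in 1-based fully-closed
genomic coordinates (the GenBank convention); BED12 output converts to
0-based half-open. A cluster's residue interval $[a, b]$ maps to CDS
nucleotides $[3a-2,\ 3b]$ and then, through a per-base exon map, to
genomic blocks. The per-base map makes mid-codon exon junctions a
non-event: a codon straddling a junction simply contributes bases to
two blocks. On the minus strand CDS position 1 is the highest genomic
coordinate of the CDS.

Each mapped cluster carries four nested context regions used for
density comparisons:

| region | definition |
|---|---|
| `cluster_exonic` | the cluster's genomic blocks |
| `cluster_exonic_plus_intronic` | contiguous span from first to last block |
| `full_mRNA` | union of all exons |
| `gene` | the annotated gene span |

The exonic+intronic region is read as the *contiguous genomic span*
of the cluster, so it includes every intron interleaved between the
blocks. For clusters spanning two or three exons — the only cases that
occur at realistic exon-span mixtures — this is equivalent to adding
only the interrupting introns.

## Variant classification

Alleles are first reduced to their minimal anchored representation
(shared trailing then leading bases trimmed, at least one base kept),
then typed by length relation: SNV, insertion, deletion, or MNV for
equal lengths above one. One molecular consequence is called per
variant using the severity precedence

`splice_region > stop_gained > stop_lost > frameshift > inframe >
missense > synonymous`,

with the splice region defined as the 2 nt canonical donor/acceptor
dinucleotides of each intron. Coding SNVs and MNVs are resolved by
mutating the affected codon(s) and translating both versions; indels
are frameshift when their length change is not a multiple of three. A
ref allele that disagrees with the genome is a hard error, not a
warning — silent reference drift is the classic failure mode of
variant re-annotation.

Minor allele frequencies are binned into `[0, 0.005)`,
`[0.005, 0.01)`, `[0.01, 0.05)`, `[0.05, 0.5]`. The source material
prints these as overlapping closed intervals; half-open edges are used
so that the bins form a partition. Frequencies below 0.005 are
"rare". An absent frequency is `unspecified` and excluded from bin
proportions, mirroring how unspecified records are discarded from
clinical-class proportions. Clinical labels collapse onto a
pathogenic spectrum (pathogenic, probably/likely pathogenic, risk
factor), a benign spectrum (benign, likely benign), and `unspecified`
for everything else.

## Amino-acid exchange analysis

The 20 residues partition into hydrophobic (A, V, L, I, M, F, W, P),
polar (G, S, T, C, Y, N, Q, H), acidic (E, D) and basic (K, R)
groups. Protein-change strings (HGVS.p short form, 3- or 1-letter
codes) are parsed into substitution, synonymous, insertion, deletion,
frameshift, stop-gained and stop-lost records. Substitutions fill a
4×4 source-by-destination group matrix plus per-residue loss/gain
vectors; insertions and deletions are attributed per affected residue
(an insertion of `EEK` adds two acidic and one basic count), and
stop-involving substitutions sit in a side tally because the stop
symbol has no group. The grand total of the matrix always equals the
number of substitution records — a conservation law asserted in the
tests.

## Density statistics

The variant fraction of a region is the exact ratio of overlapping
variant count to region length in nucleotides (0.25 = one variant
every 4 bp). Cluster-level fractions — not pooled counts — are the
observations for the one-way ANOVA across the four region classes,
so every cluster contributes equally regardless of gene size; Tukey
HSD (with the Tukey–Kramer correction for unequal group sizes)
locates the pairwise differences. Chi-square homogeneity tests
(Pearson, no continuity correction) compare categorical tallies;
expected counts below 5 log a warning but do not abort. No
multiple-testing correction is applied across the report's tests.

## The synthetic-data generator

Every stage is validated by parameter recovery on cohorts with planted
ground truth. The generator's defaults are the study conditions the
package tests itself against:

* cluster lengths: truncated normal, mean 24.2 / sd 3.9 aa (negative)
  and 27.8 / 7.6 aa (positive), bounded to [20, 75], sampled by
  rejection. Note the lower bound truncates about 14% of the
  negative-length distribution, so the *realized* mean is about 1 aa
  above the location parameter — the tests compare against the
  truncated distribution's analytic mean;
* within-cluster same-sign density 0.55, background charged-residue
  frequency 0.02 per charged residue type; one opposite-sign residue
  is written immediately on each side of a plant so detected
  boundaries stay tight;
* exon-span mixture for the cluster's coding sequence: 67% one exon,
  31% two, 2% three; an extra intron lands outside the cluster with
  probability 0.4 so single-exon clusters still occur in multi-exon
  genes;
* nucleotide variant types: 80% SNV, 12% deletion, 8% insertion
  (deletions outnumber insertions roughly 3:2 at the nucleotide
  level; the protein-change level uses 3:1);
* ExAC-style MAF bins: 78% (negative) / 85% (positive) in the rare
  bin among specified records; 15% of records carry no frequency;
* protein-change categories: 55% substitution, 28% synonymous,
  12.75% deletion, 4.25% insertion (the 17% indel mass split 3:1);
  affected residues weighted Glu 34.5%, Asp 22%, the remainder
  uniform over the uncharged residues; acidic-source substitutions
  go to polar residues 42% of the time; insertion lengths put 54% of
  the mass on a single residue with geometric decay to twelve, and
  88% of inserted residues are acidic.

Back-translation uses uniform synonymous codon choice — codon-usage
bias is irrelevant to every statistic computed here. Intron and
intergenic sequence is uniform random DNA; splice-site motifs are not
simulated because consequence calling is positional, not
motif-based.

What the generator does *not* emulate: mutation-rate heterogeneity
along the genome, linkage between variants, population structure,
multi-isoform genes, and real splice-site sequence. Passing the
recovery tests therefore shows that the pipeline measures what was
planted — it does not show that real human cohorts satisfy the
planted laws.

## Numerical and degenerate-input choices

* `window_pvalue` uses the exact binomial tail (`pbinom` upper tail),
  never a normal approximation.
* Greedy selection ties (equal p, equal length) resolve leftmost, so
  output is reproducible across platforms.
* A zero-length region is an argument error for the variant fraction;
  an all-constant ANOVA input (zero within-group variance) is a
  degenerate-input error rather than an infinite F.
* An empty variant set short-circuits the report: tallies are zero,
  the fraction table is all zeros and the test block carries a
  `degenerate` flag instead of an ANOVA.
* The ANOVA type-I property is checked on an exchangeable null —
  equal planted density on equal-length regions — so that the check
  exercises the statistical stage itself. On nested regions of very
  different lengths, binomial variance differences make fraction
  variances unequal across groups; with balanced group sizes the F
  test is robust to this, but the nominal-rate guarantee is only
  claimed for the exchangeable case.

## Problem sizes used in validation

The shipped validation uses cohorts of 2000 simulated genes for the
exon-span recovery, at least 5000 variants or protein-change records
per mixture-recovery check (3000 for the insertion length spectrum),
1000 random gene models for the coordinate round-trip, 1000 random
coding SNVs for the consequence-caller oracle, and 500 replicates for
the ANOVA type-I rate. Each planted proportion must be recovered
within three binomial standard errors of its configured value.

## Known limitations

* One transcript per gene; alternative isoforms are out of scope.
* Mixed-charge clusters (high total charge of both signs) are not
  detected — only single-sign clusters.
* The splice region is the minimal 2 nt definition; extended
  splice-region windows (as in VEP) are not used.
* The detector's per-window alpha is uncorrected (see above).
* Real-data headline counts depend on the database release queried;
  the package reproduces classifications and statistics, not any
  specific release's totals.
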