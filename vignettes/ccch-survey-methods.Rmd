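---
title: "Methods behind the CCCH family survey pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the CCCH family survey pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccchfamily)
```

# Scope

CCCH zinc-finger proteins carry one to six `C-X(m)-C-X(n)-C-X(3)-H`
motifs and act on mRNA metabolism; plant genomes hold dozens of family
members whose survey requires a recurring set of computations: motif
detection and classification, subfamily assignment, nuclear-export
signal (NES) and tandem zinc-finger (TZF) architecture detection,
duplication typing of paralogous pairs, Ka/Ks selection analysis, and
paralog expression-divergence categorization. This vignette documents
how each step is modelled, the tunable parameters and their defaults,
the numerical conventions, and what the validation on synthetic data
does and does not establish. The package is an R library: its
functions, this vignette and `scripts/acceptance.R` are the interface;
no shell executable is shipped.

# Motif scanning

A motif is a geometric pattern: cysteines at offsets 0, `1+m`, `2+m+n`
and a histidine at `3+m+n+p` from the start. Spacer residues (the X
positions) are **unrestricted** — the notation implies no constraint —
which matters on cysteine-rich sequences, where spacers may themselves
contain C or H. Defaults cover the classes described in plant
families: `m` in [4, 15], `n` in [4, 6], `p` fixed at 3 (every named
class ends `C-X3-H`; the range stays configurable).

Published family tables report only per-protein motif *counts*, so an
overlap policy had to be chosen. The default `greedy_nonoverlap`
sweeps left to right; at each C all in-range geometries are evaluated
and the smallest-span candidate wins (ties to smallest `m`), its span
is consumed, and scanning resumes after it. This makes counts
well-defined and reproducible. An `all_matches` mode returns every
geometric occurrence so users can audit the greedy choice. The scanner
is validated against a brute-force enumerate-then-sweep oracle on
random sequences (100 seeded 300-mers in the acceptance suite).

Class labels: (7,5,3) and (8,5,3) are *conventional*; the catalogue of
classes regarded as present in the *Populus* family additionally holds
(5,4,3), (7,4,3), (8,4,3), (8,6,3), (9,5,3), (11,5,3) and the
*Populus*-unique (11,6,3), while (10,5,3) — reported in *Arabidopsis*
and rice — is flagged as absent. The catalogue is an argument of
`classify_motif()`, not a hard-coded fact.

# Subfamily assignment

The CCCH-a…e taxonomy is defined on motif compositions: a = 1–3 ×
(7,5,3) only; b = 1–6 × (8,5,3) only; c = 2–3 motifs mixing both
conventional classes; d = exactly one (5,4,3) plus exactly one of
(7,5,3)/(8,5,3)/(10,5,3); e = any remaining composition containing a
non-conventional motif. The published rules overlap, so
`assign_subfamily()` applies them in the fixed precedence **d → c → a
→ b → e**, chosen so the more specific composite rules win; the
matched rule is recorded in the returned rationale. Two deliberate
readings: the "2–3" bound of CCCH-c limits the *total* motif count
(the per-class reading would admit up to six motifs, contradicting the
composite nature of the rule), and only-conventional compositions
outside the stated ranges are returned `unclassified` rather than
forced, because the count ranges are treated as definitional. The
phylogenetic 13-subfamily classification of the *Populus* family is
tree-based and outside this package's scope.

# NES and TZF detection

The NES consensus `[LV]-x(2,3)-[LIVFM]-x(2,3)-L-x-[LIMTKD]` spans 9–11
residues. All match start positions are reported; at a start where
both spacer widths fit, the shortest instantiation is recorded (ties
between the two 10-residue combinations go to the shorter first
spacer). Only the per-protein boolean feeds the survey tables; the
full match list supports auditing. The implementation enumerates slots
directly and is checked against an independent PCRE lookahead oracle.

A TZF architecture is two identical (8,5,3) motifs separated by a
fixed spacer. "Separated by 18 amino acids" is measured from the H of
the first motif to the first C of the second, exclusive on both ends —
the source material does not define the endpoints, so the convention
is documented here and the spacing is a parameter. The five residues
preceding the first motif (the lead-in, part of the RNA-binding
surface in characterized TZF proteins) are extracted for reporting
only: published lead-in consensus descriptions are too ambiguous to
encode as a filter.

# Physico-chemical parameters

Molecular weight is the sum of average residue masses plus one water.
The isoelectric point solves the Henderson–Hasselbalch net-charge
balance over the termini and the D, E, C, Y, H, K, R side chains by
bisection on [0, 14] to |charge| < 1e-4. The pKa set is the EMBOSS
default (N-term 8.6, C-term 3.6; K 10.8, R 12.5, H 6.5, D 3.9, E 4.1,
C 8.5, Y 10.1): the constants of the desktop tools used by older
surveys are unpublished, and different reputable pKa tables shift pI
by up to a few tenths of a pH unit — comparisons against published pI
columns should allow ±0.3. Unknown residues (X) either raise an error
or are skipped with a warning, per argument.

# Duplication typing

Pairs are typed **W** (segmental: both gene intervals fully inside the
two sides, in either orientation, of a single homologous block pair),
else **T** (tandem), else **O**. Three conventions are ours where the
source rules are silent: W takes precedence over T (a tandem-looking
pair inside a block pair is W); the 100-kb tandem distance is measured
between the nearer gene ends (0 when intervals overlap), not
midpoints; and block containment requires full inclusion of both gene
intervals — partial overlap does not count. The tandem rule itself is
standard: at most 5 intervening gene loci (locus-index difference
minus one), at most 100 kb, and protein similarity of at least 80 %.

Similarity comes from an in-house affine-gap Smith–Waterman with the
EBI/EMBOSS `water` defaults (BLOSUM62, gap open 10, gap extend 0.5).
A gap of length L costs `open + L·extend`, which is also the
Biostrings convention, so scores are cross-checked in the tests both
against `pairwiseAlignment` and against exhaustive alignment
enumeration on toy pairs. Traceback is deterministic: highest cell,
ties to the smallest row then column, moves preferred diagonal > up >
left. `similarity_pct` counts identities plus positive-score
substitutions over alignment columns, as the EBI tool reports.

# Ka/Ks estimation

The counting method is Nei–Gojobori (1986) with Jukes–Cantor
correction — adopted as the standard simple method because the survey
literature this pipeline serves typically cites Ka/Ks without naming
an algorithm. Codon alignments are built by threading a global
(Needleman–Wunsch) protein guide alignment back onto the CDSs; gap
columns and codons with stops or ambiguous bases are dropped with a
logged count rather than imputed.

Site counting enumerates the three single-nucleotide changes at each
codon position; changes producing stop codons are excluded from the
averaging denominator, and site totals are averaged over the two
sequences, so S + N = 3 × codons always. Multi-substitution codons are
averaged over the orderings of single steps with equal weight;
orderings passing through a stop codon are excluded (all retained if
every ordering hits a stop) — the same stop-avoidance convention as
the site counts. Proportions p ≥ 3/4 make the Jukes–Cantor log
undefined; these are flagged explicitly instead of returning NaN. The
selection call is `purifying` for Ka/Ks strictly below 0.5 — the
interpretation threshold used in plant paralog surveys — with the
boundary value itself classed `relaxed_or_positive`; the conventional
neutrality threshold 1.0 is available via the `threshold` argument.

# Expression divergence

Probe-level matrices are collapsed by per-gene median (genes sharing a
probe set get identical rows). Gene-wise normalization is the row
z-score with sample SD (n − 1); the desktop clustering tools this
mirrors do not document their convention, so the sample SD was fixed
here once. Clustering is average linkage (UPGMA) on 1 − Pearson r via
`stats::hclust`; tie handling follows `hclust`'s own convention, and
the tests validate merges against a naive agglomeration oracle that
recomputes every between-cluster average each step (ties have measure
zero on the continuous matrices used). An optional log2
pre-transformation is off by default because input scale varies by
platform.

"Expressed in a tissue" is not defined by the surveys that report the
four divergence categories, so it is operationalized as: normalized
value > tau, default tau = 0, i.e. above the gene's own mean. Reports
carry the tau used. The four categories are pure set relations on the
two expressed-tissue sets — 1 disjoint (not both empty), 2 identical
(two empty sets are category 2, flagged), 3 proper subset (direction
recorded, category symmetric), 4 partial overlap. qPCR quantification
uses ΔCt (2^−(Ct_target − Ct_reference)): only a reference gene is
specified in the protocols mirrored here, not a calibrator sample, so
ΔΔCt would be under-determined.

# Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with ground
truth, under a single integer seed (identical arguments + seed give
byte-identical output, and the caller's RNG state is restored).

*Proteomes.* Backgrounds are drawn uniformly from the 16 residues
excluding C, H, L and V: without C/H no accidental motif geometry can
occur, and without L/V no accidental NES (the consensus needs [LV] at
its first slot and a literal L downstream), so planted-feature truth
is exact — recall and precision 1.0 are provable properties of the
construction, and the tests confirm them. Planted features are
separated by at least one background residue. NES instances use x
residues avoiding all consensus class letters so each instance matches
at exactly one start. The default motif mixture weights the two
conventional classes at 0.4 each and (5,4,3)/(8,6,3) at 0.1 each,
with 1–3 copies per protein — echoing the dominance of conventional
motifs in real families. This background is deliberately unrealistic
(no compositional bias, no homology); passing recovery tests
demonstrates correctness of the scanners' logic, not performance on
real proteomes, where motif geometry is rarer but C-rich regions can
make the overlap policy matter.

*Gene maps.* Genes are laid out with 150–300 kb inter-gene gaps
(comfortably failing the tandem distance rule), tandem arrays use
10–30 kb gaps (satisfying it), and block pairs are intervals with
1 kb margins around matched gene runs. Real synteny — inversions,
partial block retention, nested duplications — is not modelled; the
map exists to exercise the W/T/O decision logic, not to simulate
genome evolution.

*Codon pairs.* The substitution process proposes uniform random
single-nucleotide changes, rejects stop-creating proposals outright,
accepts synonymous proposals always and nonsynonymous ones with
probability ω; the accepted count is Poisson with mean
codons × `expected_sub_per_codon` (default 0.25, a moderate divergence
where Jukes–Cantor corrections are mild). This acceptance-thinning
scheme is not a GY94-style codon model — it has no transition/
transversion bias and no rate heterogeneity — but its realized dN/dS
matches ω in expectation, which is exactly what the NG86 recovery
property needs: the acceptance run checks that the median estimate
over 200 replicates of 300 codons lies within ±20 % of ω at ω = 0.1
and 0.3.

*Expression.* Each planted pair draws category-consistent tissue sets
with cardinalities 2–4 out of six labels; rows are +1 on the set, −1
off it, plus Gaussian noise. The cardinality bound keeps the
above-mean threshold margin at ≥ 2/3 of the signal step, so at the
study's noise level (SD 0.2) misclassification is rare and the ≥ 95 %
recovery property holds with headroom; at zero noise recovery is
exact. Real microarray noise (probe effects, saturation,
heteroscedasticity) is not modelled.

# Numerical and formatting conventions

Coordinates are 1-based inclusive in all tables; scanner outputs use
0-based starts in R structures and 1-based positions in written
reports. Lowercase FASTA input is uppercased silently; a trailing `*`
stop in protein FASTA is stripped with a message. Locus ranks are
per-chromosome by start coordinate, ties broken by gene id with a
message. POPTR-style locus identifiers map their 4-digit field 0001–
0019 to linkage groups I–XIX; any other value becomes
`scaffold_<n>` — the scaffold label format is this package's
convention, as the source tables never print one. All percentages are
reported to one decimal. Reports are TSV with a `#`-prefixed YAML
front matter recording thresholds, seed and package version, so
re-running a configuration reproduces files byte-identically.

# Validation problem sizes

The test and acceptance suites use: 100 seeded 300-mers for the
scanner-vs-oracle equality; exhaustive alignment enumeration on toy
pairs of length ≤ 5 (local) and ≤ 6 (global) over a 4-letter alphabet,
plus BLOSUM62 score cross-checks against Biostrings on random protein
pairs; 200 replicates × 300 codons per ω for Ka/Ks recovery; 200
planted pairs at noise SD 0.2 for expression-category recovery; and
5-row matrices against the naive clustering oracle. These sizes give
stable medians and exhaustive coverage where enumeration is feasible
while keeping the default check fast.

# Known limitations

- The NES census of a real family requires the real sequences; the
  package ships only the printed characteristics tables, so that audit
  is left to users who supply the family FASTA.
- NG86 underestimates divergence at high saturation; pairs with
  p ≥ 3/4 are flagged undefined rather than extrapolated.
- The greedy overlap policy is one defensible convention; on C-rich
  sequences `all_matches` should be consulted before comparing counts
  across studies.
- pI values depend on the pKa table; cross-tool agreement beyond
  ±0.3 pH units should not be expected.
- The expression "expressed set" threshold tau = 0 is a modelling
  choice; category assignments can change with tau, which is why every
  report records it.
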