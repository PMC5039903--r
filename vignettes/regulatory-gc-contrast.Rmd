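---
title: "Contrasting regulatory-region GC content between trait groups: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrasting regulatory-region GC content between trait groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisScan)
```

# The analytical problem

Gene regulatory regions — the few kilobases upstream of a transcription
start site — carry transcription-factor binding motifs and a base
composition that may covary with expression. For a clock gene such as
*PER1*, whose promoter is activated by CLOCK/BMAL1 dimers through E-box
hexamers (CACGTG), a natural comparative question is whether any feature of
the upstream sequence separates species by an activity trait (diurnal vs
nocturnal) rather than by phylogeny. cisScan implements the three analyses
such a study needs on one aligned regulatory region across species:

1. **Motif conservation** — locate E-boxes in a reference sequence, project
   them through the alignment, classify every taxon's state, and ask
   whether any motif position partitions the taxa by trait.
2. **Phylogeny** — a maximum-likelihood tree under HKY85 with
   discrete-gamma rate variation, with bootstrap supports and a
   trait-monophyly test: does the tree group species by trait or by
   ancestry?
3. **GC contrast** — whole-region and sliding-window GC content compared
   between trait groups with Welch's *t*-test under Bonferroni family-wise
   control, and detection of contiguous significant "core" windows.

A phylogenetic sequence simulator with position-dependent base composition
generates alignments with planted ground truth, so every stage is testable
end to end without any external data.

# Input model and conventions

The central object is a `RegulatoryAlignment`: equal-width IUPAC DNA rows
(uppercase, `-` gaps) paired one-to-one with a metadata table (`id`,
`species`, `group` ∈ {Haplorhini, Strepsirrhini, outgroup}, `behavior` ∈
{Diurnal, Nocturnal}). Outgroup rows are flagged `in_primate_tests =
FALSE` and never enter statistical contrasts; they only root the tree.
All column coordinates in inputs and outputs are **0-based, half-open**
(BED convention). `U` is rejected: the package handles genomic DNA.
Soft-masked (lowercase) input is uppercased so masking cannot perturb GC
counts.

# Trimming

Two column filters are provided.

* `trimGappyout()` removes gap-rich columns. The default **fixed** mode
  drops every column whose gap fraction exceeds `gMax` (default 0.2) — a
  transparent, reproducible rule. The **auto** mode chooses the cut from
  the data: distinct gap scores (1 − gap fraction) are sorted ascending,
  the curve (fraction of columns removed → gap score) is formed, and the
  cut is placed at the point of maximum increase between consecutive
  slopes; columns strictly below the cut score are removed. This is a
  documented, deterministic rule in the spirit of alignment-trimming
  tools' gap-profile heuristics; it is not a bit-exact replica of any
  particular tool, and users with external trimming pipelines can feed
  pre-trimmed alignments. With fewer than three distinct gap scores the
  slope rule is undefined and all columns are kept.
* `completeDeletion()` retains exactly the columns in which every row is
  one of A/C/G/T — the matrix used for tree building. Ambiguity codes
  (including heterozygous calls like S) count as missing here, but are
  *not* gaps for the gap-fraction rule.

Both return the kept-column map (strictly increasing original indices) so
window and core coordinates can be projected back to the untrimmed
alignment, plus per-sequence aligned and ungapped lengths
(`trimmedLengths()`), since published per-species "length after trimming"
figures can mean either.

# GC content and the window scan

`gcContent()` counts G+C over A+C+G+T; gaps and *all* ambiguity codes are
excluded from numerator and denominator (an S is not half a G), and a
window with no valid base is undefined rather than zero. The scan
(`groupWindowTests()`) uses full windows only, at starts 0, step, 2·step,
… while start + window ≤ ncol; defaults are a 500 bp window and 25 bp
step, the classic operating point for regulatory-region GC profiles. Per
window and group it reports n, mean, SD and the 95% CI half-width of the
mean (t-quantile form), then Welch's two-sided *t*-test between the two
trait levels.

Multiplicity is controlled by Bonferroni: the threshold is α/m where **m
counts only testable windows** (both sides with ≥ 2 defined values) — a
window where a group drops to one sequence (e.g. a shared deletion)
consumes no share of α. With α = 0.05 and an alignment yielding m ≈ 113
windows the threshold is ≈ 0.00044, the operating point reported in
comparative *PER1* work. `detectCoreRegions()` merges maximal runs of
significant windows whose starts differ by exactly the step; a core spans
first start to last end and carries its mean group GC difference.

Degenerate inputs are defined rather than fatal: two constant samples with
equal means give t = 0, p = 1; constant samples with different means give
an infinite statistic and p = 0; fewer than two values per side makes the
window untestable.

## What the Welch scan does and does not control

Bonferroni guarantees family-wise error control **when the per-window test
is valid**, i.e. when taxa are exchangeable within groups. Species are
not: close relatives share drift along internal branches, so the
within-group SD understates the sampling variance of a group mean
(phylogenetic pseudoreplication), and the scan is anticonservative on
tree-structured data. The package's test suite demonstrates both regimes:
on an exchangeable null (star phylogeny) the measured family-wise error
stays below α + 3 SE, while on a realistic primate tree the same null
produces a substantially inflated rate. This mirrors the caveat any
comparative GC contrast carries — a significant window is evidence of a
group difference, not proof that the trait rather than shared ancestry
produced it — and is why the companion phylogeny and monophyly analyses
matter. Phylogenetically corrected contrasts (e.g. generalized least
squares on the tree) are deliberately out of scope for the published
analysis path.

# Motif conservation

`findMotifSites()` reports exact, possibly overlapping matches on the
gap-stripped sequence in 0-based ungapped coordinates. CACGTG is its own
reverse complement, so one strand suffices; non-palindromic motifs are
searched on both strands with the strand recorded.
`motifConservation()` maps each reference hit to alignment columns
(skipping reference gap columns) and classifies every taxon: `conserved`,
`substituted` (offsets and from→to listed), `ambiguous` (IUPAC code
present), or `gapped`. `traitPartition()` asks, per motif position,
whether the observed characters split perfectly between the two trait
levels; taxa with gaps at the motif are excluded rather than treated as a
fifth character state — absence of the site is not an allele.

# Phylogeny

The tree machinery is self-contained and deliberately simple:

* **Starting tree**: neighbor joining (`njTree()`) on K80 distances
  (`k80DistanceMatrix()`); saturated pairs are flagged and capped,
  negative NJ branch lengths clamped to zero.
* **Likelihood**: HKY85 with empirical base frequencies (counted from the
  complete-deletion matrix, not ML-optimised — standard, cheaper, and
  exposed as a parameter object) and discrete-gamma rate variation with
  `nCategories = 4` equal-probability categories whose rates are the bin
  means (Yang's discretisation) and average exactly 1. Transition
  probabilities use the TN93 closed form — no matrix exponentials — and
  site patterns are compressed with multiplicities before Felsenstein
  pruning (the inner loop is compiled code). The rate matrix is
  normalised to one expected substitution per unit branch length.
* **Search** (`fitMLTree()`): alternate per-branch Brent optimisation
  (tolerance 1e-6 on the branch, bounds [1e-8, 10] substitutions/site),
  bounded 1-D searches for κ and (unless fixed) the gamma shape α on a
  log scale, and nearest-neighbor-interchange sweeps that accept only
  improvements — so the log-likelihood is monotone over accepted moves —
  until a full cycle gains < 1e-4 log units. The shape can be fixed
  (`fixedAlpha`), e.g. at a published estimate such as 1.9765, or
  profiled; both modes exist because published "G parameter" values
  rarely state which was done.
* **Bootstrap** (`bootstrapSupport()`): column resampling with a mandatory
  seed; each replicate restarts from the ML tree with the fitted
  substitution parameters held fixed, re-optimises branch lengths and
  sweeps NNIs. Support is the percentage of replicates containing each
  internal split of the reference tree; splits absent from the reference
  receive no entry.
* **Monophyly** (`monophylyTest()`): root at the outgroup, find the
  smallest clade containing all tips of each trait level; intruder count =
  clade size − level size.

Ties in NJ agglomeration follow the distance routine's deterministic
order; likelihood is invariant under re-rooting and tip order (reversible
model), which the suite checks, along with exact agreement between the
pruning recursion and brute-force enumeration over internal states on
small instances, and against an independent likelihood implementation.

Numerical notes: pattern likelihoods are computed without scaling, which
is safe for the tens-of-taxa, few-kilobase regime this package targets;
very large trees would need log-scaling. Branch lengths are bounded above
at 10 substitutions/site; the floor 1e-8 avoids log-of-zero at the
zero-distance limit.

# The simulator

`simulateAlignment()` evolves sites independently along a tree under HKY
with a **position-dependent equilibrium**: at site x the stationary
distribution is strand-symmetric with GC fraction g(x) (π~G~ = π~C~ =
g/2), g(x) a piecewise-linear profile. The default profile ramps from
0.55 distal to a 0.62 peak at 85% of the region — regulatory-region GC in
the mid-50s to low-60s rising toward the gene, with the maximum placed
near the third (most proximal) planted E-box. The root sequence is drawn
from the site-wise stationary distribution, so tip composition tracks
g(x) regardless of branch lengths (the suite regresses windowed tip GC on
windowed g and requires slope within [0.8, 1.2]). Per-site rates are
discrete-gamma draws (shape default 1.9765, matching the inference
default); κ defaults to 3, a typical mammalian noncoding
transition/transversion ratio.

**Trait-linked cores.** A core is an interval whose equilibrium is
depressed by δ on the branches of the affected trait's maximal subtrees —
a stylised model of convergent compositional evolution (e.g. sustained
biased substitution) in the lineages carrying the trait. A pure
equilibrium shift realises only 1 − e^(−λt) of δ at the tips, which for
realistic primate branch lengths is a small fraction; the shift is
therefore modelled as **having reached its new equilibrium at the origin
of each affected subtree** (the subtree-root state at core sites is drawn
from the shifted stationary distribution, and within-subtree evolution
uses the shifted equilibrium). Every affected tip then carries the full δ
in expectation, with no additional tuning knob. This choice is what makes
a planted δ the quantity the scan should recover.

Planted motifs are overwritten after simulation (with optional per-tip
substitutions, including ambiguity codes for heterozygous sites) rather
than evolved under constraint — the downstream analysis only reads their
conservation state. Deletions become `-` runs in the configured tips; a
small-indel rate adds random 1–10 bp deletions if requested. Everything
is driven by one mandatory seed and is byte-reproducible.

Two presets encode the study scale the package targets:
`paperLikePreset()` (3.3 kb, the 15-taxon species fixture, a mild
region-wide nocturnal depression of 2 GC points — which reproduces the
published per-taxon GC span of the mid-50s to high-50s — deepened to 8
points in two nocturnal-linked cores, the first ending 223 bp upstream of
the first E-box and overlapped by a 130 bp deletion in three haplorhine
tips, plus three E-boxes with the classic singleton substitutions) and
`coreRecoveryPreset()` (4 kb, the 14 primates, one core of δ = 0.08;
δ = 0 gives the matched null). The species fixture's branch lengths are
plausible regulatory-region divergences (human–chimp ≈ 0.004,
primate–mouse path ≈ 0.5 substitutions/site), chosen once as part of the
study design.

**What the simulator does not emulate:** context-dependent (CpG) mutation,
insertions, alignment error (it emits the true alignment), selection on
motifs, and within-species polymorphism beyond planted ambiguity codes.
Passing recovery tests therefore show the pipeline detects the signal
structure it assumes; they do not certify performance on misaligned or
CpG-skewed real data.

# Problem sizes used in the validation suite

The suite exercises: exhaustive likelihood enumeration up to 5 taxa × 4
sites; window-scan recovery and family-wise error at 4 kb × 14 taxa with
200 null replicates; and tree recovery with 100 bootstrap replicates on
6-taxon, 5 kb strong-signal alignments — sizes at which every check runs
comfortably on a single core while matching the scale of the motivating
study design.

# Known limitations

* The Welch scan inherits the phylogenetic non-independence caveat above.
* No FDR or permutation alternatives on the default path — Bonferroni
  only, as in the published analysis the pipeline mirrors.
* No SPR/TBR tree searches and no model selection across substitution
  models; HKY+Γ is fixed by design.
* The gappyout-style auto cut is a documented stand-in, not a bit-exact
  replica of any external trimmer.
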