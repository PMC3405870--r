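---
title: "Detecting functionally divergent sites with symmetric KL information"
author: "klsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting functionally divergent sites with symmetric KL information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(klsite)
```

## The problem

When a gene family splits into functionally distinct subfamilies — for
example, signaling chemokine receptors (CKRs) versus decoy receptors that
bind chemokines without signaling, or virus-encoded receptor homologs with
constitutive activity — the sites whose functional constraints changed leave
a footprint in the alignment: the two subfamilies prefer different amino
acids there, while sites under shared constraints stay similar in both.
`klsite` scores that footprint column by column and then asks a structural
question: are the divergent sites biased toward the intracellular
(G-protein-facing) side of the receptor, as expected when signaling is lost,
or toward the ligand-binding pocket, as expected when ligand dependence is
lost?

## The site score

For one alignment column and one group of sequences, let \(p(i)\),
\(i = 1..20\), be the group's site-specific amino acid composition. The
divergence between two groups with compositions \(p\) and \(q\) is the
symmetrized Kullback–Leibler information

\[
D(p, q) \;=\; \sum_{i=1}^{20} p(i)\,\log\frac{p(i)}{q(i)}
      \;+\; \sum_{i=1}^{20} q(i)\,\log\frac{q(i)}{p(i)},
\]

which is zero iff \(p = q\), symmetric by construction, and grows with the
compositional separation. This is the two-group special case of the
cumulative relative entropy used for subfamily functional-divergence
detection (Hannenhalli & Russell 2000). The log base defaults to the
natural log (nats) and is configurable; selection is rank-based, so the
base never changes which sites are selected.

### Composition estimation

Raw column counts are a poor estimate of \(p\): databases over-sample some
lineages, and with tens of sequences many residues are never observed.
Two standard corrections are applied, in the PSI-BLAST tradition
(Altschul et al. 1997):

1. **Henikoff–Henikoff position-based weights** (Henikoff & Henikoff 1994).
   At a column with \(r\) distinct residue types, a sequence carrying a
   type shared by \(m\) sequences receives increment \(1/(rm)\); summed
   over columns and normalized, these weights down-weight redundant
   sequences. Weights are computed per group, because each group's
   composition is an estimate for that subfamily alone (pooled weighting is
   available as an option).

2. **Data-dependent pseudocounts.** With a substitution matrix \(s_{ij}\)
   and background frequencies \(P_i\), the ungapped scale \(\lambda_u\) is
   the unique positive root of
   \(\sum_{ij} P_i P_j e^{\lambda s_{ij}} = 1\), giving target frequencies
   \(q_{ij} = P_i P_j e^{\lambda_u s_{ij}}\). The pseudocount vector is
   \(g_i = \sum_j (f_j / P_j)\, q_{ij}\) for observed weighted frequencies
   \(f\), and the regularized composition is
   \((\alpha f + \beta g) / (\alpha + \beta)\) with
   \(\alpha = n_\mathrm{distinct} - 1\) (the column's independent-
   observation count) and pseudocount weight \(\beta = 0.1\) by default.
   Any \(\beta > 0\) makes every composition strictly positive, so the KL
   value is always finite.

\(\lambda_u\) is solved once per comparison alignment by Newton–Raphson on
the constraint function, maintaining a bracket with bisection fallback (the
constraint function is convex with \(g(0) = 0\), so the positive root is
approached from the right; the solver refuses matrices whose expected
background score is non-negative, for which no positive root exists). The
default matrix is BLOSUM62 with Robinson–Robinson (1991) background
frequencies — the PSI-BLAST defaults — for which the solved scale is the
familiar ungapped BLAST value 0.3176. Both matrix and background are
configurable, and NCBI-format matrix files can be read directly.

### Skip and selection rules

- A column where more than half of the pooled sequences are gapped is
  skipped entirely (`gap_majority`); such columns have no reliable
  composition. The fraction is unweighted and pooled over both groups.
- A column where one group has no residues at all (possible with unequal
  group sizes) cannot be compared and is skipped as `group_empty`.
- Evaluable columns are ranked by KL value and the top
  \(\lceil 0.05\, n_\mathrm{evaluable} \rceil\) are selected (quantile
  configurable). Ties at the cutoff break toward the smaller column index,
  so output is deterministic.
- Selected sites falling where the reference (structure-bearing) sequence
  is gapped are then dropped — they cannot be mapped onto the structure —
  so the final count may fall below the ceiling. The order (select first,
  then drop unmappable) deliberately mirrors the original procedure rather
  than re-ranking after exclusion.

Ambiguity codes (`X`, `B`, `Z`, ...) are normalized to gaps on input: the
composition model is a distribution over exactly 20 residue types. Columns
are indexed 1-based internally, the natural R convention; all user-facing
output reports reference residue numbers in the structure's author (PDB)
numbering.

## The structural axis and bias tests

Residues of the reference receptor are projected onto the axis joining the
geometric center of the extracellular loops plus N-terminal region with
that of the intracellular loops (Cα coordinates, unweighted means). The
C-terminal tail is excluded from the intracellular center because it
extends into the cytosol and would drag the center off the bundle; fusion
inserts (e.g. the T4 lysozyme of crystallization constructs) are excluded
from everything. Each residue's score is the inner product of the unit
axis vector (midpoint → extracellular center) with the vector from the
axis midpoint to its Cα: positive = extracellular side, negative =
intracellular, in Ångström. C-terminal residues *are* projected; they are
excluded only from the center computation.

As a sanity check on the axis construction, the distance from the axis
midpoint to the geometric center of the seven transmembrane helices is
reported (`tm_center_distance`); for CXCR4 (PDB 3ODU, chain A) with the
packaged region config this is about 3.3 Å, i.e. the midpoint sits
essentially at the bundle center.

The spatial-bias test compares projection scores of selected-site residues
against all remaining projected residues with a Welch (unequal-variance)
two-sample t-test — the default of R's `t.test`, which the implementation
wraps; the one-sided alternative `"less"` encodes intracellular bias. The
pocket-enrichment test converts per-comparison pocket-site counts into
ratios of the total selected sites and compares the two sets of ratios
(e.g. decoy-receptor vs viral-receptor comparisons) with a one-sided Welch
test, treating ratios as plain real samples; no binomial model and no
multiple-testing correction are applied, matching the original analysis.

### The packaged CXCR4 configuration

Region boundaries are configuration, not code. The packaged config for
3ODU chain A reconstructs GPCRDB-style element boundaries from the
receptor's Ballesteros–Weinstein anchor residues (N56^1.50^, D84^2.50^,
R134^3.50^, W161^4.50^, P211^5.50^, P254^6.50^, P299^7.50^) and the known
region membership of boundary residues; the C-terminal range is 303–328
and the lysozyme insert (numbered in the 1000s in that entry) is excluded.
Because the exact boundaries used originally are not recorded, the
3.3 Å midpoint check is reported with a boundary-choice tolerance of a few
tenths of an Ångström. The packaged pocket list contains the CXCR4
ligand-cavity residues annotated in the published comparisons; pocket
detection itself (CASTp) is out of scope. Coordinates are not bundled —
`fetch_reference_structure()` downloads the PDB entry on demand.

## What the synthetic generators emulate

`generate_alignment()` produces the statistical structure the scorer
assumes: two groups, i.i.d. columns, a shared per-column composition drawn
from a symmetric Dirichlet (concentration 0.5 by default, giving the
low-entropy columns typical of protein families), per-cell gaps, and a set
of *planted* columns where the groups' compositions separate with a
divergence parameter \(d\): group A mixes toward the shared composition
with its \(\{K,R,E,D\}\) mass removed, group B toward the uniform
distribution on \(\{K,R,E,D\}\). Two properties follow by construction:
at \(d = 0\) planted columns are statistically identical to unplanted ones
(so top-5% selection recovers them exactly at chance rate), and at
\(d = 1\) the supports are disjoint (maximal separation). The designated
reference sequence receives no injected gaps — it models the complete
structure-bearing sequence; injected reference gaps would silently unmap
planted sites. Columns listed as `majority_gap_sites` have
\(\lfloor n/2\rfloor + 1\) non-reference rows gapped, deterministically
crossing the skip threshold.

What the generator does **not** emulate: phylogenetic correlation among
sequences (no tree; sequences are exchangeable within groups), alignment
error, and site-to-site rate variation beyond what the Dirichlet induces.
Passing the planted-site benchmarks therefore demonstrates correctness of
the scoring machinery under the model's own assumptions, not robustness to
tree-structured redundancy — on real data that robustness rests on the
Henikoff weighting.

`generate_structure()` builds an idealized seven-helix Cα bundle with
loops beyond the membrane boundaries in canonical GPCR topology. The
default `"adjacent"` layout places each loop between the helices it
connects; the `"balanced"` layout instead spaces the three loops of each
side 120° apart with identical angular offsets on both sides, which makes
the two loop sets exact mirror images: with empty terminal arms the axis
midpoint then coincides with the TM-bundle center to machine precision,
giving an exact fixture for the geometry. Helix spirals are centered to
zero mean for the same reason. Structures round-trip through fixed-width
PDB text at the format's 0.001 Å precision.

Generators take an optional `seed`; when `NULL` they draw from the current
RNG state, so a single caller-level `set.seed()` governs a whole
simulation — library functions never reset the stream behind the caller's
back unless asked.

## Numerical choices and verification scale

- λ solver tolerance: residual \(\le 10^{-12}\) requested, \(10^{-9}\)
  guaranteed; verified against a closed-form two-letter model (root
  \(\log((1+\sqrt 5)/2)\)) and an independent bisection oracle on
  BLOSUM62.
- Welch results are cross-checked against the textbook formulae to
  \(10^{-10}\) on randomized samples.
- The test suite exercises planted-site recovery at 40+40 sequences × 300
  columns with 15 planted sites (recall and precision at the 5% cut), the
  chance-level null over 50 replicate generations, and the bias test's
  type-I error over 10,000 subset-null replicates — sizes chosen to make
  Monte-Carlo error small relative to the properties asserted while
  keeping the default suite fast.
- Degenerate inputs fail loudly: no positive λ root, coincident axis
  centers, all-gap groups, both-constant t-test samples, insertion codes
  in PDB input.

## Known limitations

- Two groups only; the multi-group cumulative relative entropy is a
  possible extension, not implemented.
- The 5% rule uses the ceiling of the evaluable-column count; percentile
  interpolation variants would select marginally different sets.
- Henikoff weights are computed over all columns, including later-skipped
  ones (per-group by default); the original procedure's choice on both
  points is unrecorded, so both are options rather than certainties.
- Results on real receptor families depend on alignment quality; the
  scoring assumes the alignment is given and correct.
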