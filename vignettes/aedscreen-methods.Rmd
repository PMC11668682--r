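---
title: "aedscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aedscreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aedscreen)
```

# The problem

The αβ T-cell receptor (TCR) only reaches the cell surface as a complete
TCR–CD3 octamer, so knocking out a TCR chain also removes CD3 and with
it the handle that bispecific T-cell engagers (such as blinatumomab)
use to redirect T cells. A *decoupled* TCR keeps the complex assembled
and CD3-responsive while silencing antigen-driven signalling. The
engineering route this package supports: find a conserved,
structurally permissive motif in the TCR germline (the `FGxGT` run at
the end of α-chain J genes, just outside CDR3), saturate it with a
degenerate-codon library, and read out a pooled FACS sort-seq screen to
find variants that stop responding to peptide while still responding
through CD3.

`aedscreen` implements every computational stage of that campaign and
pairs each with a synthetic generator so the full pipeline is testable
end to end with known ground truth.

# Germline motif discovery

**Alignment.** Germline J/V amino-acid segments are short and
near-identical, so the aligner is a progressive scheme with *exact*
pairwise steps: affine-gap Gotoh dynamic programming (BLOSUM62, gap
open 10, gap extend 1, a gap of length $L$ costing
$\mathrm{open} + L\cdot\mathrm{extend}$) over a UPGMA guide tree built
from pairwise identity distances (`stats::hclust`, average linkage).
Profile merges use mean-of-pairs column scores under the same gap
model. For two sequences the output is the exact pairwise optimum,
which is what makes an independent-oracle test possible; the heuristic
multiple aligners typically used for this task are not reproduced
bit-for-bit, and nothing downstream depends on their tie-breaking.

**Conservation.** Per alignment column: residue frequencies over
non-gap symbols (summing to 1), the modal residue — lexicographically
smallest among ties, for determinism — its frequency, and the gap
fraction over all rows. All-gap columns are flagged, with gap fraction
1 and undefined modal residue.

**Motif calling.** A window of length $k$ qualifies when every column
has gap fraction ≤ 0.5 (the motif must exist in most germlines) and at
most `max_wildcards` columns fall below the conservation threshold;
sub-threshold columns are rendered `x`. Overlapping qualifying windows
merge into maximal runs and leading/trailing wildcards are trimmed.
Defaults $k = 5$, threshold 0.85, one wildcard — the shape of the
FGxGT and WYxQ motifs. The source material never quantifies "highly
conserved"; these are package choices, exposed as parameters.
Conservation is computed pooled across species by default (the
cross-species alignment is the point of the exercise); per-species
profiles can be obtained by aligning per-species subsets.

**Filtering.** The engineering criteria demand the motif lie outside
the CDR loops and outside the α-chain connecting peptide motif (aCPM),
since aCPM mutations kill both binding and signalling. Motif columns
are mapped through each row's column map to ungapped coordinates and
any overlap with an excluded span, in any gene, removes the motif.
Coordinates are 0-based half-open throughout.

**Bundled fixture.** `synthetic_germline_set()` is a deterministic,
synthetic 15-sequence TRAJ-like set (no database material): a variable
CDR3-like prefix containing a fully conserved `DYKL` decoy, two
variable spacer columns, then `F G x G T` at 93–100% column identity.
The decoy exists precisely to exercise the exclusion filter.

# NNK library design

Degenerate codons expand through the IUPAC map; translation uses the
standard genetic code (no codon-usage weighting — not needed for
diversity accounting). NNK (N = A/C/G/T, K = G/T) yields 32 codons
covering all 20 amino acids with a single stop (TAG). Diversity is
counted at the amino-acid level with stop-containing combinations
excluded: two NNK positions give $32^2 = 1024$ codon combinations and
$20^2 = 400$ protein variants. The parent-identical variant arising
from NNK is included — 400 is exactly $20 \times 20$. Outputs are
sorted, so the design is order-stable and deterministic. Mutagenic
oligos are emitted directly as degenerate IUPAC strings with fixed
template flanks (codon-aligned spans enforced).

# The synthetic screen

The generator states a world and keeps it fixed; its defaults are the
conditions of the screen being emulated where stated, and a single
documented choice where not.

* **Library**: the 400-variant `FGQGT` NNK library. The cloning
  backbone `FEQWT` (libraries were built on an already-decoupled
  backbone) is included at elevated initial abundance
  (`backbone_weight = 40`, ≈ 9% of the pool — un-mutated template
  carryover at the scale routinely seen in nicking mutagenesis).
* **Cells**: $10^6$ per round (the transfection scale of the screen);
  initial abundance log-normal with σ = 0.5 to emulate cloning skew.
* **Phenotypes**: each variant gets latent `expression`,
  `dextramer_binding`, `peptide_response`, `blina_response` in [0, 1].
  Five planted decoupled variants draw expression ∈ [0.8, 1], peptide
  response ∈ [0, 0.05], blinatumomab response ∈ [0.85, 1]. A quarter of
  the remaining variants are non-expressors (Beta(1, 30) expression) —
  the motif sits at the αβ interface and radical substitutions often
  abolish surface expression. Ordinary variants draw Beta(2, 2)
  responses joined by a Gaussian copula with correlation 0.7: both
  readouts are NFAT-GFP reporter outputs of the same signalling
  machinery, so they co-vary, and that correlation is exactly why the
  blinatumomab arm can separate decoupled variants from dead ones.
  The ground-truth flag `is_decoupled` applies thresholds (peptide
  ≤ 0.15, blinatumomab ≥ 0.6, expression ≥ 0.5).
* **Gates**: multiplicative binomial model. The expression sort passes
  with probability `expression × dextramer_binding`; GFP-high gates
  with `expression × dose × response`, where dose is an Emax term
  `c / (c + EC50)` (peptide 0.1 µg/ml with EC50 0.03; blinatumomab
  12 ng/ml with EC50 2 — the screen's stated stimulus levels). GFP-low
  gates are exact complements, so cells are conserved per variant by
  construction. The real screen's P1–P4 gate geometry is not
  quantitatively specified anywhere; five named gates
  (`DEX_CD3`, `PEP_GFPhigh/low`, `BLINA_GFPhigh/low`) are this
  package's abstraction of its logic.
* **Rounds**: the sorted expression gate feeds two challenge aliquots
  (binomial 50/50 split); the peptide GFP-low output is expanded
  (multinomial resampling to $10^6$) and seeds the next of 3 rounds —
  the carried-forward population of the original design.
* **Reads**: read counts per population are `min(depth, cells)` — one
  read per cell below the depth, multinomial downsampling above it
  (which is what makes the error-0 round-trip test *exact* at small
  scale). Reads are single-end 75-nt synthetic amplicons: fixed flanks
  around the 15-nt motif, each variant's canonical (lexicographically
  first) NNK codons substituted, i.i.d. substitution errors at rate
  0.001, constant Phred-33 quality `I`. Paired-end overlap merging is
  deliberately out of scope — parsing is identical post-merge.

What the generator does **not** emulate: PCR amplification bias, index
hopping, chimeras, gate spillover/compensation, clonal interference or
growth-rate differences between rounds beyond gate passage. A green
recovery test therefore establishes that the calling rule recovers
planted signal under multinomial/binomial sampling noise and sequencing
error — not that it is robust to those unmodelled artefacts.

# Variant tracking

Reads are located by the fixed 12-nt template flanks around the motif
(≤ 1 mismatch per anchor at the expected offset, exact search as
fallback), then classified by the cleaning rule — a read passes only
if *no* variation occurs outside the targeted codons. Failures carry
exactly one primary reason in fixed order: anchor → frame →
low-quality → ambiguous base → off-target mutation → stop codon (the
quality and ambiguity checks are package extensions of the rule,
placed so that later checks only ever see clean codons; quality floor
Q20, configurable). Counting aggregates synonymous codons at the
amino-acid level — the screen reported variants as amino-acid motifs —
with frequency = count / column total and rank 1 the most frequent,
ties broken lexicographically.

Trajectories compare each variant's rank and frequency in a selected
population against the expression-sorted reference of the same round:
$\Delta\mathrm{rank} = r_{sel} - r_{ref}$ and
$e = \log_2\!\frac{f_{sel} + \varepsilon}{f_{ref} + \varepsilon}$ with
$\varepsilon = 1/(2\,\mathrm{depth}_{sel})$ — de-enrichment-safe
smoothing; variants unobserved in the selected column are flagged
missing, enter the enrichment with frequency 0, and take effective rank
$n_{obs} + 1$ for rank arithmetic (one past the bottom; nothing is
imputed into the trajectory record itself).

# Candidate calling

The decoupling score is $D = e_{BLINA} - e_{PEP}$, and candidates must
satisfy all of: peptide rank drop ≥ 20; peptide enrichment ≤ −1 (at
least a two-fold frequency drop); blinatumomab rank *worsening* ≤ 20;
blinatumomab enrichment ≥ −0.5; reference frequency ≥
$1/(4\cdot\mathrm{library\ size})$. The published rule is qualitative
("decrease in rank and de-enrichment … maintenance of rank and absence
of de-enrichment"); these numbers quantify it and must be reported
with any result.

One choice deserves emphasis: **"maintenance of rank" is enforced
one-sidedly.** A variant that *improves* its blinatumomab rank is never
disqualified, because improved BLINA⁺ ranking is itself the selection
signal — decoupled variants accumulate reference frequency through the
carried-forward rounds and then rank even higher in the BLINA⁺ gate,
routinely improving by more than any sensible symmetric bound. A
symmetric |Δrank| rule would systematically reject exactly the
variants the screen is designed to find.

The backbone variant is excluded from candidacy by default (it
dominates the library by construction and its decoupling is known a
priori); a flag re-admits it. Because highly ranked reference variants
have little room to improve, the rank-improvement report normalises
rank changes by the ceiling `start_rank − 1` (capacity 0 at rank 1),
clipped to [−1, 1]. No significance testing is attached to enrichments:
the screen has no replicate structure to estimate a null from.

# Ring quantification

Co-culture image pairs (bright-field + red fluorescence) are smoothed
with a Gaussian of σ = 14.4 µm — the stated analysis setting —
separably, with reflective boundaries (avoiding the edge darkening that
would bias radial profiles; the kernel is normalised to sum 1 and
handles kernels wider than the image). The pixel size is a required
calibration input (fixture default 1.3 µm/px, making σ ≈ 11 px, since
σ is specified in µm but the acquisition's µm/px is not).

Cluster centres come from the largest 4-connected component above an
Otsu threshold, intensity-weighted (the original analysis selected
clusters manually; 12 clusters per condition, which the demo mirrors).
Radial profiles average intensity in annular bins (default width one
pixel-equivalent); each channel profile is min–max normalised per
cluster profile and the statistic is
$\max_k\,[\widehat{BF}_k - \widehat{FL}_k]$ — T-cell density peaking
outside the tumour disc. Conventions made explicit because the source
leaves them open: bright-field polarity is "high = cell-dense" (an
inversion flag exists), normalisation is per cluster profile, the
subtraction order is bright-field minus fluorescence (flag to swap),
and exact ties in the difference profile (noise-free annuli produce
plateaus) resolve to the middle tied bin. Constant profiles cannot be
min–max normalised; such clusters are zeroed and flagged degenerate
rather than erroring.

Group comparison is one-way ANOVA from explicit sums of squares with
Tukey HSD adjusted pairwise p-values (`ptukey` on the studentized
range; verified against `TukeyHSD`). Degenerate inputs get defined
answers instead of NaN: no between-group variation → F = 0, p = 1;
zero within-group variance with real separation → F = ∞, p = 0.

# Numerical and testing choices

* Single config seed fans out to per-stage seeds by a fixed affine
  rule modulo $2^{31}-1$; all randomness flows through
  `withr::with_seed`, so stages are independently reproducible and the
  caller's RNG state is never disturbed.
* Property tests use frozen seed sets; the Monte-Carlo properties
  (copula correlation within ±0.15, binomial 3-σ coverage, planted
  enrichment monotonicity) are evaluated over those fixed seeds.
* The carried-population monotonicity property is read per trajectory:
  over 50 seeds, ≥ 90% of planted-variant frequency trajectories in
  the peptide GFP-low population are non-decreasing across rounds
  (individual trajectories can dip by multinomial expansion noise
  without indicting the model).
* The 20-seed recovery test runs the full simulator → parser → caller
  chain with reads held in memory; the FASTQ file path itself is
  exercised separately (exactness and CLI tests) so the suite stays
  inside its time budget without changing the stated world.

# Known limitations

* The aligner is exact pairwise/profile Gotoh, adequate for short
  near-identical germline segments; it is not a general-purpose MSA
  tool and large divergent inputs will be slow (O(n²) guide-tree
  construction in pure R).
* Image I/O is 8-bit grayscale PNG; TIFF acquisition files must be
  converted upstream. Analysis itself operates on numeric matrices.
* The screen simulator's gate model is multiplicative with Emax dose
  terms — the simplest model reproducing the screen's logic, not a
  calibrated cytometry model.
* Candidate thresholds are package defaults for the simulated world;
  on real data they are knobs to be reported, not constants.
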