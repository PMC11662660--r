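---
title: "Sort-seq DMS activity inference: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sort-seq DMS activity inference: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortscape)
```

## The assay and the inference problem

A single-codon NNB saturation library of an anti-CRISPR protein is
expressed in a CRISPRi reporter strain: the stronger a variant inhibits
dCas9, the brighter the cell. Cells are flow-sorted into K contiguous
fluorescence gates (default K = 4, equal cell numbers per gate) and each
fraction is amplicon-sequenced. Per variant this yields a *fraction
distribution* `x` — its read frequencies across the K gates, normalized to
a probability vector. The inference task is to map `x` back to the
variant's full log-fluorescence histogram, and from it a scalar activity.

The working axis is natural-log fluorescence on [0, 14]. The instrument's
exact transform behind that axis is a convention, not a measured fact; the
package treats it as natural log because a dynamic range of e^14 ≈ 1.2e6
matches a typical cytometer, and hard-clamps mass outside the range into
the edge bins/gates rather than discarding it.

## The affine regression model

Benchmark mutants — default 16, cloned and measured individually by flow
cytometry — provide training pairs: their fraction distribution `x_i`
(length K) and their measured histogram `y_i` (B = 20 equally spaced bins
on [0, 14], normalized to sum to one). The model is a fully parameterized
affine map

$$\hat y = W x + b, \qquad W \in \mathbb{R}^{B \times K},\; b \in \mathbb{R}^B,$$

fit by minimizing $\sum_i \lVert W x_i + b - y_i \rVert^2 + \lambda \lVert W \rVert_F^2$
with zero-initialized full-batch gradient descent (learning rate 1e-2, up
to 1e5 iterations, stopping when the objective decrease per iteration
falls below 1e-10; all configurable). The objective is convex, so the
analytic ridge solution on the bias-augmented design is the same optimum
and serves as a permanent cross-check (`ridge_closed_form()` vs
`fit_affine_gd()`).

Numerical points worth stating explicitly:

* **The penalty applies to `W` only.** Penalizing the offset would shrink
  predictions toward the zero histogram, which cannot be renormalized.
* **The design is exactly rank-deficient.** Fraction distributions sum to
  one, so the bias column of `[X, 1]` equals the row sums of `X`. With
  λ > 0 the penalty supplies curvature (≈ 2λ) along that null direction
  and the optimum is unique; at λ = 0 the closed-form solver returns the
  minimum-norm least-squares solution via an SVD pseudoinverse, which is
  also the point zero-initialized gradient descent converges to. This
  rank deficiency also sets the gradient-descent convergence rate at
  small λ: reaching the optimum to 1e-5 per parameter needs on the order
  of `1 / (lr · 2λ)` iterations, which is why equivalence checks run with
  λ ≥ 1e-2 or a raised iteration cap.
* **Raw affine output is not a distribution.** Negative entries are
  clipped to zero and the vector renormalized; a post-clip mass below
  1e-6 is reported as a degenerate prediction rather than silently
  rescaled.

λ is selected by leave-one-out cross-validation over a log grid
(1e-4 … 10) on the benchmark set, refitting on 15 and scoring the per-bin
MSE of the held-out histogram; the grid search uses the closed-form
solver for speed, which is exact for the same objective. Activity is the
expectation of the predicted histogram over bin centers (*mean log
fluorescence intensity*). One model is fit per biological replicate
against the shared benchmark histograms; the per-replicate activities are
averaged and their sample (n−1) standard deviation is the confidence
measure — the replicate-wise definition is required for that confidence
to mean anything, which is why a joint fit across replicates is not the
default.

## Read processing and normalization

Paired-end amplicon reads are merged on their overlap: candidate overlap
lengths are scored as matches minus mismatches, a candidate is admissible
when its mismatch fraction is at most 10%, and equal best scores at
different lengths are rejected as ambiguous (this deliberately rejects
repeat-induced slippage rather than guessing). Within the overlap the
higher-Phred base wins, ties to R1. Merged reads are compared to the
wild-type ORF codon-by-codon in the fixed reading frame — the amplicon has
a fixed design, so no realignment and no indel tolerance. Only wild-type
reads and reads differing in exactly one codon whose mutant codon lies in
the NNB set are counted; everything else is a sequence not contained in
the library and is tallied by reject reason. Synonymous single-codon
variants merge into the WT class at amino-acid level; stop variants are
counted but excluded from landscape statistics by default.

Counts become fraction distributions in the stated order: pseudocount
(default 1; the magnitude is a convention and is recorded in the output),
then normalization within each sorting fraction, then across fractions.
Within-fraction normalization makes the result exactly invariant to
per-fraction sequencing depth — the functional reason the two-stage scheme
exists — and equal sorted cell numbers per gate justify equal fraction
weights. Variants with ≤ 10 total raw reads are flagged low-coverage;
they still receive an `x` but are excluded from tolerance and correlation
statistics by default (inclusion is a switch, since published summary
statistics do not state the exclusion rule).

## The synthetic experiment generator

The generator exists so every stage can be tested against known truth; it
emulates the assay's statistical structure, not its chemistry.

* **Fluorescence truths** are 1–2 component Gaussian mixtures clamped to
  [0, 14], assigned per amino-acid substitution (fluorescence is a protein
  phenotype, so synonymous codon variants share their amino acid's truth
  and carry no jitter). Defaults: wild type at mean 10 (sd 0.8), dead
  variants at mean 3 (sd 0.8) — the no-inhibitor control peak —
  intermediates uniform on [4.5, 8]. A `bimodal = TRUE` scenario gives
  the wild type a second low component, the AcrIIA5-like shape.
* **Continuous mutation effects.** Tolerated and dead substitutions get a
  small per-variant Gaussian shift of their component means (sd 0.25 and
  0.15 respectively). All-identical "wild-type-like" truths would be a
  degenerate rank structure no real library has; the jitter keeps the
  planted tolerant fraction sharp (the shifts are small against the ~1
  log-unit gap to the 90%-of-wild-type threshold) while making ranks
  well-defined.
* **Per-position tolerance** (default 0.7 of missense substitutions
  wild-type-like, half of the remainder dead) matches the ~70% tolerance
  regime these compact Acr proteins show; a per-position vector plants
  mutation-intolerant segments. Stop variants are always dead.
* **Sorting conditions on the gate**: for each gate, N cells (default
  1e6; study-scale runs here use 5e4) are drawn multinomially with
  probability proportional to library frequency × gate probability,
  mirroring a sorter collecting a fixed number of cells per fraction
  rather than thinning a common pool. Library frequencies are a Dirichlet
  draw (concentration 5) over codon variants plus WT. Sequencing is a
  second multinomial at the requested depth; FASTQ emission adds optional
  iid substitution errors (no indels — amplicon context) with R2 reverse
  complemented and constant Phred qualities.
* **Benchmarks** are picked at evenly spaced ranks of truth activity, the
  synthetic analogue of choosing mutants that span the observed fraction
  distributions; their flow events are drawn from their truth mixtures.
* **Annotations** are random category labels plus a conservation score
  built as the negative z-scored per-residue mean truth activity plus
  unit noise — conserved residues tolerate fewer substitutions, giving
  the weak negative activity–conservation correlation real landscapes
  show.

What the generator does *not* model, and what passing tests therefore do
not establish about real data: PCR amplification bias, UMI structure,
autofluorescence drift, gate spillover/sorter impurity, indels, and any
deviation of real fluorescence distributions from clamped Gaussian
mixtures. Tests on this generator validate the *inference machinery* —
counting, normalization algebra, the convex fit, the landscape
statistics — not the biological accuracy of any particular published
landscape.

## Problem sizes and verification

The study-scale configuration used throughout the test suite and the
acceptance script is an 87-residue protein (1720 amino-acid mutant cells
plus stop column), 4 gates on [0, 14], 5e4 cells per fraction, 2e5 reads
per fraction, 3 replicates, 16 benchmarks with 2e4 flow events each. At
those sizes the pipeline recovers the truth ranking at Spearman ρ ≈ 0.97
and the planted tolerant fraction within a fraction of a percentage
point, and separates dead from wild-type-like variants completely.
Smaller designs (5–30 codons) back the exact checks: error-free FASTQ
round-trips reproduce simulated count tables bit for bit, and
deep-sequencing fraction distributions converge to the analytic
conditional sort distribution (checked at 1e6 reads over 2e7 sorted cells
per gate, so that residual sorting noise does not mask read-sampling
convergence).

## Known limitations

* Activities are point summaries of predicted histograms; bimodal
  predicted distributions are averaged, not deconvolved.
* The affine map is unconstrained apart from post-hoc clipping; it is not
  a generative sorting model and can extrapolate poorly for fraction
  distributions far outside the benchmark span.
* Confidence is a 3-replicate standard deviation — informative as a flag,
  not a calibrated interval.
* Landscape statistics treat cells independently; no epistasis, since the
  library is single-codon by construction.
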