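# sortscape

Sort-seq (Flow-seq) deep mutational scanning analysis for anti-CRISPR
proteins — and for any other single-codon saturation library read out by
FACS fractionation plus amplicon sequencing.

## The problem

Anti-CRISPR (Acr) proteins such as AcrIIA4 and AcrIIA5 inhibit CRISPR-Cas9.
In a bacterial CRISPRi reporter assay, an active Acr blocks dCas9 and
restores RFP expression, so a cell's fluorescence reads out how well its
Acr variant works. A single-codon NNB saturation library (every codon
replaced in turn by the 48 NNB codons: any base at positions 1–2, C/G/T at
position 3) couples thousands of variants to that readout at once: cells
are sorted into K contiguous fluorescence gates (default 4, equal cell
numbers per gate), each fraction is amplicon-sequenced, and each variant
ends up with a *fraction distribution* — the normalized vector of its read
frequencies across gates.

`sortscape` turns those reads into per-variant inhibition potencies and a
position × amino-acid mutational fitness landscape:

1. **reads** — merge paired-end amplicons by their overlap (Phred-weighted
   consensus, ties to R1), keep only wild-type reads and reads with a
   mutation in *exactly one* codon that lies in the NNB set, and count
   variants per (replicate, fraction).
2. **normalize** — add pseudocounts, normalize within each sorting
   fraction (absorbing depth differences), then across fractions, giving
   each variant a probability vector `x` over the K gates.
3. **model** — the core statistic: an affine regression
   `y ≈ W x + b` mapping fraction distributions to binned log-fluorescence
   histograms (B = 20 equally spaced bins on [0, 14]), trained on ~16
   benchmark mutants whose histograms were measured individually by flow
   cytometry. The squared-error objective with an L2 penalty on `W` (bias
   unpenalized) is fit by zero-initialized full-batch gradient descent and
   cross-checked against the closed-form ridge solution; λ is chosen by
   leave-one-out cross-validation. A variant's *activity* is the mean log
   fluorescence of its predicted histogram, averaged over three biological
   replicates, with the replicate standard deviation as an inverse
   confidence measure.
4. **landscape** — assemble activities into the fitness landscape and its
   summary statistics: the fraction of mutants retaining ≥ 90% of
   wild-type activity, per-residue means, residue-subgroup distributions,
   and the correlation of activity with ConSurf-style conservation scores.

A fully seeded synthetic experiment generator (truncated Gaussian-mixture
fluorescence truths, multinomial FACS sorting conditional on each gate,
multinomial sequencing, FASTQ emission) makes every stage testable with
known ground truth.

## Worked example

```r
library(sortscape)

set.seed(1)
orf <- paste(c("ATG", sample(setdiff(nnb_codons(), "TAG"), 86, TRUE), "TAA"),
             collapse = "")
design <- design_library(orf)          # 87-residue protein, positions 2-87

sim <- simulate_experiment(design,
                           gates = gate_scheme(cells_per_fraction = 5e4),
                           reads_per_fraction = 2e5, seed = 1)
run <- run_pipeline(sim$counts, design, sim$benchmark_events,
                    annotation = sim$annotation)
run
#> <sortscape_run>
#>   detected mutants: 100.0% (> min reads)
#>   selected lambda:  0.01 (mean LOO MSE 0.00204)
#>   WT activity:      10.00 mean log fluorescence
#>   tolerant mutants: 69.2% (>= 90% of WT)
#>   conservation:     r = -0.13 (p = 7e-08)
```

Read: every amino-acid variant exceeded the 10-read detection threshold;
the affine model cross-validates at a mean per-bin MSE of 0.002; the wild
type sits at the high-fluorescence peak (mean log fluorescence ≈ 10 of a
0–14 axis); 69% of substitutions keep at least 90% of wild-type potency
(the generator planted 69.2%); and activity correlates weakly and
negatively with the synthetic conservation scores, as expected when
conserved residues tolerate fewer substitutions. `plot_landscape(run$landscape)`,
`plot_waterfall(run$estimates)` and `plot_loo(run$loo$by_replicate$rep1)`
draw the standard figures; `tidy()`/`glance()` expose the fitted models.

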