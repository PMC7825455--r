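# curvestage

Growth-curve staging and stage-profiled skeletal-muscle transcriptome
analysis for pigs (and other livestock with sigmoidal growth).

## The problem

Postnatal growth in pigs follows an S-shaped trajectory: the growth rate
rises to a maximum and then decays as body weight saturates. Sampling
muscle at ages defined by the *shape* of that trajectory — rather than at
arbitrary calendar ages — gives biologically comparable developmental
stages. `curvestage` implements the two halves of such a study:

1. **Staging.** Fit the three classical three-parameter sigmoid families
   to longitudinal body-weight records,

   - logistic: `y(t) = A / (1 + b e^(-kt))`
   - Gompertz: `y(t) = A e^(-b e^(-kt))`
   - Von Bertalanffy: `y(t) = A (1 - b e^(-kt))^3`

   with `A` the mature weight (kg), `b` a shape parameter and `k` a rate
   (per day). The inflection points are obtained in closed form via the
   substitution `u = b e^(-kt)`: the **MGI** (age of maximum growth rate)
   is the root of the second derivative (`u = 1, 1, 1/3` for the three
   families respectively) and the **GRI**/**RSI** (transitions between
   the gradually, rapidly and slowly increasing stages) are the two roots
   of the third derivative (`u = 2 ± √3`, `(3 ± √5)/2`, `(4 ± √7)/9`).
   Every closed-form root is self-checked against the analytic derivative
   it annihilates, and the test suite verifies it against bracketing
   bisection.

2. **Stage-profiled transcriptome.** For RNA-seq libraries collected at
   the GRI, MGI and RSI stages (3 replicates each): CPM computation and
   the "> 0.5 CPM in ≥ 1 library" expressed-set filter; `log2(CPM+1)`
   sample clustering and PCA; stage-versus-MGI differential expression by
   a moderated negative-binomial Wald test with Benjamini–Hochberg FDR
   and the `|log2FC| > 1, q < 0.1` call rule; 100-kb cis-window
   assignment of protein-coding targets to lncRNAs; and a
   candidate-lncRNA screen (Pearson correlation panels, `2^-ΔΔCt` qPCR
   quantification, canonical miRNA seed-match scanning with a
   dinucleotide-shuffle permutation null).

Seeded synthetic generators (`sim_config()`, `simulate_*()`) emulate
every input — weight records, counts, annotations, correlated panels,
candidate sequences — so the full workflow runs and is tested without
any external data.

## Worked example

```r
library(curvestage)

model <- growth_model("von_bertalanffy", A = 174.607, b = 0.852, k = 0.006)
inflection_points(model)
#> <inflection_report> von_bertalanffy model
#>   GRI    23.85 d     3.13 kg   (GIS -> RIS)
#>   MGI   156.41 d    51.74 kg   max rate 465.62 g/day
#>   RSI   288.97 d   107.05 kg   (RIS -> SIS)
```

Read: an animal following this curve transitions from the gradually to
the rapidly increasing stage at ~24 days (~3.1 kg), grows fastest at
~156 days (~52 kg, gaining ~466 g/day), and enters the slowly increasing
stage at ~289 days (~107 kg). `stage_of(report, t)` assigns any age to
GIS/RIS/SIS.

The full synthetic workflow is driven by the numbered scripts:

```sh
Rscript analysis/01_growth_staging.R        # fit + staging
Rscript analysis/02_expression_profiles.R   # CPM filter, clustering, PCA
Rscript analysis/03_differential_expression.R
Rscript analysis/04_cis_targets.R
Rscript analysis/05_candidate_screen.R
```

Each prints its findings (e.g. script 01 selects the Von Bertalanffy
family with the highest R²; script 02 shows the GRI samples splitting
off at the dendrogram root and lncRNA mean expression below mRNA;
script 03 reports realized FDR ≈ 0.05 and power ≈ 0.8 against the
simulation truth) and writes its tables under `results/`.

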