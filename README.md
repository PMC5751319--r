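# kdaselect

Gaussian kernel discriminant analysis (KDA) with fast, reconstruction-error
based selection of the kernel scale parameter, built for protein
subcellular-localization experiments but applicable to any labeled
high-dimensional data with nonlinear class structure.

## The problem

Protein feature encodings derived from PSI-BLAST position-specific scoring
matrices (PSSMs) are high-dimensional — 1000 features for PsePSSM, 220 for
PSSM-S — and not linearly separable by location class. KDA performs Fisher
discriminant analysis implicitly in the feature space induced by the
Gaussian kernel

    K(x, y) = exp(-||x - y||² / s²),

maximizing the kernelized Rayleigh quotient `J(a) = aᵀM̃a / aᵀL̃a`, where
`M̃ = Σᵢ Nᵢ(Mᵢ − M)(Mᵢ − M)ᵀ` and `L̃ = Σᵢ Kᵢ(E − (1/Nᵢ)J)Kᵢᵀ` are the
between- and within-class kernel scatter matrices. The coefficients are the
top `d ≤ C − 1` eigenvectors of `(L̃ + μI)⁻¹M̃`.

Everything hinges on the scale `s`. Grid search finds it by running a full
classifier evaluation per candidate. This package implements a cheaper
selector: pick *edge* and *internal* samples from the largest class
(far/near the class centroid, with mixed/pure ε-neighborhoods), and choose
the `s` maximizing

    f(s) = ( ‖RE(Ω_ed)‖∞ − ‖RE(Ω_in)‖∞ ) / std{RE(Ω_in)},

where `RE(x) = K(x,x) − ‖t(x)‖² = 1 − ‖t(x)‖²` is the kernel reconstruction
error of a sample projected onto the fitted discriminant subspace. No
classifier is run during selection, yet the chosen scale matches the
grid-search optimum on the benchmarks the package generates.

Around this core the package provides: a PSI-BLAST ASCII PSSM parser,
PsePSSM and PSSM-S encoders, KNN classification with jackknife
(leave-one-out) evaluation, per-class sensitivity / specificity / Matthews
correlation and overall accuracy `Q`, seeded synthetic generators (Gaussian
blobs, concentric rings/shells, PSSM profiles), and a CLI
(`exec/kdaselect`) with subcommands `simulate`, `extract-features`,
`select-param`, `reduce`, `evaluate`, `run`.

## Worked example

Two noisy concentric rings (60 points, 2 classes) — linearly inseparable,
ideal for a kernel method:

```r
library(kdaselect)
data <- demo_rings(seed = 1)
sel <- select_scale(data, d = 1, u = 8)
print(sel)
```

```
Scale selection (reconstruction): best s = 1
 scale max_re_edge max_re_internal sd_re_internal  objective
   0.1   0.9809990       0.9809990   1.995392e-09 -2.2853931
   0.2   0.9881951       0.9881952   4.260243e-08 -2.2469234
   0.3   0.9892626       0.9892631   2.271825e-07 -2.1200000
   0.4   0.9279825       0.9279837   8.946889e-07 -1.3883188
   1.0   0.9233576       0.9224847   3.670752e-04  2.3778242
   2.0   0.8427701       0.8433695   5.665517e-04 -1.0579638
   3.0   0.7458468       0.7464814   6.416719e-04 -0.9889488
   4.0   0.7304196       0.7373322   2.448886e-03  -2.8227686
```

The objective peaks at `s = 1`: there the edge samples' reconstruction
errors clearly exceed the internal samples' while the internal errors stay
tight. Evaluating the chosen scale:

```r
jk <- jackknife(data, s = sel$best, d = 1, k = 5, mode = "fast")
print(eval_metrics(jk$counts))
```

```
  class Sen Spe MCC
 class1   1   1   1
 class2   1   1   1
Overall accuracy Q = 1 on 60 samples
```

Leave-one-out KNN in the 1-dimensional KDA space classifies every sample
correctly — the same accuracy a full grid search attains, at a fraction of
the work (8 KDA fits and no classifier passes, versus 8 fits plus 8
leave-one-out KNN sweeps).

The same flow runs from the shell:

```sh
kdaselect run --preset demo-rings --method both --knn-k 5 --report report.json
```

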