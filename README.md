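# onedhic

Explicit, copy-number-aware normalization of binned Hi-C contact matrices
through their one-dimensional contact profile.

Hi-C counts carry multiplicative biases from local genome features (G+C
content, read mappability, restriction-site density). The dominant remedies —
matrix balancing (vanilla/ICE/KR) — force every bin to the same total, which
silently treats copy-number differences as biases. On cancer cell lines and
other aberrant karyotypes this erases real signal and inflates batch effects.
`onedhic` is for anyone normalizing Hi-C (or capture Hi-C) from such samples:
it removes the feature-driven biases explicitly and leaves karyotype intact,
with an *optional*, separate copy-number correction when a euploid-equivalent
map is wanted.

## The model

The per-bin totals (the *contact profile*) are modeled as a negative binomial
generalized additive model on the genomic covariates:

    t_i = Σ_j x_ij ~ NB(λ_i, θ),    log λ_i = α + Σ_k f_k(z_ki)

with thin-plate regression spline smooths `f_k` (REML smoothing selection,
dispersion θ estimated jointly). The fitted means are rescaled to mean one,
`λ'_i = λ_i / (Σ_j λ_j / n)`, and every entry is corrected as

    x̂_ij = x_ij / sqrt(λ'_i λ'_j)

The corrected profile stays proportional to local copy number. Optionally, an
8-state hidden Markov model with Student-t emissions (tied locations k·β for
k = 1..7, an "8 or more" state, shared scale and degrees of freedom; fitted by
Baum–Welch, decoded by Viterbi) infers per-bin copy number c_i, and

    x̂*_ij = x̂_ij / sqrt(c_i c_j)

yields the euploid-equivalent matrix.

The package also provides the balancing baselines (`vanilla()`, `ice()`,
`kr()`), observed/expected transformation, four matrix-reproducibility
metrics (banded Spearman, O/E Pearson, stratum-adjusted correlation
coefficient, spectral Laplacian score) with a ROC harness, and a simulator
producing Hi-C matrices with distance decay, smooth biases and injected
copy-number aberrations.

## Worked example

Simulate a biased diploid genome (4 chromosomes × 125 bins at 100 kb), inject
random copy-number aberrations on two chromosomes, then normalize with the
copy-number correction enabled:

```r
library(onedhic)

cfg  <- sim_config(seed = 1)
sim  <- simulate_base_matrix(cfg)
spec <- draw_cnv_spec(sim$bins, chroms = c("chr1", "chr2"), seed = 2)
m    <- inject_cnv(sim$matrix, spec)
m
#> ContactMatrix: 500 bins (0 masked), 4 chromosome(s), 115871 stored entries
#> resolution: 100000 bp; total counts: 1.5081e+06

res <- oned_normalize(m, sim$features, cnv = TRUE)
res$fit
#> NB-GAM contact-profile fit: 500 bins, features: gc, map, res
#> theta = 4.771, deviance = 501.414, converged: TRUE
res$cn
#> Copy-number profile: 500 bins called, 19 segment(s), loglik = -4166.7262
head(res$cn$segments)
#>   chrom   start      end cn
#> 1  chr1       0   600000  2
#> 2  chr1  600000  1700000  8
#> 3  chr1 1700000  2300000  3
#> 4  chr1 2300000 12500000  2
#> 5  chr2       0   300000  2
#> 6  chr2  300000  2800000  4

mean(res$cn$cn == pmin(spec$cn, 8), na.rm = TRUE)
#> [1] 0.874
```

The fitted dispersion is low here because the injected aberrations inflate
the profile's spread; on the unaberrated matrix θ is an order of magnitude
higher. The segment table shows the inferred copy number per maximal run of
bins (the injected CN-10 region is called as the open-ended top state), and
87% of bins get exactly the injected state. `export_segments()` writes the
table as BED; `correction_vector()` exposes λ' for bedGraph export.

A thin command-line wrapper covering the same functionality (subcommands
`normalize`, `cnv`, `balance`, `compare`, `simulate`) is installed at
`inst/cli/oned.R`:

```sh
Rscript inst/cli/oned.R simulate --out-dir sim --seed 5 --cnv
Rscript inst/cli/oned.R normalize --matrix sim/matrix.tsv --bins sim/bins.bed \
    --gc sim/gc.bedGraph --map sim/map.bedGraph --res sim/res.bedGraph \
    --cnv --out corrected.tsv --vector-out lambda.bedGraph
```

Matrices are exchanged as sparse triplet text (`bin1 TAB bin2 TAB count`,
0-based ids, `# resolution=` header) against a 4-column BED bin table;
feature tracks are bedGraph tiling the bins exactly.

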