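# pleiopolar

Detection of pleiotropic SNPs — variants with a direct effect on two or
more traits — from GWAS summary statistics.

Genome-wide association studies report, per SNP, an effect size and its
standard error; `z = beta/SE` is approximately standard normal when the
SNP has no effect. Given aligned z-scores for `p` traits, each SNP is a
point in `p`-dimensional space, and pleiopolar works in polar coordinates:

- **distance** `r_i = sqrt(sum_j z_ij^2)` — the overall effect, tested
  against a central chi distribution with `p` degrees of freedom;
- **angle** — the sharedness. For two traits the quadrant-folded angle
  `atan(|z_y|/|z_x|)` is stretched by the fourfold transform
  `4*theta mod 2pi`, so the trait axes (trait-specific effects) map to 0
  and the diagonal (perfect sharing) to `pi`; for general `p` the angle to
  the nearest trait axis `acos(max_j |z_j|/r)` is rescaled by
  `pi / acos(1/sqrt(p))`, which coincides with the fourfold construction
  at `p = 2`. The angle is tested against a mean-zero von Mises null whose
  concentration `kappa(r)` is calibrated by simulation (curves for
  `p = 2..6` ship with the package); the tail probability is evaluated by
  the series expansion of `exp(kappa cos t)` integrated term by term via a
  hypergeometric antiderivative.

Because correlated traits (genetic correlation, sample overlap) correlate
z-scores even for null SNPs, panels are first decorrelated: the null
covariance is estimated on SNPs with Mahalanobis distance < 5 and removed
by ZCA-cor whitening, which keeps each whitened component maximally
correlated with its original trait. Significance is assigned in two
FDR-controlled stages (Storey q-values): SNPs with `q_r < 0.05` proceed to
the angle test, and `q_theta < 0.05` within that subset flags a SNP as
significantly shared. Shared SNPs can be collapsed into loci by positional
clumping and summarized as a weighted trait (or trait-domain) network.

Intended users: statistical geneticists with per-trait summary statistics
who want SNP-level sharedness calls (e.g. to find shared etiology, or to
exclude horizontally pleiotropic instruments from Mendelian
randomization).

## Worked example

Plant one perfectly shared SNP `(z_x, z_y) = (8, 8)` and one trait-specific
SNP `(8, 0)` among 10,000 null SNPs:

```r
library(pleiopolar)
set.seed(7)
Z <- rbind(matrix(rnorm(10000 * 2), ncol = 2), c(8, 8), c(8, 0))
m <- nrow(Z)
variants <- data.frame(id = sprintf("snp%05d", 1:m), chrom = "1",
                       pos = (1:m) * 5000L, ea = "A", oa = "G",
                       ambiguous = FALSE)
panel <- z_panel(variants, Z, c("traitX", "traitY"))

model <- estimate_null_covariance(panel)     # Mahalanobis < 5, two passes
polar <- to_polar(zca_cor_whiten(panel, model))
res <- two_stage_select(polar, builtin_kappa_curve(2))
res[res$q_r < 0.05, c("id", "r", "theta_trans", "p_r", "q_r",
                      "p_theta", "q_theta", "shared_flag")]
#>             id         r theta_trans          p_r          q_r   p_theta
#> 10001 snp10001 11.300608  3.14023709 1.859888e-28 1.860260e-24 0.0000000
#> 10002 snp10002  7.951537  0.01838618 1.863988e-14 9.321803e-11 0.9702157
#>         q_theta shared_flag
#> 10001 0.0000000        TRUE
#> 10002 0.9702157       FALSE
```

Both planted SNPs pass the distance stage (`q_r` far below 0.05: both have
a real overall effect). Only the diagonal SNP has a sharedness angle near
`pi` (3.140) and is flagged shared; the axis SNP sits at angle ~0 with
`p_theta = 0.97`, exactly the trait-specific null the angle test is built
around. No null SNP is flagged.

File-based runs (`run_pipeline()` / the `inst/cli/pleiopolar` script) read
per-trait summary statistics, harmonize alleles across traits (swapped
alleles flip the z sign, strand flips are resolved by reverse complement,
irreconcilable variants are dropped, palindromic ones flagged), and write
a results TSV, the whitening model and a run manifest:

```sh
pleiopolar=$(Rscript -e 'cat(system.file("cli", "pleiopolar", package = "pleiopolar"))')
Rscript "$pleiopolar" run --sumstats traitX.tsv,traitY.tsv --out myrun
```

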