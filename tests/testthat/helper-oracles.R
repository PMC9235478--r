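# Independent oracles and fixture builders used across the test files.

# von Mises tail probability by adaptive quadrature (the independent check
# for the series implementation); integrand rescaled by exp(-kappa) so it
# stays bounded for large concentrations.
vm_tail_quadrature <- function(theta, kappa) {
  f <- function(t) exp(kappa * (cos(t) - 1))
  stats::integrate(f, theta, pi, rel.tol = 1e-12)$value /
    stats::integrate(f, 0, pi, rel.tol = 1e-12)$value
}

# mean-zero von Mises sampler (Best & Fisher rejection), independent of the
# package's estimator code path
rvm_dev <- function(n, kappa) {
  if (kappa == 0) return(runif(n, 0, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    u1 <- runif(n); u2 <- runif(n)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    c0 <- kappa * (rr - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    out <- c(out, acos(f[ok]))
  }
  out[seq_len(n)]  # absolute deviations in [0, pi]
}

# correlated bivariate/multivariate null z-scores with pairwise rho
rznull <- function(m, p = 2, rho = 0) {
  S <- matrix(rho, p, p); diag(S) <- 1
  matrix(rnorm(m * p), m, p) %*% chol(S)
}

# write a small summary-statistic file; `rows` is a data.frame with columns
# snp, chr, pos, ea, oa and any of beta/se/z
write_sumstats_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# build a trait_scan in memory without touching disk
make_scan <- function(trait, ids, ea, oa, z,
                      chrom = "1", pos = seq_along(ids) * 1000L) {
  df <- data.frame(id = ids, chrom = chrom, pos = pos, ea = ea, oa = oa,
                   beta = z, se = 1, z = z, stringsAsFactors = FALSE)
  structure(df, trait_name = trait,
            n_dropped = c(bad_se = 0L, bad_alleles = 0L, nonfinite = 0L,
                          bad_pos = 0L, duplicate = 0L),
            class = c("trait_scan", "data.frame"))
}

# a small panel with planted effect rows appended to iid noise
planted_panel <- function(m_null, planted, p = 2, seed = 1) {
  set.seed(seed)
  Z <- rbind(matrix(rnorm(m_null * p), m_null, p), planted)
  m <- nrow(Z)
  variants <- data.frame(id = sprintf("snp%06d", seq_len(m)),
                         chrom = as.character(rep_len(1:22, m)),
                         pos = seq_len(m) * 5000L, ea = "A", oa = "G",
                         ambiguous = FALSE, stringsAsFactors = FALSE)
  z_panel(variants, Z, paste0("trait", seq_len(p)))
}
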