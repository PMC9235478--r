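#' Effect-magnitude distribution for the synthetic generator
#'
#' Magnitudes are on the z-score scale. `"heritability"` mimics a GWAS of
#' `n_indiv` individuals where each trait's heritability `h2` is spread
#' evenly over that trait's causal SNPs: the per-SNP noncentrality is
#' `sqrt(n_indiv * h2 / n_causal)`, with `n_causal` resolved from the
#' design's class sizes at simulation time.
#'
#' @param family `"heritability"`, `"constant"`, `"halfnormal"` or
#'   `"uniform"`.
#' @param value magnitude for `"constant"`.
#' @param sd scale for `"halfnormal"` (`|N(0, sd^2)|`).
#' @param min,max range for `"uniform"`.
#' @param n_indiv,h2 cohort size and per-trait heritability for
#'   `"heritability"`.
#' @return An `effect_dist` specification list.
#' @export
effect_dist <- function(family = c("heritability", "constant", "halfnormal", "uniform"),
                        value = 1, sd = 1, min = 0, max = 1,
                        n_indiv = 549, h2 = 0.6) {
  family <- match.arg(family)
  structure(list(family = family, value = value, sd = sd, min = min, max = max,
                 n_indiv = n_indiv, h2 = h2), class = "effect_dist")
}

draw_magnitudes <- function(dist, n, n_causal_per_trait) {
  switch(dist$family,
         constant = rep(dist$value, n),
         halfnormal = abs(rnorm(n, 0, dist$sd)),
         uniform = runif(n, dist$min, dist$max),
         heritability = rep(sqrt(dist$n_indiv * dist$h2 / n_causal_per_trait), n))
}

#' Simulation design for multi-trait z-score panels
#'
#' Defaults reproduce the desk-scale analog of the reference false-positive
#' rate experiment: two traits, 50,000 SNPs, 10% of SNPs specific to each
#' trait and 10% pleiotropic (the remainder null), inter-trait z-score
#' correlation 0.8, 20 replicates, and effect magnitudes from the
#' heritability mapping (cohort 549, h2 = 0.6).
#'
#' @param m_total total SNP count (>= 1000).
#' @param p trait count.
#' @param frac_specific_per_trait fraction of SNPs specific to each trait.
#' @param frac_pleiotropic fraction of SNPs affecting every trait.
#' @param rho inter-trait correlation of the z-score noise, in (-1, 1).
#' @param effects an [effect_dist()].
#' @param concordant_pleiotropy force concordant effect signs across traits
#'   for pleiotropic SNPs (direction is irrelevant after orthant folding;
#'   default independent signs).
#' @param n_replicates replicate count for [fpr_experiment()].
#' @param seed base RNG seed; each replicate derives its own substream.
#' @return A `sim_design` list.
#' @export
sim_design <- function(m_total = 50000L, p = 2L,
                       frac_specific_per_trait = 0.10, frac_pleiotropic = 0.10,
                       rho = 0.8, effects = effect_dist(),
                       concordant_pleiotropy = FALSE,
                       n_replicates = 20L, seed = 1L) {
  stopifnot(m_total >= 1000L, p >= 2L, rho > -1, rho < 1)
  if (p * frac_specific_per_trait + frac_pleiotropic >= 1)
    stop("class fractions must sum to < 1 (the remainder is the null class)")
  structure(list(m_total = as.integer(m_total), p = as.integer(p),
                 frac_specific_per_trait = frac_specific_per_trait,
                 frac_pleiotropic = frac_pleiotropic, rho = rho,
                 effects = effects,
                 concordant_pleiotropy = isTRUE(concordant_pleiotropy),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_design")
}

# deterministic per-replicate substream, kept below 2^31
replicate_seed <- function(seed, replicate, stream = 0L) {
  (abs(seed) %% 1000003L) * 2029L + replicate * 97003L + stream * 7901L
}

# upper-triangular Cholesky factor of the exchangeable correlation
# (1 - rho) I + rho J
equicorr_chol <- function(p, rho) {
  S <- matrix(rho, p, p)
  diag(S) <- 1
  chol(S)
}

#' Simulate a multi-trait z-score panel with known ground truth
#'
#' Each SNP's z-vector is its true effect vector plus correlated noise with
#' pairwise correlation `rho`. Trait-specific SNPs carry one nonzero effect
#' entry with random sign; pleiotropic SNPs carry equal-magnitude effects
#' on every trait with independent (or concordant) signs. Deterministic
#' given `(design$seed, replicate)`.
#'
#' @param design a [sim_design()].
#' @param replicate replicate index (integer >= 1).
#' @return List with `panel` (a [z_panel()]) and `truth` (data.frame: `id`,
#'   `class` in null/specific/pleiotropic, `trait` for specific SNPs, and
#'   the true effect vector columns `eff_1..p`).
#' @export
simulate_panel <- function(design, replicate = 1L) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(replicate_seed(design$seed, replicate))
  m <- design$m_total; p <- design$p
  m_spec <- round(design$frac_specific_per_trait * m)
  m_pleio <- round(design$frac_pleiotropic * m)
  n_causal_per_trait <- m_spec + m_pleio

  cls <- rep("null", m)
  trait_of <- rep(NA_integer_, m)
  idx <- 1L
  for (j in seq_len(p)) {
    if (m_spec > 0) {
      cls[idx:(idx + m_spec - 1L)] <- "specific"
      trait_of[idx:(idx + m_spec - 1L)] <- j
      idx <- idx + m_spec
    }
  }
  if (m_pleio > 0) {
    cls[idx:(idx + m_pleio - 1L)] <- "pleiotropic"
    idx <- idx + m_pleio
  }
  # scatter the classes across the genome deterministically
  ord <- sample.int(m)
  cls <- cls[ord]; trait_of <- trait_of[ord]

  eff <- matrix(0, m, p)
  spec_rows <- which(cls == "specific")
  if (length(spec_rows)) {
    mag <- draw_magnitudes(design$effects, length(spec_rows), n_causal_per_trait)
    sgn <- sample(c(-1, 1), length(spec_rows), replace = TRUE)
    eff[cbind(spec_rows, trait_of[spec_rows])] <- sgn * mag
  }
  pleio_rows <- which(cls == "pleiotropic")
  if (length(pleio_rows)) {
    mag <- draw_magnitudes(design$effects, length(pleio_rows), n_causal_per_trait)
    sgn <- if (design$concordant_pleiotropy) {
      matrix(rep(sample(c(-1, 1), length(pleio_rows), replace = TRUE), p),
             ncol = p)
    } else {
      matrix(sample(c(-1, 1), length(pleio_rows) * p, replace = TRUE), ncol = p)
    }
    eff[pleio_rows, ] <- sgn * mag
  }

  L <- equicorr_chol(p, design$rho)
  Z <- eff + matrix(rnorm(m * p), m, p) %*% L

  chrom <- as.character(rep_len(1:22, m))
  # positions: consecutive 5 kb spacing within each chromosome
  pos <- integer(m)
  for (cc in unique(chrom)) {
    w <- which(chrom == cc)
    pos[w] <- seq_along(w) * 5000L
  }
  variants <- data.frame(id = sprintf("snp%06d", seq_len(m)),
                         chrom = chrom, pos = pos, ea = "A", oa = "G",
                         ambiguous = FALSE, stringsAsFactors = FALSE)
  truth <- data.frame(id = variants$id, class = cls, trait = trait_of,
                      stringsAsFactors = FALSE)
  colnames(eff) <- paste0("eff_", seq_len(p))
  truth <- cbind(truth, eff)
  list(panel = z_panel(variants, Z, paste0("trait", seq_len(p))),
       truth = truth)
}

#' Simulate a fully null panel (pair-permutation analog)
#'
#' The z-score-level analog of permuting phenotypes as pairs: every SNP is
#' from the null class, so only the correlated noise structure (pairwise
#' `rho`) remains and no SNP has any true effect.
#'
#' @inheritParams simulate_panel
#' @return A [z_panel()].
#' @export
simulate_null_permuted <- function(design, replicate = 1L) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(replicate_seed(design$seed, replicate, stream = 1L))
  m <- design$m_total; p <- design$p
  Z <- matrix(rnorm(m * p), m, p) %*% equicorr_chol(p, design$rho)
  z_panel(null_variants(m), Z, paste0("trait", seq_len(p)))
}

#' False positive rate experiment
#'
#' Runs the calibration experiment over `design$n_replicates` replicates.
#' `mode = "permuted"` measures the distance-test FPR: the fraction of all
#' SNPs with `p_r < level` on fully null panels (after covariance
#' estimation and whitening). `mode = "specific"` measures the angle-test
#' FPR: panels with specific/pleiotropic/null classes are run through the
#' full pipeline (whitening, polar transform, kappa lookup) and the
#' fraction of ground-truth trait-specific SNPs with `p_theta < level` is
#' recorded, as those SNPs would falsely be called pleiotropic.
#'
#' @param design a [sim_design()].
#' @param mode `"permuted"` or `"specific"`.
#' @param curve kappa curve for `design$p` (default: the bundled curve);
#'   only used in `"specific"` mode.
#' @param level nominal p-value threshold (default 0.05).
#' @param tol von Mises series truncation threshold.
#' @return List with `mode`, `per_replicate` fractions, their `mean` and
#'   `sd`, and `n` (SNPs per replicate entering the fraction).
#' @export
fpr_experiment <- function(design, mode = c("permuted", "specific"),
                           curve = NULL, level = 0.05, tol = 1e-8) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "sim_design"))
  if (mode == "specific" && is.null(curve)) curve <- builtin_kappa_curve(design$p)
  fr <- numeric(design$n_replicates)
  n_used <- NA_integer_
  for (rep_i in seq_len(design$n_replicates)) {
    if (mode == "permuted") {
      panel <- simulate_null_permuted(design, rep_i)
      model <- estimate_null_covariance(panel)
      polar <- to_polar(zca_cor_whiten(panel, model))
      p_r <- chi_sf(polar$r, design$p)
      fr[rep_i] <- mean(p_r < level)
      n_used <- length(p_r)
    } else {
      sim <- simulate_panel(design, rep_i)
      model <- estimate_null_covariance(sim$panel)
      polar <- to_polar(zca_cor_whiten(sim$panel, model))
      specific <- sim$truth$class == "specific"
      p_theta <- theta_pvalues(polar[specific, , drop = FALSE], curve, tol = tol)
      fr[rep_i] <- mean(p_theta < level)
      n_used <- sum(specific)
    }
  }
  list(mode = mode, per_replicate = fr, mean = mean(fr), sd = stats::sd(fr),
       n = n_used)
}

#' Write simulated per-trait summary statistics to disk
#'
#' Emits one summary-statistic TSV per trait (beta = z, se = 1) plus a
#' ground-truth TSV, so the full file-level pipeline can be exercised
#' end to end on synthetic data.
#'
#' @param sim output of [simulate_panel()].
#' @param prefix output path prefix; files are
#'   `<prefix>.<trait>.tsv` and `<prefix>.truth.tsv`.
#' @return Character vector of the per-trait file paths, invisibly.
#' @export
write_sim_sumstats <- function(sim, prefix) {
  panel <- sim$panel
  paths <- character(length(panel$traits))
  for (k in seq_along(panel$traits)) {
    df <- data.frame(snp = panel$variants$id, chr = panel$variants$chrom,
                     pos = panel$variants$pos, ea = panel$variants$ea,
                     oa = panel$variants$oa,
                     beta = sprintf("%.17g", panel$Z[, k]), se = "1",
                     stringsAsFactors = FALSE)
    paths[k] <- sprintf("%s.%s.tsv", prefix, panel$traits[k])
    data.table::fwrite(df, paths[k], sep = "\t")
  }
  data.table::fwrite(sim$truth, sprintf("%s.truth.tsv", prefix), sep = "\t")
  invisible(paths)
}
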