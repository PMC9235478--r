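# ratio A(kappa) = I1(kappa) / I0(kappa), computed with scaled Bessel
# functions so large kappa does not overflow
bessel_ratio <- function(kappa) {
  if (kappa > 5e3) return(1 - 1 / (2 * kappa) - 1 / (8 * kappa^2))
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Maximum-likelihood concentration of a mean-zero von Mises
#'
#' Solves `A(kappa) = mean(cos(theta))` with `A = I1/I0`, using the
#' Best-Fisher closed-form approximation refined by Newton steps. With the
#' mean direction fixed at zero the estimator depends on the angles only
#' through `mean(cos(theta))`, so mirroring deviations to `±theta`
#' (`mirrored = TRUE`, the convention for folded sharedness angles) gives
#' the same estimate; the flag documents how the input is interpreted.
#'
#' @param angles angular deviations from 0, in radians (`[0, pi]` when
#'   mirrored).
#' @param mirrored treat `angles` as absolute deviations of a symmetric
#'   (mirrored) sample.
#' @param cap upper bound on the estimate (default 1e6); hit with a warning
#'   when the sample is degenerate (all angles ~ 0).
#' @return Estimated concentration `kappa >= 0`.
#' @export
vm_mle_kappa <- function(angles, mirrored = TRUE, cap = 1e6) {
  if (length(angles) == 0L) stop("no angles supplied")
  if (length(angles) < 50L)
    warning("fewer than 50 angles; kappa estimate will be unstable")
  rbar <- mean(cos(angles))
  if (rbar <= 0) return(0)
  if (rbar >= 1 - 1e-12) {
    warning("all angles concentrated at 0; kappa capped at ", cap)
    return(cap)
  }
  # Best & Fisher (1981) starting value
  k <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  k <- min(max(k, 1e-8), cap)
  for (iter in 1:50) {
    A <- bessel_ratio(k)
    Aprime <- 1 - A / k - A^2
    if (Aprime <= 0) break
    step <- (A - rbar) / Aprime
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (k_new > cap) { k_new <- cap; k <- k_new; break }
    if (abs(k_new - k) < 1e-10 * (1 + k)) { k <- k_new; break }
    k <- k_new
  }
  if (k >= cap) warning("kappa estimate hit the cap of ", cap)
  k
}

#' von Mises tail probability via the series antiderivative
#'
#' Returns `P(deviation >= theta)` for a mean-zero von Mises variable:
#' the ratio of `integral_theta^pi exp(kappa cos t) dt` to the same
#' integral over `[0, pi]` (the normalization constant cancels). The
#' integrand is expanded as `sum_j (kappa cos t)^j / j!` and integrated
#' term by term with the hypergeometric antiderivative; summation stops
#' once the last added term falls below `tol`, with a hard error at
#' `max_terms` terms.
#'
#' @param theta angular deviations in `[0, pi]` (vectorized).
#' @param kappa concentration(s) `>= 0`, recycled against `theta`.
#' @param tol series truncation threshold, in `(0, 1e-4]`.
#' @param max_terms term cap before a non-convergence error.
#' @return Tail probabilities in `[0, 1]`.
#' @export
vm_tail_pvalue <- function(theta, kappa, tol = 1e-8, max_terms = 10000L) {
  if (!(tol > 0 && tol <= 1e-4)) stop("`tol` must be in (0, 1e-4]")
  if (any(theta < 0 | theta > pi + 1e-12, na.rm = TRUE))
    stop("`theta` must lie in [0, pi]")
  if (any(kappa < 0, na.rm = TRUE)) stop("`kappa` must be >= 0")
  n <- max(length(theta), length(kappa))
  vm_tail_cpp(rep_len(as.numeric(theta), n), rep_len(as.numeric(kappa), n),
              tol, as.integer(max_terms))
}

#' Calibrate the concentration curve kappa(r) by null simulation
#'
#' For each grid distance `r*`, simulates trait-specific null SNPs on the
#' whitened scale: one trait's z-score is `±mu(r*)` plus unit normal noise
#' with `mu(r*) = sqrt(max(r*^2 - (p - 1), 0))`, all other traits pure unit
#' normal. Rows whose realized distance falls within `bin_halfwidth` of
#' `r*` are kept (the bin is widened, with a warning, until at least
#' `min_retained` rows survive), their sharedness angles `theta_trans` are
#' computed, and a mean-zero von Mises concentration is fitted by maximum
#' likelihood. The angle is treated as a circular (2D) quantity for every
#' p: the observed and null direction always span a 2D plane.
#'
#' @param p trait count (>= 2).
#' @param r_grid increasing distances to calibrate at (recommended within
#'   `[0.5, 15]`).
#' @param n_sims simulated SNPs per grid point (>= 10000 recommended).
#' @param seed integer RNG seed; the curve is deterministic given
#'   `(p, r_grid, n_sims, seed)`.
#' @param bin_halfwidth half-width of the realized-r bin; defaults to half
#'   the median grid spacing.
#' @param min_retained minimum simulations per bin before widening.
#' @return A `kappa_curve`: data.frame with columns `r`, `kappa` and
#'   attributes `p`, `n_sims`, `seed`.
#' @export
calibrate_kappa_curve <- function(p, r_grid = seq(0.5, 12, by = 0.25),
                                  n_sims = 50000L, seed = 1L,
                                  bin_halfwidth = NULL, min_retained = 500L) {
  stopifnot(p >= 2, length(r_grid) >= 2, all(diff(r_grid) > 0))
  if (is.null(bin_halfwidth)) bin_halfwidth <- stats::median(diff(r_grid)) / 2
  set.seed(as.integer(seed))
  factor <- angle_norm_factor(p)
  kappa <- numeric(length(r_grid))
  for (g in seq_along(r_grid)) {
    rstar <- r_grid[g]
    mu <- sqrt(max(rstar^2 - (p - 1), 0))
    Z <- matrix(rnorm(n_sims * p), n_sims, p)
    Z[, 1] <- Z[, 1] + sample(c(-mu, mu), n_sims, replace = TRUE)
    r_real <- sqrt(rowSums(Z^2))
    bw <- bin_halfwidth
    keep <- abs(r_real - rstar) <= bw
    while (sum(keep) < min_retained && bw < max(r_grid)) {
      bw <- 2 * bw
      warning(sprintf("r* = %.2f: widening bin to +/- %.3f to retain >= %d simulations",
                      rstar, bw, min_retained))
      keep <- abs(r_real - rstar) <= bw
    }
    theta_trans <- nearest_axis_angle(Z[keep, , drop = FALSE])$angle * factor
    kappa[g] <- vm_mle_kappa(theta_trans, mirrored = TRUE)
  }
  structure(data.frame(r = r_grid, kappa = kappa),
            p = as.integer(p), n_sims = as.integer(n_sims),
            seed = as.integer(seed),
            class = c("kappa_curve", "data.frame"))
}

#' Look up the calibrated concentration at a distance
#'
#' Piecewise-linear interpolation on the calibration grid, clamped to the
#' endpoint values outside it.
#'
#' @param r distances (vectorized), `>= 0`.
#' @param curve a `kappa_curve`.
#' @return Concentrations `kappa >= 0`.
#' @export
kappa_lookup <- function(r, curve) {
  stopifnot(inherits(curve, "kappa_curve"))
  approx(curve$r, curve$kappa, xout = r, rule = 2)$y
}

#' Angle-test p-values for a polar table
#'
#' Per SNP, `p_theta = vm_tail_pvalue(theta_trans, kappa_lookup(r))`.
#' Degenerate rows (r = 0) get p_theta = 1.
#'
#' @param polar a `polar_table` from [to_polar()].
#' @param curve a `kappa_curve` calibrated for the same trait count.
#' @param tol series truncation threshold passed to [vm_tail_pvalue()].
#' @return Vector of tail probabilities.
#' @export
theta_pvalues <- function(polar, curve, tol = 1e-8) {
  stopifnot(inherits(polar, "polar_table"), inherits(curve, "kappa_curve"))
  if (!identical(as.integer(attr(polar, "p")), as.integer(attr(curve, "p"))))
    stop("kappa curve was calibrated for a different trait count than the polar table")
  pv <- vm_tail_pvalue(polar$theta_trans, kappa_lookup(polar$r, curve), tol = tol)
  pv[polar$degenerate] <- 1
  pv
}

#' Read and write calibration curves; access the bundled curves
#'
#' Curves are stored as two-column text tables with a small header block
#' (`p`, `n_sims`, `seed`). Curves for p = 2..6 ship with the package
#' (`builtin_kappa_curve()`), regenerable with, e.g.,
#' `write_kappa_curve(calibrate_kappa_curve(p = 2, seed = 20220627), path)`.
#'
#' @param curve a `kappa_curve`.
#' @param path file path.
#' @param p trait count of the bundled curve (2..6).
#' @export
write_kappa_curve <- function(curve, path) {
  stopifnot(inherits(curve, "kappa_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# p: %d", attr(curve, "p")),
               sprintf("# n_sims: %d", attr(curve, "n_sims")),
               sprintf("# seed: %d", attr(curve, "seed")),
               "r\tkappa"), con)
  writeLines(sprintf("%.6g\t%.10g", curve$r, curve$kappa), con)
  invisible(path)
}

#' @rdname write_kappa_curve
#' @export
read_kappa_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    as.integer(sub(sprintf("^# %s:\\s*", key), "", ln[1]))
  }
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t")
  structure(data.frame(r = df$r, kappa = df$kappa),
            p = get("p"), n_sims = get("n_sims"), seed = get("seed"),
            class = c("kappa_curve", "data.frame"))
}

#' @rdname write_kappa_curve
#' @export
builtin_kappa_curve <- function(p) {
  path <- system.file("extdata", "kappa", sprintf("kappa_p%d.tsv", p),
                      package = "pleiopolar")
  if (path == "")
    stop(sprintf("no bundled kappa curve for p = %d (available: 2..6); run calibrate_kappa_curve()", p))
  read_kappa_curve(path)
}
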