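#' Chi distribution survival function for the distance test
#'
#' Under the null hypothesis of no overall effect, each whitened z-score is
#' standard normal, so the distance r is central-chi distributed with
#' degrees of freedom equal to the trait count p; equivalently r^2 is
#' chi-square with p df.
#'
#' @param r distances `>= 0` (vectorized).
#' @param p degrees of freedom (trait count), integer `>= 1`.
#' @return `P(R >= r)` under the central chi distribution.
#' @export
chi_sf <- function(r, p) {
  if (any(r < 0, na.rm = TRUE)) stop("`r` must be >= 0")
  pchisq(r^2, df = p, lower.tail = FALSE)
}

# Storey pi0: proportion of true nulls, estimated by the cubic smoother of
# pi0(lambda) = mean(p > lambda) / (1 - lambda) over the lambda grid,
# evaluated at the largest lambda; falls back to 1 when it misbehaves.
estimate_pi0 <- function(pvec, lambda = seq(0.05, 0.95, by = 0.05)) {
  pi0_l <- vapply(lambda, function(l) mean(pvec > l) / (1 - l), numeric(1))
  pi0 <- tryCatch({
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    predict(fit, x = max(lambda))$y
  }, error = function(e) NA_real_)
  if (is.na(pi0) || pi0 <= 0 || pi0 > 1) {
    if (!is.na(pi0) && pi0 > 1) pi0 <- 1 else {
      warning("pi0 smoother misbehaved; falling back to pi0 = 1")
      pi0 <- 1
    }
  }
  pi0
}

#' False discovery rate q-values
#'
#' Storey q-values: `q_(i) = min_{k >= i} pi0 * m * p_(k) / k` with pi0
#' estimated by the smoother method (cubic smoothing spline of the
#' tail-based estimates over lambda = 0.05, 0.10, ..., 0.95, evaluated at
#' 0.95 and clipped to (0, 1]). `method = "bh"` forces pi0 = 1, which
#' reproduces the Benjamini-Hochberg adjustment.
#'
#' @param pvec p-values in `[0, 1]`.
#' @param method `"storey"` (default) or `"bh"`.
#' @return q-values in input order.
#' @export
qvalues <- function(pvec, method = c("storey", "bh")) {
  method <- match.arg(method)
  if (length(pvec) == 0L) stop("empty p-value vector")
  if (any(pvec < 0 | pvec > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(pvec)
  pi0 <- if (method == "storey" && m >= 100) estimate_pi0(pvec) else 1
  o <- order(pvec)
  q <- pi0 * m * pvec[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Two-stage selection of significantly shared SNPs
#'
#' Stage 1 tests the overall effect: `p_r` from the chi distribution, with
#' q-values over all SNPs; only SNPs with `q_r < r_q_threshold` proceed.
#' Stage 2 tests sharedness: `p_theta` from the von Mises tail (reported
#' for every SNP for diagnostics), but `q_theta` is computed strictly on
#' the stage-1 survivor subset. A SNP is flagged shared when it passes
#' both stages.
#'
#' @param polar a `polar_table` from [to_polar()] (on whitened scores).
#' @param curve a `kappa_curve` for the same trait count.
#' @param r_q_threshold,theta_q_threshold q-value cut-offs (default 0.05
#'   each).
#' @param tol von Mises series truncation threshold.
#' @param qvalue_method passed to [qvalues()].
#' @return A `result_table` data.frame: variant metadata (when present),
#'   `r`, `theta_trans`, `p_r`, `q_r`, `p_theta`, `q_theta` (NA outside the
#'   survivor subset) and `shared_flag`.
#' @export
two_stage_select <- function(polar, curve,
                             r_q_threshold = 0.05, theta_q_threshold = 0.05,
                             tol = 1e-8, qvalue_method = "storey") {
  stopifnot(inherits(polar, "polar_table"))
  p <- attr(polar, "p")
  p_r <- chi_sf(polar$r, p)
  q_r <- qvalues(p_r, method = qvalue_method)
  p_theta <- theta_pvalues(polar, curve, tol = tol)
  survivor <- q_r < r_q_threshold
  q_theta <- rep(NA_real_, nrow(polar))
  if (!any(survivor)) {
    warning("no SNPs pass the distance-test FDR threshold; empty stage 2")
  } else {
    q_theta[survivor] <- qvalues(p_theta[survivor], method = qvalue_method)
  }
  shared <- survivor & !is.na(q_theta) & q_theta < theta_q_threshold
  meta_cols <- intersect(c("id", "chrom", "pos"), names(polar))
  out <- cbind(as.data.frame(polar)[, meta_cols, drop = FALSE],
               data.frame(r = polar$r, theta_trans = polar$theta_trans,
                          p_r = p_r, q_r = q_r, p_theta = p_theta,
                          q_theta = q_theta, shared_flag = shared))
  attr(out, "p") <- p
  attr(out, "thresholds") <- c(r = r_q_threshold, theta = theta_q_threshold)
  class(out) <- c("result_table", "data.frame")
  out
}

#' Write a result table as TSV
#'
#' @param results a `result_table` from [two_stage_select()].
#' @param path output path.
#' @export
write_results <- function(results, path) {
  data.table::fwrite(as.data.frame(results), path, sep = "\t")
  invisible(path)
}
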