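# Symmetric inverse square root via eigen-decomposition.
# Eigenvalues are floored for stability on near-singular correlation.
inv_sqrt_sym <- function(S, floor = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("covariance/correlation matrix is singular (non-positive eigenvalue)")
  vals <- pmax(e$values, floor)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' Estimate the null inter-trait covariance of z-scores
#'
#' Two-pass estimator: pass 1 computes the zero-mean covariance
#' `crossprod(Z)/m` on all rows; pass 2 recomputes it on the rows whose
#' Mahalanobis distance (square root of the quadratic form under the pass-1
#' covariance, zero mean) is below `threshold`, excluding SNPs with a large
#' overall effect from the null estimate. The ZCA-cor whitening matrix is
#' `W = corr^{-1/2} diag(1/sdev)`, i.e. the inverse symmetric square root of
#' the correlation matrix after scale standardization, which decorrelates
#' while keeping each whitened component maximally correlated with its
#' original counterpart.
#'
#' @param panel a [z_panel()] or numeric z-score matrix (m x p, m > 10p).
#' @param threshold Mahalanobis distance cut-off (the distance, not its
#'   square); default 5.
#' @param iterate if `TRUE`, repeat the subset selection with the refitted
#'   covariance until the retained set is stable (max 20 rounds) instead of
#'   the default single refit.
#' @return A `whitening_model`: list with `sigma`, `corr`, `sdev`, `W`,
#'   `n_null`, `mahalanobis_threshold` and `traits`.
#' @export
estimate_null_covariance <- function(panel, threshold = 5, iterate = FALSE) {
  Z <- as_z_matrix(panel)
  m <- nrow(Z); p <- ncol(Z)
  if (m <= 10 * p) stop("need more than 10 * p rows to estimate the null covariance")
  traits <- if (inherits(panel, "z_panel")) panel$traits else colnames(Z)
  if (is.null(traits)) traits <- paste0("trait", seq_len(p))

  S <- crossprod(Z) / m
  keep_prev <- rep(NA, m)
  n2 <- m
  for (round in seq_len(if (iterate) 20L else 1L)) {
    d2 <- rowSums((Z %*% solve(S)) * Z)
    keep <- sqrt(pmax(d2, 0)) < threshold
    n2 <- sum(keep)
    if (n2 < 10 * p)
      stop(sprintf("only %d SNPs below the Mahalanobis threshold (need >= %d); increase `threshold`",
                   n2, 10L * p))
    S <- crossprod(Z[keep, , drop = FALSE]) / n2
    if (identical(keep, keep_prev)) break
    keep_prev <- keep
  }
  sdev <- sqrt(diag(S))
  corr <- cov2cor(S)
  W <- inv_sqrt_sym(corr) %*% diag(1 / sdev, p)
  dimnames(W) <- dimnames(S) <- dimnames(corr) <- list(traits, traits)
  structure(list(sigma = S, corr = corr, sdev = sdev, W = W,
                 n_null = n2,
                 mahalanobis_threshold = threshold, traits = traits),
            class = "whitening_model")
}

#' @export
print.whitening_model <- function(x, ...) {
  cat(sprintf("<whitening_model> %d traits, fitted on %d null SNPs (Mahalanobis < %g)\n",
              length(x$traits), x$n_null, x$mahalanobis_threshold))
  cat("correlation:\n"); print(round(x$corr, 4))
  invisible(x)
}

#' Apply ZCA-cor whitening to a z-score panel
#'
#' Transforms each row z by the model's whitening matrix, `W z`, so that the
#' null-subset sample covariance of the transformed scores is the identity.
#'
#' @param panel a [z_panel()] or z-score matrix with the model's trait order.
#' @param model a `whitening_model` from [estimate_null_covariance()].
#' @return Same class as `panel`, with whitened z-scores.
#' @export
zca_cor_whiten <- function(panel, model) {
  stopifnot(inherits(model, "whitening_model"))
  Z <- as_z_matrix(panel)
  if (ncol(Z) != ncol(model$W)) stop("panel and whitening model disagree on trait count")
  if (inherits(panel, "z_panel") && !identical(panel$traits, model$traits))
    stop("panel and whitening model disagree on trait ordering")
  Zw <- Z %*% t(model$W)
  if (inherits(panel, "z_panel")) {
    z_panel(panel$variants, Zw, panel$traits)
  } else {
    colnames(Zw) <- colnames(Z)
    Zw
  }
}

#' Serialize a whitening model to JSON text
#'
#' Matrices are stored row-major with trait names, the Mahalanobis threshold
#' and the null-SNP count, for reuse and audit.
#'
#' @param model a `whitening_model`.
#' @param path output path.
#' @export
write_whitening_model <- function(model, path) {
  stopifnot(inherits(model, "whitening_model"))
  obj <- list(traits = model$traits,
              sigma = as.vector(t(model$sigma)),
              corr = as.vector(t(model$corr)),
              sdev = as.vector(model$sdev),
              W = as.vector(t(model$W)),
              n_null = model$n_null,
              mahalanobis_threshold = model$mahalanobis_threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_whitening_model
#' @export
read_whitening_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$traits)
  unflat <- function(v) matrix(as.numeric(v), p, p, byrow = TRUE,
                               dimnames = list(obj$traits, obj$traits))
  structure(list(sigma = unflat(obj$sigma), corr = unflat(obj$corr),
                 sdev = as.numeric(obj$sdev), W = unflat(obj$W),
                 n_null = as.integer(obj$n_null),
                 mahalanobis_threshold = as.numeric(obj$mahalanobis_threshold),
                 traits = as.character(obj$traits)),
            class = "whitening_model")
}
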