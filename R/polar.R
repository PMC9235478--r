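#' Distance from the origin
#'
#' Euclidean norm of each z-score row: the per-SNP overall effect size
#' \eqn{r = \sqrt{\sum_j z_j^2}}.
#'
#' @param z numeric vector (one SNP) or matrix (SNPs x traits).
#' @return Scalar or length-m vector of distances, all >= 0.
#' @export
radius <- function(z) {
  if (is.matrix(z)) sqrt(rowSums(z^2)) else sqrt(sum(z^2))
}

#' Quadrant-folded angle for two traits
#'
#' Angle with the x-axis after folding all quadrants on top of each other,
#' i.e. `atan(|zy| / |zx|)` in `[0, pi/2]`. Direction of effect is
#' deliberately discarded: each quadrant differs only in effect sign.
#' A (0, 0) row gets angle 0 (such rows never reach the angle test).
#'
#' @param zx,zy z-scores for the two traits (vectorized).
#' @return Angles in `[0, pi/2]`.
#' @export
folded_angle_2d <- function(zx, zy) {
  ifelse(zx == 0 & zy == 0, 0, atan2(abs(zy), abs(zx)))
}

#' Fourfold angle transform
#'
#' Stretches the folded angle so it covers the full circle:
#' `theta_trans = 4 * theta mod 2*pi`. Both trait axes map to 0 (the
#' trait-specific null direction) and the diagonal maps to pi (maximal
#' sharedness, the antipode of the null).
#'
#' @param theta angles in `[0, pi/2]`.
#' @return Angles in `[0, 2*pi)`.
#' @export
fourfold_transform <- function(theta) {
  if (any(theta < 0 | theta > pi / 2 + 1e-12, na.rm = TRUE))
    stop("fourfold_transform() expects angles in [0, pi/2]")
  (4 * theta) %% (2 * pi)
}

#' Angle to the nearest trait axis (general p)
#'
#' Works on absolute values of the row (folding all orthants), takes the
#' axis of the largest |z| as the null direction, and returns
#' `acos(max_j |z_j| / r)` together with that axis index. Ties go to the
#' lowest trait index (the angle itself is unaffected by the choice).
#'
#' @param z numeric vector (one SNP) or matrix (SNPs x traits).
#' @return List with `angle` (in `[0, acos(1/sqrt(p))]`) and `axis`.
#' @export
nearest_axis_angle <- function(z) {
  zm <- if (is.matrix(z)) abs(z) else matrix(abs(z), nrow = 1)
  r <- sqrt(rowSums(zm^2))
  axis <- max.col(zm, ties.method = "first")
  zmax <- zm[cbind(seq_len(nrow(zm)), axis)]
  angle <- ifelse(r == 0, 0, acos(pmin(1, zmax / r)))
  if (!is.matrix(z)) list(angle = angle[1], axis = axis[1])
  else list(angle = angle, axis = axis)
}

#' Angle normalization factor
#'
#' The nearest-axis angle is maximal when all |z| coordinates are equal,
#' at `theta_max(p) = acos(1/sqrt(p))`. The factor `pi / theta_max(p)`
#' rescales angles so maximal sharedness always maps to pi regardless of
#' the trait count; at p = 2 it equals 4, matching the fourfold transform.
#'
#' @param p trait count, integer >= 2.
#' @return The multiplier `pi / acos(1/sqrt(p))`.
#' @export
angle_norm_factor <- function(p) {
  if (any(p < 2)) stop("angle normalization needs p >= 2")
  pi / acos(1 / sqrt(p))
}

#' Convert a whitened z-score panel to polar coordinates
#'
#' Computes per SNP the distance `r`, the nearest-axis angle `theta_raw`,
#' and the normalized sharedness angle
#' `theta_trans = theta_raw * angle_norm_factor(p)` in `[0, pi]`. For p = 2
#' this equals the fourfold transform of the folded angle re-expressed as
#' angular deviation from the null direction 0. Zero rows (r = 0) are
#' flagged degenerate with theta_trans = 0; they are never significant on r
#' so they never reach the angle test.
#'
#' @param panel a (whitened) [z_panel()] or numeric z-score matrix.
#' @return A `polar_table`: data.frame with columns `id`, `chrom`, `pos`
#'   (when available), `r`, `theta_raw`, `theta_trans`, `axis`,
#'   `degenerate`, with the trait count in attribute `p`.
#' @export
to_polar <- function(panel) {
  Z <- as_z_matrix(panel)
  p <- ncol(Z)
  if (p < 2) stop("polar transform needs at least 2 traits")
  r <- radius(Z)
  naa <- nearest_axis_angle(Z)
  degenerate <- r == 0
  theta_trans <- naa$angle * angle_norm_factor(p)
  theta_trans[degenerate] <- 0
  out <- data.frame(r = r, theta_raw = naa$angle, theta_trans = theta_trans,
                    axis = naa$axis, degenerate = degenerate)
  if (inherits(panel, "z_panel"))
    out <- cbind(panel$variants[, c("id", "chrom", "pos")], out)
  attr(out, "p") <- p
  class(out) <- c("polar_table", "data.frame")
  out
}

#' @export
`[.polar_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "p") <- attr(x, "p")
    class(out) <- c("polar_table", "data.frame")
  }
  out
}

#' Write a polar table as TSV
#'
#' @param polar a `polar_table` from [to_polar()].
#' @param path output path.
#' @export
write_polar <- function(polar, path) {
  df <- as.data.frame(polar)
  for (col in c("r", "theta_raw", "theta_trans"))
    df[[col]] <- sprintf("%.17g", df[[col]])  # full precision round trip
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
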