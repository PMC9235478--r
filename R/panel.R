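#' Multi-trait z-score panel
#'
#' Container for an aligned m x p matrix of per-SNP, per-trait z-scores plus
#' variant metadata. All downstream stages (whitening, polar transform,
#' significance) operate on this object. Rows are variants, columns traits;
#' alleles of every row are expressed on the first trait's orientation.
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ea`, `oa`
#'   and logical `ambiguous` (strand-ambiguous A/T or C/G variant).
#' @param Z numeric matrix of z-scores, `nrow(variants)` x `length(traits)`.
#' @param traits character vector of trait labels (length >= 2).
#'
#' @return An object of class `z_panel`: a list with elements `variants`,
#'   `Z` and `traits`.
#' @export
z_panel <- function(variants, Z, traits) {
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  if (!is.data.frame(variants)) stop("`variants` must be a data.frame")
  if (nrow(variants) != nrow(Z)) stop("variants and Z disagree on row count")
  if (length(traits) != ncol(Z)) stop("traits and Z disagree on column count")
  if (length(traits) < 2) stop("a z-score panel needs at least 2 traits")
  if (anyNA(Z) || any(!is.finite(Z))) stop("Z must be finite with no missing cells")
  colnames(Z) <- traits
  structure(list(variants = variants, Z = Z, traits = as.character(traits)),
            class = "z_panel")
}

#' @export
print.z_panel <- function(x, ...) {
  cat(sprintf("<z_panel> %d variants x %d traits (%s)\n",
              nrow(x$Z), length(x$traits), paste(x$traits, collapse = ", ")))
  cat(sprintf("  strand-ambiguous flagged: %d\n", sum(x$variants$ambiguous)))
  invisible(x)
}

#' @export
dim.z_panel <- function(x) dim(x$Z)

# Accept either a z_panel or a bare numeric matrix wherever only the
# z-scores matter (simulation-level code paths).
as_z_matrix <- function(x) {
  if (inherits(x, "z_panel")) return(x$Z)
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  stop("expected a z_panel or a numeric matrix")
}

# minimal variant metadata for matrix-only inputs
null_variants <- function(m) {
  data.frame(id = sprintf("snp%06d", seq_len(m)),
             chrom = "1", pos = seq_len(m), ea = "A", oa = "G",
             ambiguous = FALSE, stringsAsFactors = FALSE)
}

#' Write / read a merged z-score panel as TSV
#'
#' Numeric z columns are serialized at full double precision (17 significant
#' digits) so that a write/read round trip is bit-identical.
#'
#' @param panel a [z_panel()].
#' @param path output file path.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` returns a
#'   [z_panel()].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "z_panel"))
  df <- panel$variants[, c("id", "chrom", "pos", "ea", "oa")]
  zcols <- as.data.frame(apply(panel$Z, 2, function(z) sprintf("%.17g", z)),
                         stringsAsFactors = FALSE)
  names(zcols) <- paste0("z_", panel$traits)
  df <- cbind(df, zcols, ambiguous = panel$variants$ambiguous)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  zc <- grep("^z_", names(df), value = TRUE)
  if (length(zc) < 2) stop("panel file has fewer than 2 z_<trait> columns")
  Z <- as.matrix(df[, zc, drop = FALSE])
  variants <- data.frame(id = as.character(df$id), chrom = as.character(df$chrom),
                         pos = as.integer(df$pos), ea = df$ea, oa = df$oa,
                         ambiguous = as.logical(df$ambiguous),
                         stringsAsFactors = FALSE)
  z_panel(variants, Z, sub("^z_", "", zc))
}
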