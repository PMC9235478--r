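#' Column mapping for summary-statistic files
#'
#' GWAS summary statistics come in many dialects; this helper names the
#' columns holding each required field. Either (`beta`, `se`) or `z` must be
#' mapped: when `z` is mapped it is taken verbatim, otherwise z = beta / se.
#'
#' @param snp,chr,pos,ea,oa,beta,se,z column names in the input file
#'   (`ea` = effect allele, `oa` = other allele). Set `z` to map a
#'   precomputed z-score column; set `beta`/`se` to `NULL` if absent.
#' @return A named list usable as `column_map` in [read_sumstats()].
#' @export
sumstats_columns <- function(snp = "snp", chr = "chr", pos = "pos",
                             ea = "ea", oa = "oa",
                             beta = "beta", se = "se", z = NULL) {
  list(snp = snp, chr = chr, pos = pos, ea = ea, oa = oa,
       beta = beta, se = se, z = z)
}

#' Read one trait's GWAS summary statistics
#'
#' Reads a delimited text file with a header, maps columns via `column_map`,
#' computes z = beta/se when no z column is mapped, and drops unusable rows
#' (se <= 0, missing or identical alleles, non-finite values, position < 1).
#' Dropped-row counts are kept in the `n_dropped` attribute. Duplicated
#' variant ids keep their first occurrence with a warning.
#'
#' @param path file path (tab-, comma- or whitespace-delimited, with header).
#' @param trait_name label for this trait.
#' @param column_map see [sumstats_columns()].
#' @param delim field delimiter; `"auto"` (default) autodetects.
#' @return A `trait_scan`: data.frame with columns id, chrom, pos, ea, oa,
#'   beta, se, z, and attributes `trait_name` and `n_dropped`.
#' @export
read_sumstats <- function(path, trait_name,
                          column_map = sumstats_columns(), delim = "auto") {
  raw <- if (identical(delim, "auto")) {
    data.table::fread(path, data.table = FALSE)
  } else {
    data.table::fread(path, sep = delim, data.table = FALSE)
  }
  need <- c("snp", "chr", "pos", "ea", "oa")
  has_z <- !is.null(column_map$z)
  need <- c(need, if (has_z) "z" else c("beta", "se"))
  for (field in need) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(raw))
      stop(sprintf("mapped column '%s' (field '%s') not found in %s",
                   if (is.null(col)) "<unmapped>" else col, field, path))
  }
  pick <- function(field) raw[[column_map[[field]]]]
  df <- data.frame(
    id = as.character(pick("snp")),
    chrom = as.character(pick("chr")),
    pos = suppressWarnings(as.integer(pick("pos"))),
    ea = toupper(as.character(pick("ea"))),
    oa = toupper(as.character(pick("oa"))),
    stringsAsFactors = FALSE
  )
  if (has_z) {
    df$z <- suppressWarnings(as.numeric(pick("z")))
    df$beta <- if (!is.null(column_map$beta) && column_map$beta %in% names(raw))
      suppressWarnings(as.numeric(pick("beta"))) else NA_real_
    df$se <- if (!is.null(column_map$se) && column_map$se %in% names(raw))
      suppressWarnings(as.numeric(pick("se"))) else NA_real_
  } else {
    df$beta <- suppressWarnings(as.numeric(pick("beta")))
    df$se <- suppressWarnings(as.numeric(pick("se")))
    df$z <- df$beta / df$se
  }

  n_dropped <- c(bad_se = 0L, bad_alleles = 0L, nonfinite = 0L,
                 bad_pos = 0L, duplicate = 0L)
  bad_alleles <- is.na(df$ea) | is.na(df$oa) | df$ea == "" | df$oa == "" |
    df$ea == df$oa
  bad_se <- if (has_z) rep(FALSE, nrow(df)) else (is.na(df$se) | df$se <= 0)
  nonfinite <- !is.finite(df$z)
  bad_pos <- is.na(df$pos) | df$pos < 1L
  # count each row once, in rule order
  n_dropped["bad_se"] <- sum(bad_se)
  n_dropped["bad_alleles"] <- sum(bad_alleles & !bad_se)
  n_dropped["nonfinite"] <- sum(nonfinite & !bad_se & !bad_alleles)
  n_dropped["bad_pos"] <- sum(bad_pos & !bad_se & !bad_alleles & !nonfinite)
  keep <- !(bad_se | bad_alleles | nonfinite | bad_pos)
  df <- df[keep, , drop = FALSE]
  dup <- duplicated(df$id)
  if (any(dup)) {
    warning(sprintf("%s: %d duplicated variant id(s); keeping first occurrence",
                    trait_name, sum(dup)))
    n_dropped["duplicate"] <- sum(dup)
    df <- df[!dup, , drop = FALSE]
  }
  if (nrow(df) == 0L)
    stop(sprintf("no parseable rows in %s for trait '%s'", path, trait_name))
  rownames(df) <- NULL
  structure(df, trait_name = trait_name, n_dropped = n_dropped,
            class = c("trait_scan", "data.frame"))
}

#' Write a trait scan back to disk
#'
#' Numeric columns are written at full double precision so re-reading with
#' [read_sumstats()] reproduces z-scores bit-identically.
#'
#' @param scan a `trait_scan` from [read_sumstats()].
#' @param path output path (tab-delimited).
#' @export
write_sumstats <- function(scan, path) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(snp = scan$id, chr = scan$chrom, pos = scan$pos,
                    ea = scan$ea, oa = scan$oa,
                    beta = fmt(scan$beta), se = fmt(scan$se), z = fmt(scan$z),
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

# reverse complement, vectorized over allele strings
revcomp <- function(x) {
  flipped <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

is_palindromic <- function(ea, oa) ea == revcomp(oa)

#' Harmonize alleles across traits and assemble the z-score panel
#'
#' Restricts to variants present in every scan and expresses each variant on
#' the first trait's allele orientation: a swapped (effect, other) pair flips
#' the z sign; when neither direct nor swapped alleles match, a reverse-
#' complement (strand flip) match is attempted unless the pair is
#' strand-ambiguous (A/T or C/G); variants that still do not match are
#' dropped. Strand-ambiguous variants are retained but flagged.
#'
#' @param scans list of >= 2 `trait_scan` objects.
#' @param drop_ambiguous drop strand-ambiguous (palindromic) variants rather
#'   than flagging them.
#' @return A [z_panel()].
#' @export
harmonize_and_merge <- function(scans, drop_ambiguous = FALSE) {
  if (length(scans) < 2) stop("need at least 2 trait scans")
  traits <- vapply(scans, function(s) attr(s, "trait_name"), character(1))
  if (anyDuplicated(traits)) stop("trait names must be unique")
  common <- Reduce(intersect, lapply(scans, function(s) s$id))
  if (length(common) == 0L) stop("no variants shared by all scans")

  base <- scans[[1]]
  base <- base[match(common, base$id), , drop = FALSE]
  m <- nrow(base)
  Z <- matrix(NA_real_, m, length(scans))
  Z[, 1] <- base$z
  keep <- rep(TRUE, m)
  pal <- is_palindromic(base$ea, base$oa)

  for (k in seq_along(scans)[-1]) {
    s <- scans[[k]][match(common, scans[[k]]$id), , drop = FALSE]
    direct <- s$ea == base$ea & s$oa == base$oa
    swapped <- s$ea == base$oa & s$oa == base$ea
    unresolved <- !(direct | swapped) & !pal
    if (any(unresolved)) {
      rc_ea <- revcomp(s$ea[unresolved])
      rc_oa <- revcomp(s$oa[unresolved])
      rc_direct <- rc_ea == base$ea[unresolved] & rc_oa == base$oa[unresolved]
      rc_swapped <- rc_ea == base$oa[unresolved] & rc_oa == base$ea[unresolved]
      direct[unresolved] <- rc_direct
      swapped[unresolved] <- rc_swapped & !rc_direct
    }
    Z[, k] <- ifelse(direct, s$z, ifelse(swapped, -s$z, NA_real_))
    keep <- keep & (direct | swapped)
  }
  if (drop_ambiguous) keep <- keep & !pal
  if (!any(keep)) stop("no variants left after allele harmonization")

  variants <- data.frame(id = base$id, chrom = base$chrom, pos = base$pos,
                         ea = base$ea, oa = base$oa, ambiguous = pal,
                         stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(variants) <- NULL
  z_panel(variants, Z[keep, , drop = FALSE], traits)
}
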