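#' Configuration for an end-to-end pipeline run
#'
#' @param sumstats character vector of >= 2 summary-statistic file paths.
#' @param trait_names labels per file; defaults to file base names.
#' @param column_maps a single [sumstats_columns()] applied to every file,
#'   or a list with one map per file.
#' @param whiten estimate the null covariance and apply ZCA-cor whitening
#'   (disable when supplying pre-whitened z-scores).
#' @param mahalanobis_threshold null-covariance subset cut-off.
#' @param r_q_threshold,theta_q_threshold two-stage FDR thresholds.
#' @param qvalue_method `"storey"` or `"bh"`.
#' @param tol von Mises series truncation threshold, in (0, 1e-4].
#' @param kappa_curve `"builtin"` or a path to a curve written by
#'   [write_kappa_curve()].
#' @param drop_ambiguous drop strand-ambiguous variants during merging.
#' @param seed RNG seed recorded in the manifest (the deterministic
#'   pipeline itself consumes no randomness).
#' @param out_prefix path prefix for output files.
#' @return A `run_config` list.
#' @export
run_config <- function(sumstats, trait_names = NULL,
                       column_maps = sumstats_columns(),
                       whiten = TRUE, mahalanobis_threshold = 5,
                       r_q_threshold = 0.05, theta_q_threshold = 0.05,
                       qvalue_method = "storey", tol = 1e-8,
                       kappa_curve = "builtin", drop_ambiguous = FALSE,
                       seed = 1L, out_prefix = "pleiopolar") {
  if (length(sumstats) < 2) stop("need at least 2 summary-statistic files")
  stopifnot(r_q_threshold > 0, r_q_threshold < 1,
            theta_q_threshold > 0, theta_q_threshold < 1,
            tol > 0, tol <= 1e-4)
  if (is.null(trait_names))
    trait_names <- sub("\\.[^.]*$", "", basename(sumstats))
  if (length(trait_names) != length(sumstats))
    stop("one trait name per summary-statistic file required")
  structure(list(sumstats = sumstats, trait_names = trait_names,
                 column_maps = column_maps, whiten = isTRUE(whiten),
                 mahalanobis_threshold = mahalanobis_threshold,
                 r_q_threshold = r_q_threshold,
                 theta_q_threshold = theta_q_threshold,
                 qvalue_method = qvalue_method, tol = tol,
                 kappa_curve = kappa_curve,
                 drop_ambiguous = isTRUE(drop_ambiguous),
                 seed = as.integer(seed), out_prefix = out_prefix),
            class = "run_config")
}

#' Run the full pleiotropy pipeline
#'
#' read -> harmonize/merge -> (null covariance, whitening) -> polar
#' transform -> chi distance test and q-values -> kappa lookup, angle
#' p-values and survivor-only q-values -> shared flags. Writes the result
#' table (`<prefix>.results.tsv`), the whitening model
#' (`<prefix>.whitening.json`) and a run manifest with the configuration,
#' seed and row counts at every stage (`<prefix>.manifest.json`).
#'
#' @param config a [run_config()].
#' @param write_outputs write the three artifact files (default TRUE).
#' @return The `result_table`, invisibly.
#' @export
run_pipeline <- function(config, write_outputs = TRUE) {
  stopifnot(inherits(config, "run_config"))
  maps <- config$column_maps
  if (!is.null(maps$snp)) maps <- rep(list(maps), length(config$sumstats))
  counts <- list()

  scans <- vector("list", length(config$sumstats))
  for (k in seq_along(config$sumstats)) {
    scans[[k]] <- read_sumstats(config$sumstats[k], config$trait_names[k],
                                column_map = maps[[k]])
    counts[[paste0("read_", config$trait_names[k])]] <- nrow(scans[[k]])
  }
  panel <- harmonize_and_merge(scans, drop_ambiguous = config$drop_ambiguous)
  counts$merged <- nrow(panel$Z)
  min_in <- min(unlist(counts[grep("^read_", names(counts))]))
  if (counts$merged < 0.5 * min_in)
    warning(sprintf("harmonization dropped more than half of the variants (%d -> %d)",
                    min_in, counts$merged))

  model <- NULL
  if (config$whiten) {
    model <- estimate_null_covariance(panel, threshold = config$mahalanobis_threshold)
    counts$null_covariance_subset <- model$n_null
    panel <- zca_cor_whiten(panel, model)
  }
  polar <- to_polar(panel)
  p <- length(panel$traits)
  curve <- if (identical(config$kappa_curve, "builtin")) {
    builtin_kappa_curve(p)
  } else {
    read_kappa_curve(config$kappa_curve)
  }
  results <- two_stage_select(polar, curve,
                              r_q_threshold = config$r_q_threshold,
                              theta_q_threshold = config$theta_q_threshold,
                              tol = config$tol,
                              qvalue_method = config$qvalue_method)
  counts$stage1_survivors <- sum(results$q_r < config$r_q_threshold)
  counts$shared <- sum(results$shared_flag)

  if (write_outputs) {
    write_results(results, paste0(config$out_prefix, ".results.tsv"))
    if (!is.null(model))
      write_whitening_model(model, paste0(config$out_prefix, ".whitening.json"))
    manifest <- list(
      package = "pleiopolar",
      version = as.character(utils::packageVersion("pleiopolar")),
      config = config[setdiff(names(config), "column_maps")],
      seed = config$seed,
      row_counts = counts)
    jsonlite::write_json(manifest, paste0(config$out_prefix, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(results)
}
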