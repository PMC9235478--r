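#' Collapse shared SNPs into loci by positional clumping
#'
#' Greedy clumping of the significantly shared SNPs: sort by `q_theta`
#' ascending (ties by `p_theta`, then chromosome and position), repeatedly
#' take the best unassigned SNP as a locus lead and absorb every unassigned
#' shared SNP within `window_kb` on the same chromosome. Deterministic, and
#' idempotent on the resulting leads. This is a positional approximation of
#' LD-aware clumping; supply `ld` to additionally require pairwise r^2
#' above `ld_r2` with the lead for absorption.
#'
#' @param results a `result_table` from [two_stage_select()] carrying
#'   `chrom` and `pos`.
#' @param window_kb absorption window around the lead, in kilobases
#'   (default 5000, i.e. 5 Mb).
#' @param q_threshold only SNPs flagged shared with `q_theta` below this
#'   enter clumping.
#' @param ld optional data.frame of precomputed pairwise LD with columns
#'   `id_a`, `id_b`, `r2` (symmetric pairs need not be duplicated).
#' @param ld_r2 minimum r^2 with the lead for absorption when `ld` is given.
#' @return data.frame of loci: `chrom`, `start`, `end` (1-based, closed),
#'   `lead_id`, `n_members`, `member_ids` (comma-separated).
#' @export
positional_clump <- function(results, window_kb = 5000, q_threshold = 0.05,
                             ld = NULL, ld_r2 = 0.2) {
  stopifnot(all(c("chrom", "pos", "q_theta", "p_theta", "shared_flag") %in%
                  names(results)))
  cand <- results[results$shared_flag & !is.na(results$q_theta) &
                    results$q_theta < q_threshold, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      lead_id = character(), n_members = integer(),
                      member_ids = character(), stringsAsFactors = FALSE))
  cand <- cand[order(cand$q_theta, cand$p_theta, cand$chrom, cand$pos), ,
               drop = FALSE]
  window_bp <- window_kb * 1000
  assigned <- rep(FALSE, nrow(cand))
  loci <- list()
  ld_ok <- function(lead_id, ids) {
    if (is.null(ld)) return(rep(TRUE, length(ids)))
    hit <- (ld$id_a == lead_id & ld$id_b %in% ids & ld$r2 >= ld_r2) |
      (ld$id_b == lead_id & ld$id_a %in% ids & ld$r2 >= ld_r2)
    partners <- unique(c(ld$id_b[ld$id_a == lead_id & ld$r2 >= ld_r2],
                         ld$id_a[ld$id_b == lead_id & ld$r2 >= ld_r2]))
    ids %in% partners
  }
  while (!all(assigned)) {
    lead <- which(!assigned)[1]
    same <- !assigned & cand$chrom == cand$chrom[lead] &
      abs(cand$pos - cand$pos[lead]) <= window_bp
    if (!is.null(ld)) {
      others <- same & seq_len(nrow(cand)) != lead
      same[others] <- ld_ok(cand$id[lead], cand$id[others])
      same[lead] <- TRUE
    }
    members <- which(same)
    assigned[members] <- TRUE
    loci[[length(loci) + 1L]] <- data.frame(
      chrom = cand$chrom[lead],
      start = min(cand$pos[members]), end = max(cand$pos[members]),
      lead_id = cand$id[lead], n_members = length(members),
      member_ids = paste(cand$id[members], collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, loci)
}

#' Count how many traits each locus lead is associated with
#'
#' Operationalizes "number of traits a SNP is associated with" from the
#' pairwise runs: a lead appearing in the shared loci of pair (a, b) is
#' associated with both a and b; the count is the number of distinct traits
#' over all pairs.
#'
#' @param pairwise_loci data.frame with one row per locus and columns
#'   `trait_a`, `trait_b`, `lead_id` (e.g. row-bound [positional_clump()]
#'   outputs annotated with their trait pair).
#' @return Named integer vector: lead id -> distinct trait count.
#' @export
count_trait_associations <- function(pairwise_loci) {
  long <- rbind(data.frame(id = pairwise_loci$lead_id, trait = pairwise_loci$trait_a),
                data.frame(id = pairwise_loci$lead_id, trait = pairwise_loci$trait_b))
  counts <- tapply(long$trait, long$id, function(tr) length(unique(tr)))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Build the weighted pleiotropy trait network
#'
#' Nodes are traits; an edge's weight is the sum over that pair's shared
#' loci of the inverse of the number of traits the locus lead is associated
#' with, down-weighting SNPs that tag very general biological processes. A
#' lead shared by exactly two traits contributes 1/2; one associated with
#' seven traits contributes 1/7 to each containing pair.
#'
#' @param pairwise_loci as in [count_trait_associations()].
#' @param snp_trait_counts optional named vector (lead id -> trait count);
#'   computed from `pairwise_loci` when omitted.
#' @return A `trait_network`: list with `nodes` and an `edges` data.frame
#'   (`trait_a`, `trait_b`, `weight`, `n_loci`); edges are symmetric and
#'   stored once with `trait_a < trait_b`.
#' @export
build_network <- function(pairwise_loci, snp_trait_counts = NULL) {
  if (is.null(snp_trait_counts))
    snp_trait_counts <- count_trait_associations(pairwise_loci)
  if (nrow(pairwise_loci) == 0L)
    return(structure(list(nodes = character(),
                          edges = data.frame(trait_a = character(),
                                             trait_b = character(),
                                             weight = numeric(),
                                             n_loci = integer())),
                     class = "trait_network"))
  cnt <- snp_trait_counts[pairwise_loci$lead_id]
  if (anyNA(cnt)) stop("missing trait count for some locus leads")
  a <- pmin(pairwise_loci$trait_a, pairwise_loci$trait_b)
  b <- pmax(pairwise_loci$trait_a, pairwise_loci$trait_b)
  if (any(a == b)) stop("self-pairs are not allowed in the trait network")
  key <- paste(a, b, sep = "\r")
  weight <- tapply(1 / cnt, key, sum)
  n_loci <- tapply(cnt, key, length)
  parts <- strsplit(names(weight), "\r", fixed = TRUE)
  edges <- data.frame(trait_a = vapply(parts, `[`, "", 1),
                      trait_b = vapply(parts, `[`, "", 2),
                      weight = as.numeric(weight),
                      n_loci = as.integer(n_loci),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$trait_a, edges$trait_b))),
                 edges = edges),
            class = "trait_network")
}

#' @export
print.trait_network <- function(x, ...) {
  cat(sprintf("<trait_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) print(head(x$edges, 10))
  invisible(x)
}

#' Collapse a trait network to trait domains
#'
#' Domains inherit an edge whenever any pair of their traits is connected;
#' weights of constituent trait edges are summed. Edges internal to one
#' domain are dropped (no self-edges).
#'
#' @param net a `trait_network`.
#' @param domain_map named character vector: trait -> domain label.
#' @return A `trait_network` over domains.
#' @export
collapse_to_domains <- function(net, domain_map) {
  stopifnot(inherits(net, "trait_network"))
  unmapped <- setdiff(net$nodes, names(domain_map))
  if (length(unmapped))
    stop("traits without a domain mapping: ", paste(unmapped, collapse = ", "))
  nodes <- sort(unique(unname(domain_map[net$nodes])))
  e <- net$edges
  if (nrow(e) == 0L)
    return(structure(list(nodes = nodes,
                          edges = e), class = "trait_network"))
  da <- unname(domain_map[e$trait_a])
  db <- unname(domain_map[e$trait_b])
  keep <- da != db
  e <- e[keep, , drop = FALSE]
  if (nrow(e) == 0L)
    return(structure(list(nodes = nodes,
                          edges = data.frame(trait_a = character(),
                                             trait_b = character(),
                                             weight = numeric(),
                                             n_loci = integer())),
                     class = "trait_network"))
  a <- pmin(da[keep], db[keep]); b <- pmax(da[keep], db[keep])
  key <- paste(a, b, sep = "\r")
  weight <- tapply(e$weight, key, sum)
  n_loci <- tapply(e$n_loci, key, sum)
  parts <- strsplit(names(weight), "\r", fixed = TRUE)
  edges <- data.frame(trait_a = vapply(parts, `[`, "", 1),
                      trait_b = vapply(parts, `[`, "", 2),
                      weight = as.numeric(weight),
                      n_loci = as.integer(n_loci),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "trait_network")
}

#' Write loci and networks as TSV
#'
#' Loci are written BED-like (half-open `start0`), networks as an edge
#' list.
#'
#' @param loci data.frame from [positional_clump()].
#' @param net a `trait_network`.
#' @param path output path.
#' @export
write_loci <- function(loci, path) {
  out <- data.frame(chrom = loci$chrom, start0 = loci$start - 1L,
                    end = loci$end, lead_id = loci$lead_id,
                    n_members = loci$n_members)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_loci
#' @export
write_network <- function(net, path) {
  data.table::fwrite(net$edges, path, sep = "\t")
  invisible(path)
}
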