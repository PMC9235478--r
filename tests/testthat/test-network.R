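# build a minimal result_table by hand for clumping tests
fake_results <- function(id, chrom, pos, q_theta, p_theta = q_theta / 2,
                         shared = TRUE) {
  df <- data.frame(id = id, chrom = as.character(chrom), pos = pos,
                   r = 10, theta_trans = 3, p_r = 1e-10, q_r = 1e-8,
                   p_theta = p_theta, q_theta = q_theta,
                   shared_flag = shared, stringsAsFactors = FALSE)
  class(df) <- c("result_table", "data.frame")
  df
}

test_that("positional clumping partitions shared SNPs by distance and chromosome", {
  res <- fake_results(c("a", "b", "c"), "1", c(1e6, 2e6, 50e6),
                      q_theta = c(0.001, 0.002, 0.003))
  loci <- positional_clump(res, window_kb = 5000)
  expect_equal(nrow(loci), 2)
  expect_equal(loci$lead_id, c("a", "c"))
  expect_equal(loci$n_members, c(2L, 1L))
  expect_equal(loci$start[1], 1e6)
  expect_equal(loci$end[1], 2e6)

  # same position, different chromosomes -> separate loci, deterministic leads
  res2 <- fake_results(c("x", "y"), c("1", "2"), c(5e6, 5e6),
                       q_theta = c(0.01, 0.01), p_theta = c(0.004, 0.005))
  loci2 <- positional_clump(res2)
  expect_equal(nrow(loci2), 2)
  expect_equal(loci2$lead_id[1], "x")  # tie on q broken by p_theta
})

test_that("clumping of no shared SNPs yields an empty locus table", {
  res <- fake_results("a", "1", 100L, q_theta = 0.2, shared = FALSE)
  expect_equal(nrow(positional_clump(res)), 0)
})

test_that("clumping is idempotent: re-clumping the leads returns the same leads", {
  set.seed(51)
  m <- 200
  res <- fake_results(sprintf("s%03d", 1:m),
                      chrom = sample(1:4, m, TRUE),
                      pos = sample.int(8e7, m),
                      q_theta = runif(m, 0, 0.04))
  loci <- positional_clump(res)
  # every shared SNP in exactly one locus
  members <- unlist(strsplit(loci$member_ids, ","))
  expect_setequal(members, res$id)
  expect_equal(anyDuplicated(members), 0L)
  leads_only <- res[res$id %in% loci$lead_id, ]
  loci2 <- positional_clump(leads_only)
  expect_setequal(loci2$lead_id, loci$lead_id)
})

test_that("an LD table restricts absorption to linked SNPs", {
  res <- fake_results(c("a", "b"), "1", c(1e6, 2e6), q_theta = c(0.001, 0.002))
  ld <- data.frame(id_a = "a", id_b = "b", r2 = 0.05)
  loci <- positional_clump(res, ld = ld)       # below ld_r2 -> b not absorbed
  expect_equal(nrow(loci), 2)
  ld$r2 <- 0.5
  expect_equal(nrow(positional_clump(res, ld = ld)), 1)
})

test_that("edge weights are the sum of inverse trait counts of the locus leads", {
  loci <- data.frame(
    trait_a = c("HDL", "HDL", "HDL", "LDL"),
    trait_b = c("LDL", "LDL", "TG", "TG"),
    lead_id = c("s1", "s2", "s1", "s3"),
    stringsAsFactors = FALSE)
  counts <- count_trait_associations(loci)
  expect_equal(unname(counts[c("s1", "s2", "s3")]), c(3L, 2L, 2L))
  net <- build_network(loci)
  e <- net$edges
  expect_equal(e$weight[e$trait_a == "HDL" & e$trait_b == "LDL"], 1/3 + 1/2)
  expect_equal(e$weight[e$trait_a == "HDL" & e$trait_b == "TG"], 1/3)
  expect_equal(e$n_loci[e$trait_a == "HDL" & e$trait_b == "LDL"], 2L)
  expect_true(all(e$trait_a != e$trait_b))
  # a lead associated with 7 traits would contribute 1/7
  counts7 <- c(s9 = 7L)
  net7 <- build_network(data.frame(trait_a = "A", trait_b = "B", lead_id = "s9"),
                        snp_trait_counts = counts7)
  expect_equal(net7$edges$weight, 1 / 7)
})

test_that("an empty loci table gives an empty network", {
  net <- build_network(data.frame(trait_a = character(),
                                  trait_b = character(),
                                  lead_id = character()))
  expect_equal(length(net$nodes), 0)
  expect_equal(nrow(net$edges), 0)
})

test_that("domain collapse merges edges across the partition and drops intra-domain edges", {
  loci <- data.frame(trait_a = c("HDL", "HDL", "SBP"),
                     trait_b = c("LDL", "SBP", "DBP"),
                     lead_id = c("s1", "s2", "s3"),
                     stringsAsFactors = FALSE)
  net <- build_network(loci)
  map <- c(HDL = "Lipids", LDL = "Lipids", SBP = "Pressures", DBP = "Pressures")
  dom <- collapse_to_domains(net, map)
  expect_setequal(dom$nodes, c("Lipids", "Pressures"))
  expect_equal(nrow(dom$edges), 1)              # only Lipids-Pressures survives
  e_hdl_sbp <- net$edges$weight[net$edges$trait_a == "HDL" &
                                  net$edges$trait_b == "SBP"]
  expect_equal(dom$edges$weight, e_hdl_sbp)
  # all traits in one domain -> single node, no edges
  one <- collapse_to_domains(net, c(HDL = "D", LDL = "D", SBP = "D", DBP = "D"))
  expect_equal(one$nodes, "D")
  expect_equal(nrow(one$edges), 0)
  expect_error(collapse_to_domains(net, c(HDL = "D")), "without a domain")
})

test_that("loci and network writers emit well-formed TSV", {
  res <- fake_results(c("a", "b"), "1", c(1e6, 2e6), q_theta = c(0.001, 0.002))
  loci <- positional_clump(res)
  path <- tempfile(fileext = ".tsv")
  write_loci(loci, path)
  bed <- read.delim(path)
  expect_equal(bed$start0, loci$start - 1L)
  net <- build_network(data.frame(trait_a = "A", trait_b = "B", lead_id = "a"))
  write_network(net, path)
  expect_equal(read.delim(path)$weight, 0.5)
})
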