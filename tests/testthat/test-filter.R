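test_that("the 20-SNP fixture yields the hand-enumerated retained sets", {
  g <- toy_fixture_geno()
  perm <- filter_snps(g, filter_config(mmaf = 2 / 48, R = 0.5))
  strict <- filter_snps(g, filter_config(mmaf = 0.05, R = 0.75))
  expect_setequal(perm$snps$snp_id, toy_snp_ids(toy_expected_permissive))
  expect_setequal(strict$snps$snp_id, toy_snp_ids(toy_expected_strict))
  ## the packaged VCF carries the same fixture
  gv <- read_vcf(system.file("extdata", "toy_20snp.vcf",
                             package = "gbspopgen"),
                 system.file("extdata", "toy_metadata.tsv",
                             package = "gbspopgen"))
  pv <- filter_snps(gv, filter_config(mmaf = 2 / 48, R = 0.5))
  expect_setequal(pv$snps$snp_id, toy_snp_ids(toy_expected_permissive))
  ## removal reasons are reported per SNP
  rep1 <- attr(perm, "filter_report")
  expect_equal(sum(rep1$reason_removed == ""), 8L)
})

test_that("no-op settings return the input unchanged", {
  g <- toy_fixture_geno()
  out <- filter_snps(g, filter_config(mmaf = 0, R = 1e-9,
                                      single_snp_per_locus = FALSE))
  expect_identical(out$geno, g$geno)
  expect_identical(out$snps, g$snps)
})

test_that("filtering is monotone in mmaf and R", {
  g <- random_geno(30, 120, miss = 0.25, seed = 3)
  prev_by_maf <- Inf
  for (mmaf in c(0, 0.02, 0.05, 0.1, 0.2, 0.4)) {
    k <- n_snps(suppressWarnings(
      filter_snps(g, filter_config(mmaf = mmaf, R = 0.3,
                                   single_snp_per_locus = FALSE))))
    expect_lte(k, prev_by_maf)
    prev_by_maf <- k
  }
  prev_by_R <- Inf
  for (R in c(0.1, 0.3, 0.5, 0.7, 0.9, 1)) {
    k <- n_snps(suppressWarnings(
      filter_snps(g, filter_config(mmaf = 0.02, R = R,
                                   single_snp_per_locus = FALSE))))
    expect_lte(k, prev_by_R)
    prev_by_R <- k
  }
})

test_that("strict settings retain a subset of permissive settings", {
  g <- random_geno(40, 150, miss = 0.2, seed = 9)
  perm <- filter_snps(g, filter_config(mmaf = 2 / 80, R = 0.5,
                                       single_snp_per_locus = FALSE))
  strict <- filter_snps(g, filter_config(mmaf = 0.05, R = 0.75,
                                         single_snp_per_locus = FALSE))
  expect_true(all(strict$snps$snp_id %in% perm$snps$snp_id))
})

test_that("all-SNP removal warns rather than errors", {
  g <- toy_fixture_geno()
  expect_warning(out <- filter_snps(g, filter_config(mmaf = 0.49, R = 1)),
                 "all SNPs removed")
  expect_equal(n_snps(out), 0L)
})

test_that("identical individuals fall outside half-sib bounds, sibs inside", {
  set.seed(11)
  g <- random_geno(60, 500, miss = 0, seed = 11)
  ## plant a duplicate pair
  g$geno[2, ] <- g$geno[1, ]
  A <- relatedness_matrix(g)
  expect_gt(A[1, 2], 0.85)
  pruned <- relatedness_prune(g, bounds = c(0.25, 0.75))
  expect_false(rownames(g$geno)[1] %in% attr(pruned, "prune_report")$removed)
  expect_equal(nrow(attr(pruned, "prune_report")), 0L)
})

test_that("a planted parent-offspring pair loses exactly one member", {
  set.seed(21)
  n_snp <- 600
  p <- runif(n_snp, 0.2, 0.8)
  pop <- vapply(p, function(pp) rbinom(12, 2, pp), integer(12))
  ## offspring of individuals 1 and 2 replaces individual 12
  transmit <- function(gp) rbinom(length(gp), 1, gp / 2)
  pop[12, ] <- transmit(pop[1, ]) + transmit(pop[2, ])
  g <- make_geno(pop)
  A <- relatedness_matrix(g)
  expect_gt(A[1, 12], 0.3)
  expect_lt(A[1, 12], 0.75)
  pruned <- relatedness_prune(g, bounds = c(0.25, 0.75))
  rep <- attr(pruned, "prune_report")
  expect_gte(nrow(rep), 1L)
  involved <- c(rep$removed, rep$kept)
  expect_true(any(c("i001", "i002", "i012") %in% rep$removed))
})

test_that("unrelated panmictic samples are almost never pruned", {
  removals <- vapply(1:15, function(sd) {
    scn <- simulation_scenario("null_panmixia", n_individuals = 30,
                               n_loci = 300, mu = 2e-6,
                               epochs = data.frame(start_gen = 0, ne = 5000))
    sim <- simulate_coalescent(scn, seed = 200 + sd)
    nrow(attr(relatedness_prune(sim$geno), "prune_report"))
  }, 0L)
  expect_gte(mean(removals == 0), 0.95)
})

test_that("allele frequencies match a brute-force recount", {
  g <- random_geno(15, 40, miss = 0.2, seed = 7)
  grouping <- rep(c("a", "b", "c"), each = 5)
  af <- allele_frequencies(g, grouping)
  for (gr in c("a", "b", "c")) {
    rows <- which(grouping == gr)
    for (s in c(1, 17, 40)) {
      v <- g$geno[rows, s]
      expected_n <- 2 * sum(!is.na(v))
      got <- af[af$group == gr & af$snp_id == g$snps$snp_id[s], ]
      expect_equal(got$n_copies, expected_n)
      if (expected_n > 0)
        expect_equal(got$freq_alt, sum(v, na.rm = TRUE) / expected_n)
      else
        expect_false(got$defined)
    }
  }
  ## single heterozygote
  g1 <- make_geno(matrix(1L, 1, 1))
  af1 <- allele_frequencies(g1, "x")
  expect_equal(af1$freq_alt, 0.5)
  expect_equal(af1$n_copies, 2L)
})
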