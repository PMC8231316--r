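test_that("subpopulation allele frequencies use half-count heterozygotes", {
  gm <- toy_gm(rbind(c(0, 0, 0), c(2, 0, 1), c(0, 0, 1), c(2, 0, 2)))
  labels <- c("p1", "p1", "p2", "p2")
  paf <- pop_allele_frequencies(gm, labels)
  expect_equal(unname(paf$freq["p1", "m1"]), 0.5)  # {0,2} -> 0.5
  expect_equal(unname(paf$freq["p1", "m2"]), 0)    # fixed -> (1, 0)
  expect_equal(unname(allele_count(paf$freq["p1", "m2"])), 1)
  # pop {0,1,1,2} across both pops at m3: minor freq 4/8
  paf_all <- pop_allele_frequencies(gm, rep("all", 4))
  expect_equal(unname(paf_all$freq["all", "m3"]), 0.5)
})

test_that("loci with no data in a subpopulation are flagged and excluded", {
  gm <- toy_gm(rbind(c(0, NA), c(2, NA), c(0, 0), c(2, 2)))
  expect_warning(paf <- pop_allele_frequencies(gm, c("a", "a", "b", "b")),
                 "excluded")
  expect_true(paf$excluded["a", "m2"])
  expect_true(is.na(paf$freq["a", "m2"]))
})

test_that("allele counts respect the frequency threshold", {
  expect_equal(allele_count(0.03), 2)            # present counts at any freq
  expect_equal(allele_count(0.03, 0.05), 1)      # rare allele drops out
  expect_equal(allele_count(0.05, 0.05), 2)      # inclusive bound
  expect_equal(allele_count(0), 1)
  expect_equal(allele_count(c(0.5, 0, 0.02), 0.05), c(2, 1, 1))
})

test_that("Ne, Shannon's I, h and uh evaluate their closed forms", {
  expect_equal(effective_alleles(0.5), 2)
  expect_equal(effective_alleles(0), 1)
  expect_equal(effective_alleles(0.2), 1 / 0.68, tolerance = 1e-12)
  expect_equal(shannon_index(0.5), log(2))
  expect_equal(shannon_index(0), 0)
  expect_equal(shannon_index(0.1), 0.3250830, tolerance = 1e-6)
  hu <- haploid_diversity(0.5, 10)
  expect_equal(hu$h, 0.5)
  expect_equal(hu$uh, 10 / 9 * 0.5)
  expect_equal(haploid_diversity(0, 5)$h, 0)
  expect_true(is.na(haploid_diversity(0.5, 1)$uh))
})

test_that("diversity identities hold on a frequency grid", {
  f <- seq(0, 0.5, by = 0.01)
  ne <- effective_alleles(f)
  h <- haploid_diversity(f, 20)$h
  expect_equal(h, 1 - 1 / ne, tolerance = 1e-12)     # h = 1 - 1/Ne
  uh <- haploid_diversity(f, 20)$uh
  expect_equal(uh[h > 0] / h[h > 0], rep(20 / 19, sum(h > 0)))
  # I, h, Ne maximal at 0.5, zero/unity at fixation
  expect_equal(which.max(shannon_index(f)), length(f))
  expect_equal(which.max(ne), length(f))
  expect_equal(shannon_index(0), 0)
  expect_equal(ne[1], 1)
})

test_that("private alleles are enumerated per population and per line", {
  # 2 pops x 5 loci; pop2 carries 3 private alleles spread over 2 lines
  calls <- rbind(
    p1a = c(0, 0, 0, 0, 2),
    p1b = c(0, 0, 0, 2, 0),
    p2a = c(2, 1, 0, 0, 2), # private minor at m1, m2
    p2b = c(0, 0, 2, 2, 0)) # private minor at m3
  gm <- toy_gm(calls)
  labels <- c("p1", "p1", "p2", "p2")
  paf <- pop_allele_frequencies(gm, labels)
  pa <- private_alleles(paf, gm, labels)
  expect_equal(unname(pa$pa_mean["p2"]), 3 / 5)
  expect_equal(unname(pa$pa_mean["p1"]), 0)
  counts <- pa$per_line$pa_count[pa$per_line$group == "p2"]
  expect_setequal(counts, c(2, 1))
  expect_equal(unname(pa$lines_with_pa["p2"]), 2)
  expect_equal(unname(pa$pa_range["p2", ]), c(1, 2))

  # identical frequency profiles -> no private alleles anywhere
  same <- toy_gm(rbind(c(0, 2), c(2, 0), c(0, 2), c(2, 0)))
  paf2 <- pop_allele_frequencies(same, labels)
  pa2 <- private_alleles(paf2, same, labels)
  expect_true(all(pa2$pa_mean == 0))
  expect_error(private_alleles(
    pop_allele_frequencies(same, rep("x", 4)), same, rep("x", 4)),
    "2 subpopulations")
})

test_that("fixed private alleles score every carrier line", {
  gm <- toy_gm(rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2)))
  labels <- c("a", "a", "b", "b")
  paf <- pop_allele_frequencies(gm, labels)
  pa <- private_alleles(paf, gm, labels)
  # m1: minor fixed in b, absent in a -> private to b, both b lines carry it
  expect_equal(pa$per_line$pa_count[3:4] >= 1, c(TRUE, TRUE))
})

test_that("diversity report assembles indices with Mean as arithmetic mean", {
  sim <- simulate_panel(sim_config(n_per_group = c(12, 14), n_loci = 150,
                                   fst = 0.1, seed = 71))
  dr <- diversity_report(sim$gm, sim$truth$labels)
  expect_equal(dim(dr$table), c(7, 3))
  expect_equal(unname(dr$table[, "Mean"]),
               unname(rowMeans(dr$table[, 1:2])))
  # standard errors are across-locus sd / sqrt(L)
  paf <- pop_allele_frequencies(sim$gm, sim$truth$labels)
  ne1 <- effective_alleles(paf$freq[1, ])
  expect_equal(unname(dr$se["Ne", 1]),
               sd(ne1) / sqrt(length(ne1)), tolerance = 1e-12)
  expect_equal(unname(dr$table["Ne", 1]), mean(ne1))
  # Na on a fully segregating subpopulation reaches 2
  expect_lte(max(dr$table["Na", 1:2]), 2)
  expect_gte(min(dr$table["Na", 1:2]), 1)
})
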