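# classical one-way ANOVA sums of squares on 1-D coordinates; for squared
# Euclidean distances the AMOVA decomposition must coincide with this
anova_ss_oracle <- function(x, labels) {
  grand <- mean(x)
  ss_within <- sum(unlist(lapply(split(x, labels), function(g) {
    sum((g - mean(g))^2)
  })))
  ss_among <- sum(unlist(lapply(split(x, labels), function(g) {
    length(g) * (mean(g) - grand)^2
  })))
  list(among = ss_among, within = ss_within)
}

test_that("squared distance matrix is the squared Euclidean dosage distance", {
  X <- rbind(a = c(0, 0), b = c(2, 2), c = c(0, 0))
  D2 <- squared_distance_matrix(X)
  expect_equal(D2["a", "b"], 8)
  expect_equal(D2["a", "c"], 0)
  expect_equal(diag(D2), setNames(rep(0, 3), rownames(X)))
  expect_error(squared_distance_matrix(rbind(c(0, NA), c(1, 2))), "impute")
  # relaxed triangle inequality for squared Euclidean metrics
  set.seed(21)
  Y <- matrix(sample(0:2, 60, replace = TRUE), 6, 10)
  D <- squared_distance_matrix(Y)
  for (a in 1:6) for (b in 1:6) for (cc in 1:6) {
    expect_lte(D[a, cc], 2 * (D[a, b] + D[b, cc]) + 1e-9)
  }
})

test_that("AMOVA matches the brute-force ANOVA oracle on 1-D embeddings", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    x <- sample(0:2, n, replace = TRUE)
    labels <- rep(c("g1", "g2"), c(floor(n / 2), ceiling(n / 2)))
    if (rep == 5) { # three unequal groups
      labels <- rep(c("g1", "g2", "g3"), length.out = n)
    }
    D2 <- squared_distance_matrix(matrix(x, ncol = 1))
    am <- amova_one_level(D2, labels, n_perm = 0)
    oracle <- anova_ss_oracle(x, labels)
    expect_equal(am$SS_among, oracle$among, tolerance = 1e-9)
    expect_equal(am$SS_within, oracle$within, tolerance = 1e-9)
    expect_equal(am$SS_total, oracle$among + oracle$within,
                 tolerance = 1e-9)
  }
})

test_that("AMOVA decomposition agrees with an independent PERMANOVA on SS", {
  skip_if_not_installed("vegan")
  gm <- random_panel(n = 16, L = 40, fst = 0.2, seed = 32)
  labels <- rep(c("a", "b"), each = 8)
  D2 <- squared_distance_matrix(gm$calls)
  am <- amova_one_level(D2, labels, n_perm = 0)
  ad <- vegan::adonis2(stats::as.dist(sqrt(D2)) ~ labels, permutations = 0)
  expect_equal(am$SS_among, ad$SumOfSqs[1], tolerance = 1e-8)
  expect_equal(am$SS_within, ad$SumOfSqs[2], tolerance = 1e-8)
})

test_that("degenerate groupings behave: all variance among, or none", {
  X <- rbind(matrix(0, 3, 5), matrix(2, 3, 5))
  D2 <- squared_distance_matrix(X)
  am <- amova_one_level(D2, rep(c("p1", "p2"), each = 3), n_perm = 0)
  expect_equal(am$pct_among, 100)
  expect_equal(am$phi_pt, 1)

  # homogeneous data with arbitrary labels: negligible differentiation
  set.seed(41)
  phis <- replicate(5, {
    Y <- matrix(sample(0:2, 200, replace = TRUE, prob = c(.45, .1, .45)),
                20, 10)
    amova_one_level(squared_distance_matrix(Y),
                    sample(rep(1:2, 10)), n_perm = 49, seed = 1)$phi_pt
  })
  expect_lt(stats::median(phis), 0.05)
})

test_that("AMOVA validates groups and conserves sums of squares", {
  D2 <- squared_distance_matrix(matrix(sample(0:2, 40, TRUE), 8, 5))
  expect_error(amova_one_level(D2, rep("a", 8)), "2 groups")
  expect_error(amova_one_level(D2, c("a", rep("b", 7))), ">= 2 members")
  set.seed(51)
  for (i in 1:5) {
    n <- 10
    M <- matrix(runif(n * n, 0, 10), n, n)
    D <- M + t(M); diag(D) <- 0 # symmetric, zero-diagonal, non-Euclidean
    am <- amova_one_level(D, rep(1:2, each = 5), n_perm = 0)
    expect_equal(am$SS_among + am$SS_within, am$SS_total, tolerance = 1e-9)
    expect_equal(am$pct_among + am$pct_within, 100)
    expect_gte(am$Va, 0)
  }
})

test_that("permutation p-values are bounded, deterministic, and seeded", {
  sim <- simulate_panel(sim_config(n_per_group = c(12, 12), n_loci = 120,
                                   fst = 0.2, seed = 61))
  D2 <- squared_distance_matrix(impute_naive(sim$gm)$calls)
  a1 <- amova_one_level(D2, sim$truth$labels, n_perm = 99, seed = 7)
  a2 <- amova_one_level(D2, sim$truth$labels, n_perm = 99, seed = 7)
  expect_identical(a1$p_value, a2$p_value)
  expect_gte(a1$p_value, 1 / 100)
  expect_lte(a1$p_value, 1)
  expect_equal(a1$p_value, 0.01) # strong structure: no permutation beats it
})

test_that("Nm follows the haploid migrant formula with explicit edge cases", {
  # published reference: Nm = 86.428 from unrounded variance components;
  # the table-rounded inputs propagate ~0.003 of uncertainty into Nm
  expect_equal(nm_haploid(14.292, 2470.518), 86.428, tolerance = 6e-5)
  expect_equal(nm_haploid(14.292, 2470.518),
               2470.518 / (2 * 14.292), tolerance = 1e-12)
  expect_equal(nm_haploid(1, 1), 0.5)
  expect_equal(nm_haploid(1, 0), 0)
  expect_true(is.infinite(nm_haploid(0, 5)))
  expect_error(nm_haploid(-1, 5))
})

test_that("rising simulated FST raises PhiPT and lowers Nm", {
  med_phi <- med_nm <- numeric(0)
  for (fst in c(0.02, 0.08, 0.2)) {
    phis <- nms <- numeric(5)
    for (s in 1:5) {
      sim <- simulate_panel(sim_config(n_per_group = c(15, 15),
                                       n_loci = 250, fst = fst,
                                       seed = 100 * s))
      am <- amova_one_level(squared_distance_matrix(sim$gm$calls),
                            sim$truth$labels, n_perm = 0)
      phis[s] <- am$phi_pt
      nms[s] <- am$Nm
    }
    med_phi <- c(med_phi, stats::median(phis))
    med_nm <- c(med_nm, stats::median(nms))
  }
  expect_true(all(diff(med_phi) > 0))
  expect_true(all(diff(med_nm) < 0))
})
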