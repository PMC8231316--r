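# direct evaluation of the admixture log-likelihood, independent of the
# EM internals
loglik_oracle <- function(X, Q, P) {
  f <- Q %*% P
  sum(X * log(f) + (2 - X) * log(1 - f))
}

test_that("K = 1 admixture fit equals the pooled binomial closed form", {
  gm <- random_panel(n = 12, L = 30, seed = 2, het = 0.05)
  X <- gm$calls
  p_obs <- colMeans(X) / 2
  X <- X[, p_obs > 0 & p_obs < 1] # closed form needs polymorphic loci
  fit <- admixture_em(X, K = 1, seed = 1)
  expect_equal(unname(fit$Q), matrix(1, 12, 1))
  p <- colMeans(X) / 2
  ll <- sum(X * log(p)[col(X)] + (2 - X) * log(1 - p)[col(X)])
  expect_equal(fit$logL, ll, tolerance = 1e-8)
})

test_that("perfectly differentiated populations are recovered with certainty", {
  X <- rbind(matrix(0, 10, 40), matrix(2, 10, 40))
  fit <- admixture_em(X, K = 2, seed = 3)
  hard <- assign_subgroups(fit)
  expect_true(all(hard$admixture >= 0.99))
  expect_equal(length(unique(hard$group[1:10])), 1)
  expect_true(hard$group[1] != hard$group[11])
})

test_that("log-likelihood is invariant under label permutation and monotone over EM", {
  gm <- random_panel(n = 20, L = 60, fst = 0.15, seed = 4)
  fit <- admixture_em(gm$calls, K = 3, seed = 5)
  perm <- c(3, 1, 2)
  ll_perm <- loglik_oracle(gm$calls, fit$Q[, perm], fit$P[perm, ])
  expect_equal(ll_perm, fit$logL, tolerance = 1e-9)
  expect_true(all(diff(fit$logL_trace) > -1e-6 * (1 + abs(fit$logL))))
  expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-9))
  expect_true(all(fit$P >= 1e-6 & fit$P <= 1 - 1e-6))
})

test_that("k scan is deterministic, sized correctly, and validates K range", {
  gm <- random_panel(n = 14, L = 30, fst = 0.2, seed = 6)
  scan1 <- suppressWarnings(
    run_k_scan(gm$calls, 1, 6, replicates = 10, base_seed = 42,
               tol = 1e-4, max_iter = 200))
  expect_equal(nrow(scan1), 60) # ten runs per K, K = 1..6
  scan2 <- suppressWarnings(
    run_k_scan(gm$calls, 1, 6, replicates = 10, base_seed = 42,
               tol = 1e-4, max_iter = 200))
  expect_identical(scan1$logL, scan2$logL)
  expect_equal(unique(scan1$seed), 42:51)
  expect_error(run_k_scan(gm$calls, 3, 2, replicates = 2, base_seed = 1),
               "k_max")
})

test_that("Evanno delta-K reproduces the hand-worked table", {
  means <- c(-1000, -900, -880, -875)
  sds <- c(5, 4, 4, 5)
  # two replicates per K with exact mean m and sample sd s: m +/- s/sqrt(2)
  scan <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(K = i, logL = means[i] + c(1, -1) * sds[i] / sqrt(2))
  }))
  ev <- evanno_delta_k(scan)
  expect_equal(ev$L1, c(NA, 100, 20, 5))
  expect_equal(ev$L2_abs, c(NA, 80, 15, NA))
  expect_equal(ev$delta_K, c(NA, 20, 3.75, NA))
  expect_equal(attr(ev, "best_K"), 2)
})

test_that("Evanno edge cases: flat likelihoods, zero sd, short scans", {
  flat <- expand.grid(K = 1:4, rep = 1:2)
  flat$logL <- -500 + c(0.1, -0.1)[flat$rep]
  expect_warning(ev <- evanno_delta_k(flat), "tie")
  expect_true(all(ev$delta_K[!is.na(ev$delta_K)] == 0))

  zero_sd <- data.frame(K = rep(1:3, each = 2),
                        logL = c(-10, -12, -5, -5, -4, -4.5))
  expect_warning(expect_warning(ev2 <- evanno_delta_k(zero_sd),
                                "sd_L = 0"),
                 "undefined for every interior K")
  expect_true(is.na(attr(ev2, "best_K")))

  expect_error(evanno_delta_k(data.frame(K = rep(1:2, 2), logL = rnorm(4))),
               "3 K values")
  expect_error(evanno_delta_k(data.frame(K = 1:3, logL = rnorm(3))),
               "replicates")
})

test_that("subgroup assignment takes the admixture argmax with low-index ties", {
  Q <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8))
  out <- assign_subgroups(Q)
  expect_equal(out$group, c(1, 1, 2))
  expect_equal(out$admixture, c(0.9, 0.5, 0.8))
})

test_that("structure recovery on a simulated two-population panel", {
  sim <- simulate_panel(sim_config(n_per_group = c(25, 25), n_loci = 500,
                                   fst = 0.15, seed = 8))
  fit <- admixture_em(sim$gm$calls, K = 2, seed = 1)
  hard <- assign_subgroups(fit)
  agree <- max(mean(hard$group == sim$truth$labels),
               mean(hard$group != sim$truth$labels)) # up to label swap
  expect_gte(agree, 0.95)
})

test_that("PCA centres, orders components and fixes signs deterministically", {
  X <- rbind(c(0, 2, 0, 2), c(2, 0, 2, 0))
  pc <- snp_pca(X)
  expect_equal(pc$scores[1, 1], -pc$scores[2, 1]) # mirrored pair
  # adding a constant column changes nothing
  pc2 <- snp_pca(cbind(X, 1))
  expect_equal(pc$scores, pc2$scores)
  gm <- random_panel(n = 10, L = 15, seed = 9)
  p3 <- snp_pca(gm$calls)
  expect_true(all(diff(p3$explained) <= 1e-12))
  expect_lte(sum(p3$explained), 1 + 1e-12)
  cross <- crossprod(p3$scores)
  expect_true(all(abs(cross[upper.tri(cross)]) < 1e-8))
  expect_error(snp_pca(matrix(1, 4, 3)), "zero-variance")
})

test_that("PCA agrees with a direct covariance eigendecomposition", {
  set.seed(13)
  for (i in 1:3) {
    X <- matrix(sample(0:2, 80, replace = TRUE), 8, 10)
    pc <- snp_pca(X)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    eig <- eigen(cov(X), symmetric = TRUE)
    scores <- Xc %*% eig$vectors
    k <- sum(eig$values > 1e-10)
    expect_equal(abs(unname(pc$scores[, 1:k])), abs(scores[, 1:k]),
                 tolerance = 1e-10)
    expect_equal(pc$sdev[1:k]^2, eig$values[1:k] * 1, tolerance = 1e-10)
  }
})

test_that("complete-linkage dendrogram merges by maximum pairwise distance", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 1
  d["A", "C"] <- d["C", "A"] <- 5
  d["B", "C"] <- d["C", "B"] <- 6
  tr <- popdiv:::tree_from_dist(as.dist(d))
  expect_equal(tr$hclust$height, c(1, 6)) # A,B first; then max(5,6) = 6
  first <- sort(tr$hclust$labels[-tr$hclust$merge[1, ]])
  expect_equal(first, c("A", "B"))
  # Newick output round-trips with the same leaf set
  leaves <- ape::read.tree(text = tr$newick)$tip.label
  expect_setequal(leaves, c("A", "B", "C"))
})

test_that("dendrograms from PC space are ultrametric with tied duplicates", {
  gm <- random_panel(n = 8, L = 20, seed = 10)
  X <- rbind(gm$calls, dup = gm$calls[1, ]) # duplicated sample
  pc <- snp_pca(X)
  dnd <- pc_dendrogram(pc, n_components = 3)
  expect_equal(min(dnd$hclust$height), 0) # duplicate merges at height 0
  expect_true(all(diff(dnd$hclust$height) >= -1e-12))
  expect_setequal(ape::read.tree(text = dnd$newick)$tip.label,
                  rownames(X))
  expect_error(pc_dendrogram(pc, n_components = 50), "available")
})
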