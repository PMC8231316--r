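# Maximum-likelihood admixture model. Each line i draws allele copies at
# locus l from K latent subpopulations with mixing proportions q_i (rows of
# Q) and subpopulation minor-allele frequencies p_k (rows of P); the dosage
# g_il is Binomial(2, sum_k q_ik p_kl). The log-likelihood
#   logL = sum_il [ g_il log f_il + (2 - g_il) log(1 - f_il) ],
# f = Q P, is maximized by EM (the classic frappe/ADMIXTURE block updates),
# which is monotone in logL. Replicate random restarts provide the
# likelihood spread that the Evanno delta-K statistic needs.

ADMIX_EPS <- 1e-6 # box constraint on allele frequencies, avoids log(0)

admix_loglik <- function(X, Q, P) {
  f <- Q %*% P
  f <- pmin(pmax(f, ADMIX_EPS / 2), 1 - ADMIX_EPS / 2)
  sum(X * log(f) + (2 - X) * log1p(-f))
}

#' Fit the admixture model for one K by EM
#'
#' @param X complete numeric matrix of minor-allele dosages (samples x loci,
#'   values 0/1/2, no missing values) or a complete [genotype_matrix()].
#' @param K number of latent subpopulations, `1 <= K <=` number of samples.
#' @param seed integer seed for the random restart (initial Q and P).
#' @param max_iter maximum EM iterations (default 2000).
#' @param tol relative convergence tolerance: iteration stops when the
#'   per-iteration log-likelihood increase falls below
#'   `tol * (1 + |logL|)` (default 1e-6).
#' @return object of class `admixture_fit`: `K`, `Q` (samples x K, rows sum
#'   to 1), `P` (K x loci minor-allele frequencies in
#'   `[1e-6, 1 - 1e-6]`), `logL`, `logL_trace`, `iterations`, `converged`,
#'   `seed`.
#' @examples
#' X <- rbind(matrix(0, 4, 20), matrix(2, 4, 20))
#' fit <- admixture_em(X, K = 2, seed = 1)
#' round(fit$Q, 2)
#' @export
admixture_em <- function(X, K, seed, max_iter = 2000, tol = 1e-6) {
  if (is_genotype_matrix(X)) X <- X$calls
  X <- as.matrix(X)
  if (anyNA(X)) stop("admixture_em needs a complete matrix; impute first")
  n <- nrow(X); L <- ncol(X)
  if (K < 1 || K > n) stop("K must lie in [1, n_samples]")
  if (K == 1) {
    p <- pmin(pmax(colMeans(X) / 2, ADMIX_EPS), 1 - ADMIX_EPS)
    P <- matrix(p, 1, L)
    Q <- matrix(1, n, 1)
    ll <- admix_loglik(X, Q, P)
    return(structure(list(K = 1L, Q = Q, P = P, logL = ll,
                          logL_trace = ll, iterations = 0L,
                          converged = TRUE, seed = seed),
                     class = "admixture_fit"))
  }
  set.seed(seed)
  Q <- matrix(stats::rgamma(n * K, shape = 1), n, K)
  Q <- Q / rowSums(Q)
  pooled <- colMeans(X) / 2
  P <- matrix(rep(pooled, each = K), K, L) +
    matrix(runif(K * L, -0.1, 0.1), K, L)
  P <- pmin(pmax(P, ADMIX_EPS), 1 - ADMIX_EPS)

  trace <- numeric(max_iter + 1)
  ll_old <- admix_loglik(X, Q, P)
  trace[1] <- ll_old
  converged <- FALSE
  iter <- 0L
  X2 <- 2 - X
  while (iter < max_iter) {
    iter <- iter + 1L
    f1 <- Q %*% P
    f1 <- pmin(pmax(f1, ADMIX_EPS / 2), 1 - ADMIX_EPS / 2)
    Gl <- X / f1         # expected-count weights, minor allele
    G0 <- X2 / (1 - f1)  # and major allele
    # expected allele-copy totals, written as matrix products:
    #   sum_l A_kl over loci = q_ik * [Gl P']_ik,  sum_i A_kl = p_kl [Gl' Q]_lk
    U <- Gl %*% t(P)
    V <- G0 %*% (1 - t(P))
    CA <- t(crossprod(Gl, Q)) * P          # K x L minor-allele copies
    CB <- t(crossprod(G0, Q)) * (1 - P)    # K x L major-allele copies
    Q <- Q * (U + V) / (2 * L)
    Q <- Q / rowSums(Q) # guard against fp drift off the simplex
    P <- pmin(pmax(CA / (CA + CB), ADMIX_EPS), 1 - ADMIX_EPS)
    ll <- admix_loglik(X, Q, P)
    trace[iter + 1] <- ll
    if (ll < ll_old - 1e-6 * (1 + abs(ll_old))) {
      warning("EM log-likelihood decreased at iteration ", iter)
    }
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) { # relative tolerance
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!is.finite(ll_old)) stop("admixture EM produced a non-finite logL")
  rownames(Q) <- rownames(X)
  structure(list(K = as.integer(K), Q = Q, P = P, logL = ll_old,
                 logL_trace = trace[seq_len(iter + 1)],
                 iterations = iter, converged = converged, seed = seed),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: K =", x$K, " logL =", format(x$logL, digits = 8),
      if (x$converged) "(converged" else "(NOT converged",
      "after", x$iterations, "iterations)\n")
  sizes <- table(factor(max.col(x$Q, ties.method = "first"),
                        levels = seq_len(x$K)))
  cat("  hard-assignment sizes:", paste(sizes, collapse = " / "), "\n")
  invisible(x)
}

#' @export
logLik.admixture_fit <- function(object, ...) {
  structure(object$logL, df = object$K * ncol(object$P) +
              nrow(object$Q) * (object$K - 1), class = "logLik")
}

#' Replicate admixture fits over a range of K
#'
#' Runs [admixture_em()] for each K in `k_min:k_max` with `replicates`
#' random restarts per K (replicate r uses seed `base_seed + r - 1`), the
#' input the Evanno delta-K statistic expects. Deterministic given
#' `base_seed`.
#'
#' @inheritParams admixture_em
#' @param k_min,k_max inclusive K range.
#' @param replicates restarts per K (default 10).
#' @param base_seed integer; replicate seeds are `base_seed + 0:(replicates-1)`.
#' @param ... passed to [admixture_em()] (e.g. `max_iter`, `tol`).
#' @return data.frame (class `k_scan`) with columns `K`, `replicate`,
#'   `seed`, `logL`, `iterations`, `converged`, and the fitted objects in
#'   `attr(, "fits")` (named `"K<k>_r<r>"`).
#' @export
run_k_scan <- function(X, k_min = 1, k_max, replicates = 10, base_seed,
                       ...) {
  if (k_max < k_min) stop("k_max must be >= k_min")
  if (replicates < 1) stop("replicates must be >= 1")
  grid <- expand.grid(replicate = seq_len(replicates), K = k_min:k_max)
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- admixture_em(X, K = grid$K[i],
                              seed = base_seed + grid$replicate[i] - 1, ...)
  }
  unconv <- !vapply(fits, `[[`, logical(1), "converged")
  if (any(unconv)) {
    warning(sum(unconv), " run(s) hit max_iter without converging; ",
            "included in the scan")
  }
  out <- data.frame(K = grid$K, replicate = grid$replicate,
                    seed = base_seed + grid$replicate - 1,
                    logL = vapply(fits, `[[`, numeric(1), "logL"),
                    iterations = vapply(fits, `[[`, integer(1), "iterations"),
                    converged = !unconv)
  attr(out, "fits") <- setNames(fits, sprintf("K%d_r%d", grid$K,
                                              grid$replicate))
  class(out) <- c("k_scan", "data.frame")
  out
}

#' Evanno delta-K model selection
#'
#' From replicate log-likelihoods per K computes the Evanno table: mean and
#' sd of L(K), first differences `L'(K) = mean_L(K) - mean_L(K-1)`, second
#' differences `|L''(K)| = |L'(K+1) - L'(K)|`, and
#' `deltaK = |L''(K)| / sd_L(K)`. deltaK is defined only for interior K;
#' `best_K` is the interior K maximizing deltaK (K with zero replicate sd
#' are excluded with a warning; exact ties resolve to the smallest K with a
#' warning).
#'
#' @param scan a [run_k_scan()] result, or any data.frame with columns `K`
#'   and `logL` holding at least 2 replicates per K over at least 3
#'   consecutive K.
#' @return object of class `evanno_table`: data.frame with `K`, `n_rep`,
#'   `mean_L`, `sd_L`, `L1` (L'), `L2_abs` (|L''|), `delta_K`, plus
#'   attribute `best_K`.
#' @export
evanno_delta_k <- function(scan) {
  stopifnot(all(c("K", "logL") %in% names(scan)))
  ks <- sort(unique(scan$K))
  if (length(ks) < 3) stop("need at least 3 K values for delta-K")
  if (any(diff(ks) != 1)) stop("K values must be consecutive")
  n_rep <- vapply(ks, function(k) sum(scan$K == k), integer(1))
  if (any(n_rep < 2)) stop("need >= 2 replicates per K for sd_L")
  mean_L <- vapply(ks, function(k) mean(scan$logL[scan$K == k]), numeric(1))
  sd_L <- vapply(ks, function(k) sd(scan$logL[scan$K == k]), numeric(1))
  m <- length(ks)
  L1 <- c(NA, diff(mean_L))                       # L'(K), defined for K >= kmin+1
  L2_abs <- c(NA, abs(diff(mean_L, differences = 2)), NA) # |L''|, interior K
  delta_K <- L2_abs / sd_L
  zero_sd <- !is.na(L2_abs) & sd_L == 0
  if (any(zero_sd)) {
    warning("sd_L = 0 at K = ", paste(ks[zero_sd], collapse = ", "),
            "; delta-K undefined there and excluded from best-K")
    delta_K[zero_sd] <- NA_real_
  }
  tab <- data.frame(K = ks, n_rep = n_rep, mean_L = mean_L, sd_L = sd_L,
                    L1 = L1, L2_abs = L2_abs, delta_K = delta_K)
  defined <- which(!is.na(delta_K))
  if (length(defined) == 0) {
    warning("delta-K undefined for every interior K; best_K is NA")
    best <- NA_integer_
  } else {
    top <- delta_K[defined] == max(delta_K[defined])
    if (sum(top) > 1) {
      warning("delta-K tie between K = ",
              paste(ks[defined[top]], collapse = ", "),
              "; reporting the smallest")
    }
    best <- ks[defined[which(top)[1]]]
  }
  attr(tab, "best_K") <- best
  class(tab) <- c("evanno_table", "data.frame")
  tab
}

#' @export
print.evanno_table <- function(x, ...) {
  cat("Evanno delta-K table (best K =", attr(x, "best_K"), ")\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Hard subgroup assignment from admixture proportions
#'
#' Assigns each line to the subpopulation with the largest admixture
#' proportion (ties go to the lower index), keeping the winning proportion
#' as the line's admixture coefficient.
#'
#' @param fit an [admixture_em()] result (or any object with a `Q` matrix).
#' @return data.frame with `sample`, `group` (integer), `admixture`
#'   (max Q value).
#' @export
assign_subgroups <- function(fit) {
  Q <- if (is.list(fit)) fit$Q else fit
  stopifnot(is.matrix(Q))
  g <- max.col(Q, ties.method = "first")
  data.frame(sample = rownames(Q) %||% seq_len(nrow(Q)),
             group = g, admixture = Q[cbind(seq_len(nrow(Q)), g)],
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
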