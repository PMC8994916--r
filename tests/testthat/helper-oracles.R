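# Independent oracles used across the suite.  Everything here is written
# against the model definitions directly (double loops, subset enumeration,
# generic optimizers) and never calls the package's fast paths it checks.

# Brute-force unbinned log-likelihood: double loop over all within-chromosome
# unordered pairs, edge terms log(1 - e^{-s}), non-edge terms -s.
bf_loglik <- function(Z, counts, chroms, edge_pairs, clamp = 1e-10) {
  n <- nrow(counts)
  is_edge <- matrix(FALSE, n, n)
  if (nrow(edge_pairs))
    is_edge[edge_pairs] <- is_edge[edge_pairs[, 2:1, drop = FALSE]] <- TRUE
  ll <- 0
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    if (chroms[u] != chroms[v]) next
    s <- drop(counts[u, ] %*% Z %*% counts[v, ])
    ll <- ll + if (is_edge[u, v]) log(-expm1(-max(s, clamp))) else -s
  }
  ll
}

bf_objective <- function(Z, counts, chroms, edge_pairs, lambda1, lambda2,
                         clamp = 1e-10) {
  -bf_loglik(Z, counts, chroms, edge_pairs, clamp) +
    lambda1 * sum(svd(Z)$d) + lambda2 * sum(abs(Z))
}

# Brute-force binned Poisson log-likelihood: double loop, k log(lam) - lam -
# log(k!) with lam = C_u' X C_v (zero-count pairs contribute -lam).
bf_loglik_binned <- function(X, counts, chroms, edge_pairs, k, clamp = 1e-10) {
  n <- nrow(counts)
  kmat <- matrix(0, n, n)
  if (nrow(edge_pairs)) {
    kmat[edge_pairs] <- k
    kmat[edge_pairs[, 2:1, drop = FALSE]] <- k
  }
  ll <- 0
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    if (chroms[u] != chroms[v]) next
    lam <- drop(counts[u, ] %*% X %*% counts[v, ])
    kk <- kmat[u, v]
    ll <- ll + if (kk > 0) kk * log(max(lam, clamp)) - lam - lfactorial(kk)
      else -lam
  }
  ll
}

# Exact Poisson-binomial pmf by explicit enumeration over success subsets.
pb_enumerate <- function(probs, k) {
  T <- length(probs)
  if (k > T) return(0)
  if (k == 0) return(prod(1 - probs))
  sets <- combn(T, k)
  total <- 0
  for (j in seq_len(ncol(sets))) {
    on <- sets[, j]
    total <- total + prod(probs[on]) * prod(1 - probs[-on])
  }
  total
}

# Generic convex-solver oracle for the penalized objective on tiny
# instances: parametrize the upper triangle, smooth the two nonsmooth norms
# with a tiny epsilon, and polish multistart L-BFGS-B with Nelder-Mead.
oracle_min_objective <- function(counts, chroms, edge_pairs, lambda1,
                                 lambda2, eps = 1e-12) {
  M <- ncol(counts)
  ut <- which(upper.tri(diag(M), diag = TRUE))
  to_Z <- function(theta) {
    Z <- matrix(0, M, M)
    Z[ut] <- theta
    Z[lower.tri(Z)] <- t(Z)[lower.tri(Z)]
    Z
  }
  smooth_obj <- function(theta) {
    Z <- to_Z(pmax(theta, 0))
    -bf_loglik(Z, counts, chroms, edge_pairs) +
      lambda1 * sum(sqrt(svd(Z)$d^2 + eps)) +
      lambda2 * sum(sqrt(Z^2 + eps))
  }
  exact_obj <- function(theta)
    bf_objective(to_Z(pmax(theta, 0)), counts, chroms, edge_pairs,
                 lambda1, lambda2)
  starts <- list(rep(0.01, length(ut)),
                 rep(0.5, length(ut)),
                 seq(0.05, 0.6, length.out = length(ut)))
  best <- Inf
  for (th0 in starts) {
    r1 <- tryCatch(
      optim(th0, smooth_obj, method = "L-BFGS-B",
            lower = 0, upper = 30,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) list(par = th0))
    r2 <- optim(r1$par, exact_obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    r3 <- optim(r2$par, exact_obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, exact_obj(r3$par))
  }
  best
}

# Random tiny unbinned instance on one pseudo-chromosome.
random_tiny_instance <- function(n_sites = 8, n_marks = 3,
                                 density = 0.5, edge_prob = 0.3) {
  counts <- matrix(rbinom(n_sites * n_marks, 1, density), n_sites, n_marks)
  # guarantee at least one active mark per instance
  if (all(counts == 0)) counts[1, 1] <- 1L
  pairs <- which(upper.tri(diag(n_sites)), arr.ind = TRUE)
  sel <- runif(nrow(pairs)) < edge_prob
  edges <- pairs[sel, , drop = FALSE]
  chrom <- rep("chr1", n_sites)
  pos <- seq_len(n_sites) * 4000L
  idx <- hicdecomp::site_index(chrom, pos)
  asg <- hicdecomp::mark_assignment(counts, paste0("m", seq_len(n_marks)),
                                    idx)
  ctc <- if (nrow(edges))
    hicdecomp::contact_records(chrom[edges[, 1]], pos[edges[, 1]],
                               chrom[edges[, 2]], pos[edges[, 2]])
  else hicdecomp::contact_records(character(), integer(), character(),
                                  integer())
  list(counts = counts, chroms = chrom, edges = edges,
       assignment = asg, contacts = ctc, pos = pos)
}
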