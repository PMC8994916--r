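#' Objective specification
#'
#' Regularization weights and numerical guards for the penalized negative
#' log-likelihood: lambda1 weights the nuclear norm (low rank), lambda2 the
#' entrywise L1 norm (sparsity), and clamp_eps floors the per-edge linear
#' predictor s_uv inside log(1 - exp(-s)) so edges the model cannot explain
#' (mark-free endpoints) do not produce -Inf.
#'
#' @param lambda1 nonnegative nuclear-norm weight.
#' @param lambda2 nonnegative L1 weight.
#' @param clamp_eps small positive floor for the edge linear predictor.
#' @param pair_scope \code{"within"} restricts the non-edge background to
#'   within-chromosome pairs (the default, matching per-chromosome fitting);
#'   \code{"all"} uses every unordered site pair.
#' @return a list of class \code{"objective_spec"}.
#' @export
objective_spec <- function(lambda1 = 0, lambda2 = 0, clamp_eps = 1e-10,
                           pair_scope = c("within", "all")) {
  if (lambda1 < 0 || lambda2 < 0) stop("lambda weights must be nonnegative")
  if (clamp_eps <= 0) stop("clamp_eps must be positive")
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 clamp_eps = clamp_eps,
                 pair_scope = match.arg(pair_scope)),
            class = "objective_spec")
}

#' Edge probability under the mark-pair model
#'
#' The probability that two sites with mark vectors \eqn{C_u}, \eqn{C_v}
#' interact: each co-occurring mark pair (m, n) fires independently with
#' probability \eqn{x_{mn}}, so
#' \deqn{P = 1 - \prod_{m,n} (1 - x_{mn})^{c^u_m c^v_n} = 1 - e^{-C_u^T Z C_v}}
#' with \eqn{z = -\log(1 - x)}.
#'
#' @param C_u,C_v nonnegative mark count vectors over the same catalog.
#' @param X mark-pair probability matrix (matrix or
#'   \code{\link{mark_pair_matrix}}) with entries in [0, 1].
#' @return probability in [0, 1].
#' @export
edge_probability <- function(C_u, C_v, X) {
  if (inherits(X, "mark_pair_matrix")) X <- X$X
  w <- outer(as.numeric(C_u), as.numeric(C_v))
  active <- w > 0
  if (any(X[active] >= 1)) return(1)  # limit case: a certain mark pair
  s <- sum(w[active] * -log1p(-X[active]))
  -expm1(-s)
}

# ---- internal likelihood engine --------------------------------------------
#
# Precomputes everything the unbinned log-likelihood and its gradient need:
# per-chromosome aggregate terms (so the non-edge sum costs O(|E| + |R|)
# instead of O(|R|^2)), edge endpoint rows, and optional excluded pairs
# (held-out pairs that belong to neither the edge set nor the non-edge
# background, used by cross-validation).
.make_ll_context <- function(assignment, contacts, exclude = NULL,
                             pair_scope = "within") {
  A <- assignment$counts
  storage.mode(A) <- "double"
  dimnames(A) <- NULL
  idx <- assignment$index
  key <- .site_key(idx$chrom, idx$pos)
  M <- ncol(A)

  map_pairs <- function(df) {
    if (is.null(df) || nrow(df) == 0L)
      return(list(pairs = matrix(integer(), 0L, 2L), count = integer()))
    i <- match(.site_key(df$chrom1, df$pos1), key)
    j <- match(.site_key(df$chrom2, df$pos2), key)
    count <- if ("count" %in% names(df)) df$count else rep(1L, nrow(df))
    keep <- !(is.na(i) | is.na(j))
    if (!all(keep))
      warning(sprintf("%d contact pair(s) with endpoints outside the site index; dropped",
                      sum(!keep)))
    if (pair_scope == "within") {
      same <- keep
      same[keep] <- idx$chrom[i[keep]] == idx$chrom[j[keep]]
      if (sum(keep) > sum(same))
        warning(sprintf("%d inter-chromosomal pair(s) outside pair scope; dropped",
                        sum(keep) - sum(same)))
      keep <- same
    }
    i <- i[keep]; j <- j[keep]; count <- count[keep]
    pairs <- cbind(i, j)
    dup <- duplicated(pairs)
    if (any(dup)) {
      kk <- paste(i, j)
      agg <- rowsum(count, kk, reorder = FALSE)
      pairs <- pairs[!dup, , drop = FALSE]
      count <- as.integer(agg[match(kk[!dup], rownames(agg)), 1L])
    }
    list(pairs = pairs, count = count)
  }

  em <- map_pairs(contacts)
  xm <- map_pairs(exclude)
  edges <- em$pairs
  excl <- xm$pairs
  counts_e <- em$count
  # held-out pairs leave the edge set as well as the non-edge background
  if (nrow(excl) && nrow(edges)) {
    ek <- paste(edges[, 1L], edges[, 2L])
    xk <- paste(excl[, 1L], excl[, 2L])
    keep <- !(ek %in% xk)
    edges <- edges[keep, , drop = FALSE]
    counts_e <- counts_e[keep]
  }

  # aggregate terms: within each scope group g,
  #   sum_{u<v in g} s_uv = (t_g' Z t_g - sum_u C_u' Z C_u) / 2
  groups <- if (pair_scope == "within") split(seq_len(nrow(A)), idx$chrom)
            else list(seq_len(nrow(A)))
  Tmat <- vapply(groups, function(g) colSums(A[g, , drop = FALSE]),
                 numeric(M))
  Tmat <- matrix(Tmat, nrow = M)  # one column of colSums per group
  AtA <- matrix(0, M, M)
  for (g in groups) AtA <- AtA + crossprod(A[g, , drop = FALSE])
  # gradient of the all-pairs sum: (sum_g t_g t_g' - A'A) / 2
  G_all <- (tcrossprod(Tmat) - AtA) / 2

  # excluded pairs only enter through linear terms, so they reduce to one
  # constant matrix: sum over excluded pairs of C_u C_v^T
  Axu <- A[excl[, 1L], , drop = FALSE]
  Axv <- A[excl[, 2L], , drop = FALSE]
  Ex <- if (nrow(excl)) crossprod(Axu, Axv) else matrix(0, M, M)

  # binary (unbinned) data: compress edges to distinct mark-pattern pairs
  # with multiplicities -- the edge term cost then scales with the number of
  # distinct patterns, not |E|
  Eu <- A[edges[, 1L], , drop = FALSE]
  Ev <- A[edges[, 2L], , drop = FALSE]
  emul <- rep(1, nrow(edges))
  if (nrow(edges) && all(A %in% c(0, 1))) {
    rk <- do.call(paste, c(as.data.frame(A), sep = ","))
    pid <- match(rk, unique(rk))
    pk <- paste(pid[edges[, 1L]], pid[edges[, 2L]])
    first <- !duplicated(pk)
    emul <- as.vector(table(pk)[pk[first]])
    Eu <- Eu[first, , drop = FALSE]
    Ev <- Ev[first, , drop = FALSE]
  }

  list(A = A, M = M, n = nrow(A),
       edges = edges, excl = excl, counts = counts_e,
       Au = A[edges[, 1L], , drop = FALSE],
       Av = A[edges[, 2L], , drop = FALSE],
       Eu = Eu, Ev = Ev, emul = emul, Ex = Ex,
       Tmat = Tmat, AtA = AtA, G_all = G_all)
}

.pair_s <- function(Bu, Bv, Z) {
  if (nrow(Bu) == 0L) return(numeric(0))
  rowSums((Bu %*% Z) * Bv)
}

# sum over all in-scope unordered pairs of s_uv
.s_all <- function(ctx, Z) {
  (sum(ctx$Tmat * (Z %*% ctx$Tmat)) - sum(ctx$AtA * Z)) / 2
}

# negative log-likelihood (unbinned, Bernoulli edges) and its gradient;
# edge terms run over distinct pattern pairs weighted by multiplicity
.nll_unbinned <- function(ctx, Z, clamp_eps = 1e-10) {
  s_e <- pmax(.pair_s(ctx$Eu, ctx$Ev, Z), clamp_eps)
  sum(ctx$emul * (-log(-expm1(-s_e)) - s_e)) +
    .s_all(ctx, Z) - sum(ctx$Ex * Z)
}

.nll_grad_unbinned <- function(ctx, Z, clamp_eps = 1e-10) {
  G <- ctx$G_all - (ctx$Ex + t(ctx$Ex)) / 2
  if (nrow(ctx$Eu)) {
    s_e <- pmax(.pair_s(ctx$Eu, ctx$Ev, Z), clamp_eps)
    w <- ctx$emul * (-1 / (-expm1(-s_e)))  # d/ds [-log(1-e^{-s}) - s]
    Ge <- crossprod(ctx$Eu * w, ctx$Ev)
    G <- G + (Ge + t(Ge)) / 2
  }
  G
}

#' Unbinned log-likelihood
#'
#' The Bernoulli log-likelihood of an unbinned contact graph under the
#' transformed parameterization Z:
#' \deqn{\sum_{(u,v) \in E} \log(1 - e^{-s_{uv}}) - \sum_{(u,v) \notin E} s_{uv},
#'   \quad s_{uv} = C_u^T Z C_v.}
#' The non-edge sum is computed through the aggregate identity
#' \eqn{\sum_{u<v} s_{uv} = (t^T Z t - \sum_u C_u^T Z C_u)/2} with
#' \eqn{t = \sum_u C_u}, so the cost is linear in |E| and |R|.  Edges with
#' \eqn{s_{uv} < } \code{clamp_eps} (inexplicable edges between mark-free
#' sites) are clamped with a warning.
#'
#' @param Z symmetric nonnegative matrix (transformed probabilities).
#' @param contacts unbinned \code{\link{contact_records}} (multi-counts
#'   collapse to presence/absence).
#' @param assignment unbinned \code{\link{mark_assignment}}.
#' @param spec an \code{\link{objective_spec}} (clamp and pair scope).
#' @param exclude optional \code{contact_records}-like pair set removed from
#'   both the edge set and the non-edge background (held-out pairs).
#' @return the log-likelihood (a scalar).
#' @export
log_likelihood_unbinned <- function(Z, contacts, assignment,
                                    spec = objective_spec(), exclude = NULL) {
  ctx <- .make_ll_context(assignment, contacts, exclude, spec$pair_scope)
  s_e <- .pair_s(ctx$Au, ctx$Av, Z)
  if (any(s_e < spec$clamp_eps))
    warning(sprintf("%d edge(s) with near-zero linear predictor clamped (model cannot explain them)",
                    sum(s_e < spec$clamp_eps)))
  -.nll_unbinned(ctx, Z, spec$clamp_eps)
}

#' Penalized objective
#'
#' The convex transformed objective: negative unbinned log-likelihood plus
#' \eqn{\lambda_1 \|Z\|_*} (nuclear norm, sum of singular values) plus
#' \eqn{\lambda_2 \|Z\|_1} (entrywise).
#'
#' @inheritParams log_likelihood_unbinned
#' @return the objective value (a scalar).
#' @export
objective <- function(Z, contacts, assignment, spec = objective_spec(),
                      exclude = NULL) {
  nll <- -suppressWarnings(
    log_likelihood_unbinned(Z, contacts, assignment, spec, exclude))
  nll + spec$lambda1 * sum(svd(Z, nu = 0, nv = 0)$d) +
    spec$lambda2 * sum(abs(Z))
}

#' Poisson-binomial probability mass function
#'
#' Exact pmf of the number of successes among independent, non-identical
#' Bernoulli slot trials, by dynamic-programming convolution.  In the binned
#' model a bin pair (u, v) has \eqn{T = C_u^T 1 C_v} slots: the mark-pair
#' probability \eqn{x_{mn}} repeated \eqn{c^u_m c^v_n} times.
#'
#' @param slot_probs vector of slot success probabilities in [0, 1].
#' @param k nonnegative integer count (vectorized).
#' @return P(K = k); zero when k exceeds the number of slots.
#' @export
poisson_binomial_pmf <- function(slot_probs, k) {
  if (any(slot_probs < 0 | slot_probs > 1))
    stop("slot probabilities must lie in [0, 1]")
  if (any(k < 0 | k != round(k))) stop("k must be a nonnegative integer")
  pmf <- 1
  for (p in slot_probs)  # convolve one Bernoulli at a time
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  out <- numeric(length(k))
  inside <- k <= length(slot_probs)
  out[inside] <- pmf[k[inside] + 1L]
  out
}

#' Le Cam Poisson approximation
#'
#' Approximates the Poisson-binomial count distribution of a bin pair by a
#' Poisson with rate \eqn{\lambda_{uv} = C_u^T X C_v}; by Le Cam's theorem
#' the total-variation error is at most \eqn{\sum_i p_i^2} over slots.
#'
#' @param lambda_uv nonnegative Poisson rate.
#' @param k nonnegative integer count (vectorized).
#' @return P(K = k) under the Poisson approximation.
#' @export
lecam_poisson_pmf <- function(lambda_uv, k) {
  if (lambda_uv < 0) stop("lambda must be nonnegative")
  dpois(k, lambda_uv)
}

#' Binned log-likelihood (Le Cam Poisson path)
#'
#' Log-likelihood of binned counts under the Poisson approximation:
#' \deqn{\sum_{u<v} [k_{uv} \log \lambda_{uv} - \lambda_{uv} - \log k_{uv}!],
#'   \quad \lambda_{uv} = C_u^T X C_v,}
#' where zero-count pairs contribute only \eqn{-\lambda_{uv}}, accumulated
#' through the aggregate identity so the cost is linear in the number of
#' observed pairs.  Rates below \code{clamp_eps} on pairs with k > 0 are
#' clamped.
#'
#' @param X mark-pair probability matrix (matrix or
#'   \code{\link{mark_pair_matrix}}).
#' @param contacts binned \code{\link{contact_records}}.
#' @param assignment binned \code{\link{mark_assignment}}.
#' @param spec an \code{\link{objective_spec}}.
#' @return the log-likelihood (a scalar).
#' @export
log_likelihood_binned <- function(X, contacts, assignment,
                                  spec = objective_spec()) {
  if (inherits(X, "mark_pair_matrix")) X <- X$X
  ctx <- .make_ll_context(assignment, contacts, exclude = NULL,
                          pair_scope = spec$pair_scope)
  k <- ctx$counts
  lam <- pmax(.pair_s(ctx$Au, ctx$Av, X), spec$clamp_eps)
  sum(k * log(lam) - lfactorial(k)) - .s_all(ctx, X)
}
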