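#' Singular-value soft-thresholding (nuclear-norm proximal operator)
#'
#' Solves \eqn{\arg\min_Y \alpha \|Y\|_* + \tfrac12 \|Y - Q\|_F^2} in closed
#' form: with SVD \eqn{Q = U \mathrm{diag}(\sigma_i) V^T}, the solution is
#' \eqn{U \mathrm{diag}((\sigma_i - \alpha)_+) V^T}.
#'
#' @param Q square numeric matrix.
#' @param alpha nonnegative threshold.
#' @return the shrunk matrix.
#' @export
nuclear_prox <- function(Q, alpha) {
  if (alpha < 0) stop("alpha must be nonnegative")
  s <- svd(Q)
  d <- pmax(s$d - alpha, 0)
  s$u %*% (d * t(s$v))
}

#' Entrywise soft-thresholding (L1 proximal operator)
#'
#' Solves \eqn{\arg\min_Y \tau \|Y\|_1 + \tfrac12 \|Y - Q\|_F^2}: entries
#' with \eqn{|q| < \tau} go to zero, the rest shrink by \eqn{\tau} toward
#' zero.
#'
#' @param Q numeric matrix.
#' @param tau nonnegative threshold (lambda2 / rho inside ADMM).
#' @return the shrunk matrix.
#' @export
l1_prox <- function(Q, tau) {
  if (tau < 0) stop("tau must be nonnegative")
  sign(Q) * pmax(abs(Q) - tau, 0)
}

# ---- likelihood block (Z-update) -------------------------------------------

# Minimizes  nll(Z) + (rho/2)(||Z - Z1 + U1||^2 + ||Z - Z2 + U2||^2)  over
# symmetric Z >= 0 by projected gradient with Armijo backtracking.  The
# gradient is symmetrized, so iterates started symmetric stay symmetric.
.z_update_core <- function(ctx, Z, Z1, Z2, U1, U2, rho, clamp_eps = 1e-10,
                           max_inner = 200L, grad_tol = 1e-6,
                           max_halvings = 50L, armijo_c = 1e-4) {
  B1 <- Z1 - U1
  B2 <- Z2 - U2
  fval <- function(Z)
    .nll_unbinned(ctx, Z, clamp_eps) +
      (rho / 2) * (sum((Z - B1)^2) + sum((Z - B2)^2))
  gval <- function(Z)
    .nll_grad_unbinned(ctx, Z, clamp_eps) + rho * ((Z - B1) + (Z - B2))

  f <- fval(Z)
  step <- 1 / max(rho, 1)
  for (it in seq_len(max_inner)) {
    G <- gval(Z)
    G <- (G + t(G)) / 2
    ok <- FALSE
    for (h in seq_len(max_halvings)) {
      Znew <- pmax(Z - step * G, 0)
      D <- Znew - Z
      fnew <- fval(Znew)
      # sufficient decrease for projected gradient
      if (fnew <= f + armijo_c * sum(G * D) && is.finite(fnew)) {
        ok <- TRUE
        break
      }
      step <- step / 2
    }
    if (!ok) {
      warning("line search failed to find a decreasing step; returning current iterate")
      break
    }
    moved <- sqrt(sum((Znew - Z)^2))
    Z <- Znew
    f <- fnew
    if (moved / step < grad_tol * max(1, sqrt(sum(Z^2)))) break
    step <- step * 2  # gentle step growth between iterations
  }
  (Z + t(Z)) / 2
}

#' Likelihood-block update of the ADMM scheme
#'
#' One projected-gradient solve (with Armijo backtracking) of the Z
#' subproblem: negative unbinned log-likelihood plus the two quadratic
#' consensus terms, over symmetric Z >= 0.
#'
#' @param state an \code{admm_state} list with elements Z, Z1, Z2, U1, U2,
#'   rho (as produced internally by \code{\link{admm_fit}}).
#' @param contacts unbinned \code{\link{contact_records}}.
#' @param assignment unbinned \code{\link{mark_assignment}}.
#' @param spec an \code{\link{objective_spec}}.
#' @param exclude optional held-out pairs (see
#'   \code{\link{log_likelihood_unbinned}}).
#' @param max_inner,grad_tol inner iteration cap and relative-move stopping
#'   tolerance.
#' @return the updated Z matrix (symmetric, nonnegative).
#' @export
z_update <- function(state, contacts, assignment, spec = objective_spec(),
                     exclude = NULL, max_inner = 200L, grad_tol = 1e-6) {
  ctx <- .make_ll_context(assignment, contacts, exclude, spec$pair_scope)
  .z_update_core(ctx, state$Z, state$Z1, state$Z2, state$U1, state$U2,
                 state$rho, spec$clamp_eps, max_inner, grad_tol)
}

#' Fit the mark-pair matrix by ADMM (unbinned model)
#'
#' Alternates: (1) the likelihood block solved by projected gradient with
#' Armijo backtracking; (2) the nuclear-norm block, closed form by singular
#' value soft-thresholding at lambda1 / rho; (3) the L1 block, closed form
#' by entrywise soft-thresholding at lambda2 / rho; (4) scaled dual updates
#' U <- U + (Z - Z_aux).  Stops when
#' max(||Z - Z1||_F, ||Z - Z2||_F) / max(1, ||Z||_F) < tol.
#'
#' @param contacts unbinned \code{\link{contact_records}}.
#' @param assignment unbinned \code{\link{mark_assignment}}.
#' @param spec an \code{\link{objective_spec}} carrying lambda1, lambda2.
#' @param rho positive ADMM penalty parameter; the default
#'   \code{max(1, lambda1, lambda2)} keeps the proximal steps on the scale
#'   of the penalties, which keeps the consensus residuals converging even
#'   for strongly regularized fits.
#' @param tol relative consensus-residual tolerance.
#' @param max_iter outer iteration cap.
#' @param exclude optional held-out pairs excluded from both the edge set
#'   and the non-edge background.
#' @param init initial value for Z (default: small uniform 0.01).
#' @param max_inner inner projected-gradient iteration cap per Z-update.
#' @param trace_objective record the penalized objective each iteration
#'   (costs one SVD per iteration; on by default).
#' @return a list with the fitted \code{\link{mark_pair_matrix}} (\code{X}),
#'   the transformed matrix \code{Z}, and the final \code{admm_state}
#'   diagnostics (residuals, iterations, objective trace).
#' @export
admm_fit <- function(contacts, assignment, spec = objective_spec(),
                     rho = NULL, tol = 1e-4, max_iter = 500L, exclude = NULL,
                     init = NULL, max_inner = 200L, trace_objective = TRUE) {
  if (is.null(rho)) rho <- max(1, spec$lambda1, spec$lambda2)
  if (rho <= 0) stop("rho must be positive")
  M <- ncol(assignment$counts)
  ctx <- .make_ll_context(assignment, contacts, exclude, spec$pair_scope)
  Z <- if (is.null(init)) matrix(0.01, M, M) else (init + t(init)) / 2
  Z1 <- Z; Z2 <- Z
  U1 <- matrix(0, M, M); U2 <- matrix(0, M, M)
  obj_trace <- numeric(0)
  primal_trace <- dual_trace <- numeric(0)
  pen <- function(Z) spec$lambda1 * sum(svd(Z, nu = 0, nv = 0)$d) +
    spec$lambda2 * sum(abs(Z))
  primal <- dual <- NA_real_
  res_window <- Inf
  for (it in seq_len(max_iter)) {
    Z <- .z_update_core(ctx, Z, Z1, Z2, U1, U2, rho, spec$clamp_eps,
                        max_inner = max_inner)
    Z1_old <- Z1; Z2_old <- Z2
    Z1 <- nuclear_prox(Z + U1, spec$lambda1 / rho)
    Z2 <- l1_prox(Z + U2, spec$lambda2 / rho)
    U1 <- U1 + (Z - Z1)
    U2 <- U2 + (Z - Z2)
    primal <- max(sqrt(sum((Z - Z1)^2)), sqrt(sum((Z - Z2)^2)))
    dual <- rho * max(sqrt(sum((Z1 - Z1_old)^2)), sqrt(sum((Z2 - Z2_old)^2)))
    primal_trace <- c(primal_trace, primal)
    dual_trace <- c(dual_trace, dual)
    if (trace_objective)
      obj_trace <- c(obj_trace, .nll_unbinned(ctx, Z, spec$clamp_eps) + pen(Z))
    # both residuals: the primal consensus gap alone is blind to a still-
    # moving Z when the prox steps are near-identities (small lambda / rho)
    rel <- max(primal, dual) / max(1, sqrt(sum(Z^2)))
    if (it %% 20L == 0L) {
      if (is.finite(res_window) && rel > 10 * res_window)
        stop("ADMM diverged: consensus residual grew 10-fold over 20 iterations")
      res_window <- rel
    }
    if (rel < tol) break
  }
  Z <- pmax((Z + t(Z)) / 2, 0)
  state <- structure(list(Z = Z, Z1 = Z1, Z2 = Z2, U1 = U1, U2 = U2,
                          rho = rho, iter = it,
                          primal_residual = primal, dual_residual = dual,
                          converged = max(primal, dual) /
                            max(1, sqrt(sum(Z^2))) < tol,
                          objective_trace = obj_trace,
                          primal_trace = primal_trace,
                          dual_trace = dual_trace),
                     class = "admm_state")
  list(X = mark_pair_matrix(z_to_x(Z), assignment$catalog),
       Z = Z, state = state)
}

#' @export
print.admm_state <- function(x, ...) {
  cat(sprintf("ADMM state: %d iteration(s), primal residual %.3g, dual residual %.3g, %s\n",
              x$iter, x$primal_residual, x$dual_residual,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

# ---- binned variant --------------------------------------------------------

# Penalized Poisson negative log-likelihood in X (probability scale) with
# penalties on the transformed scale Z = -log(1 - X); gradient by chain rule
# (subgradients for the nonsmooth penalties).
.binned_obj_grad <- function(ctx, k, X, lambda1, lambda2, clamp_eps) {
  lam <- pmax(.pair_s(ctx$Au, ctx$Av, X), clamp_eps)
  Z <- -log1p(-X)
  sv <- svd(Z)
  nll <- -(sum(k * log(lam) - lfactorial(k)) - .s_all(ctx, X))
  obj <- nll + lambda1 * sum(sv$d) + lambda2 * sum(Z)
  w <- -k / lam
  Ge <- if (nrow(ctx$Au)) crossprod(ctx$Au * w, ctx$Av) else
    matrix(0, ncol(X), ncol(X))
  G <- ctx$G_all + (Ge + t(Ge)) / 2
  dZdX <- 1 / (1 - X)
  Gpen <- (lambda1 * tcrossprod(sv$u, sv$v) + lambda2) * dZdX
  list(obj = obj, grad = G + (Gpen + t(Gpen)) / 2)
}

#' Fit the mark-pair matrix on binned data (Le Cam Poisson path)
#'
#' Maximizes the penalized Poisson log-likelihood of binned counts directly
#' in X (box-constrained to [0, x_max]) by projected gradient with Armijo
#' backtracking, restarted from several random nonnegative starting points;
#' the best-objective solution is returned.  The Poisson-approximated
#' problem is treated as nonconvex, hence the restarts.
#'
#' @param contacts binned \code{\link{contact_records}}.
#' @param assignment binned \code{\link{mark_assignment}}.
#' @param spec an \code{\link{objective_spec}}.
#' @param restarts number of random restarts (>= 1).
#' @param seed integer seed controlling the restarts.
#' @param x_max upper box bound on probabilities (strictly below 1).
#' @param max_iter projected-gradient iteration cap per start.
#' @return a list with the fitted \code{\link{mark_pair_matrix}} (\code{X})
#'   and the best penalized objective value (\code{objective}).
#' @export
fit_binned <- function(contacts, assignment, spec = objective_spec(),
                       restarts = 5L, seed = 1L, x_max = 1 - 1e-6,
                       max_iter = 500L) {
  if (restarts < 1) stop("restarts must be >= 1")
  M <- ncol(assignment$counts)
  ctx <- .make_ll_context(assignment, contacts, exclude = NULL,
                          pair_scope = spec$pair_scope)
  k <- ctx$counts
  runner <- function(X) {
    og <- .binned_obj_grad(ctx, k, X, spec$lambda1, spec$lambda2,
                           spec$clamp_eps)
    f <- og$obj
    step <- 0.1
    for (it in seq_len(max_iter)) {
      G <- og$grad
      ok <- FALSE
      for (h in 1:50) {
        Xn <- pmin(pmax(X - step * G, 0), x_max)
        ogn <- .binned_obj_grad(ctx, k, Xn, spec$lambda1, spec$lambda2,
                                spec$clamp_eps)
        if (is.finite(ogn$obj) && ogn$obj <= f + 1e-4 * sum(G * (Xn - X))) {
          ok <- TRUE
          break
        }
        step <- step / 2
      }
      if (!ok) break
      moved <- sqrt(sum((Xn - X)^2))
      X <- Xn; f <- ogn$obj; og <- ogn
      if (moved / step < 1e-7 * max(1, sqrt(sum(X^2)))) break
      step <- step * 2
    }
    list(X = X, obj = f)
  }
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  best <- NULL
  for (r in seq_len(restarts)) {
    X0 <- if (r == 1L) matrix(0.01, M, M) else {
      R <- matrix(runif(M * M, 0, 0.3), M, M)
      (R + t(R)) / 2
    }
    res <- runner(X0)
    if (is.null(best) || res$obj < best$obj) best <- res
  }
  Xf <- pmin(pmax((best$X + t(best$X)) / 2, 0), x_max)
  list(X = mark_pair_matrix(Xf, assignment$catalog), objective = best$obj)
}

# seed bookkeeping: set a local seed, restore the caller's RNG state on exit
.save_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
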