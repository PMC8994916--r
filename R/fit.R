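#' Decompose a contact graph into mark-pair interaction probabilities
#'
#' The main fitting function.  Given an undirected Hi-C/Micro-C contact
#' graph and a per-site chromatin-mark assignment over a shared site index,
#' estimates the symmetric matrix X of mark-pair interaction probabilities
#' by penalized maximum likelihood.
#'
#' Unbinned data (binary site-level contacts) use the convex transformed
#' objective \eqn{-\log L(Z) + \lambda_1 \|Z\|_* + \lambda_2 \|Z\|_1} over
#' symmetric \eqn{Z \ge 0} with \eqn{x = 1 - e^{-z}}, solved by
#' \code{\link{admm_fit}}.  Binned data (integer counts) use the Le Cam
#' Poisson approximation of the Poisson-binomial count model, fitted by
#' multi-start projected gradient (\code{\link{fit_binned}}).
#'
#' @param contacts a \code{\link{contact_records}} object.
#' @param assignment a \code{\link{mark_assignment}} over the same site
#'   index (both binned or both unbinned).
#' @param lambda1 nuclear-norm (low-rank) weight.
#' @param lambda2 L1 (sparsity) weight.
#' @param rho ADMM penalty parameter (unbinned path); defaults to
#'   \code{max(1, lambda1, lambda2)}.
#' @param tol ADMM relative consensus-residual tolerance.
#' @param max_iter outer iteration cap.
#' @param restarts random restarts for the binned path.
#' @param seed integer seed (binned restarts; recorded for reproducibility).
#' @param exclude optional held-out pairs excluded from the likelihood
#'   (neither edges nor non-edge background) -- used by cross-validation.
#' @param pair_scope \code{"within"} (default) or \code{"all"}; see
#'   \code{\link{objective_spec}}.
#' @param clamp_eps log-domain safety floor.
#' @param ... further arguments passed to \code{\link{admm_fit}} /
#'   \code{\link{fit_binned}}.
#' @return an object of class \code{"hicdecomp"} with components
#'   \code{X} (the fitted \code{\link{mark_pair_matrix}}), \code{Z},
#'   \code{spec}, \code{state} (ADMM diagnostics, unbinned path),
#'   \code{objective}, \code{binned}, \code{assignment}, \code{contacts},
#'   \code{seed} and \code{call}.
#' @examples
#' truth <- make_truth(n_marks = 4, sparsity = 0.4, seed = 7)
#' asg <- sample_assignment(truth, n_sites = 120)
#' ctc <- sample_contacts(truth, asg)
#' fit <- hicdecomp(ctc, asg, lambda1 = 0.1, lambda2 = 0.1)
#' coef(fit)
#' @export
hicdecomp <- function(contacts, assignment, lambda1 = 0.1, lambda2 = 0.1,
                      rho = NULL, tol = 1e-4, max_iter = 500L, restarts = 5L,
                      seed = 1L, exclude = NULL,
                      pair_scope = c("within", "all"), clamp_eps = 1e-10,
                      ...) {
  if (!inherits(assignment, "mark_assignment"))
    stop("assignment must be a mark_assignment")
  binned <- assignment$binned
  if (!identical(binned, isTRUE(attr(contacts, "binned"))))
    stop("contacts and assignment must both be binned or both unbinned")
  spec <- objective_spec(lambda1, lambda2, clamp_eps,
                         match.arg(pair_scope))
  if (binned) {
    res <- fit_binned(contacts, assignment, spec, restarts = restarts,
                      seed = seed, ...)
    out <- list(X = res$X, Z = x_to_z(res$X), spec = spec, state = NULL,
                objective = res$objective)
  } else {
    res <- admm_fit(contacts, assignment, spec, rho = rho, tol = tol,
                    max_iter = max_iter, exclude = exclude, ...)
    obj <- if (length(res$state$objective_trace))
      res$state$objective_trace[length(res$state$objective_trace)] else NA_real_
    out <- list(X = res$X, Z = res$Z, spec = spec, state = res$state,
                objective = obj)
  }
  out$binned <- binned
  out$assignment <- assignment
  out$contacts <- contacts
  out$exclude <- exclude
  out$seed <- seed
  out$call <- match.call()
  class(out) <- "hicdecomp"
  out
}

#' @export
print.hicdecomp <- function(x, ...) {
  cat("Mark-pair decomposition of a contact graph\n")
  cat(sprintf("  model: %s, %d marks, %d %s, %d contact pair(s)\n",
              if (x$binned) "binned (Le Cam Poisson)" else "unbinned (Bernoulli)",
              length(x$X$catalog), nrow(x$assignment$counts),
              if (x$binned) "bins" else "sites", nrow(x$contacts)))
  cat(sprintf("  lambda1 = %g (nuclear), lambda2 = %g (L1)\n",
              x$spec$lambda1, x$spec$lambda2))
  if (!is.null(x$state))
    cat(sprintf("  ADMM: %d iteration(s), %s\n", x$state$iter,
                if (isTRUE(x$state$converged)) "converged" else "NOT converged"))
  cat(sprintf("  penalized objective: %.6g\n", x$objective))
  invisible(x)
}

#' @export
coef.hicdecomp <- function(object, type = c("probability", "transformed"),
                           ...) {
  switch(match.arg(type), probability = object$X$X, transformed = object$Z)
}

#' @export
summary.hicdecomp <- function(object, top = 5L, threshold = 0.01, ...) {
  X <- object$X$X
  ut <- upper.tri(X, diag = TRUE)
  vals <- X[ut]
  nz <- sum(vals > threshold)
  idx <- which(ut, arr.ind = TRUE)
  o <- order(vals, decreasing = TRUE)
  top <- min(top, sum(vals > 0))
  top_df <- if (top > 0)
    data.frame(mark1 = rownames(X)[idx[o[seq_len(top)], 1]],
               mark2 = colnames(X)[idx[o[seq_len(top)], 2]],
               probability = vals[o[seq_len(top)]]) else NULL
  out <- list(fit = object, n_marks = ncol(X),
              support_size = nz, support_threshold = threshold,
              rank = qr((object$Z > 1e-8) * object$Z)$rank,
              top_pairs = top_df)
  class(out) <- "summary.hicdecomp"
  out
}

#' @export
print.summary.hicdecomp <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  support: %d mark pair(s) with x > %g (upper triangle), numeric rank %d\n",
              x$support_size, x$support_threshold, x$rank))
  if (!is.null(x$top_pairs)) {
    cat("  strongest interactions:\n")
    print(x$top_pairs, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Score site pairs under a fitted mark-pair matrix
#'
#' Each pair (u, v) is scored by the model edge probability
#' \eqn{1 - e^{-C_u^T Z C_v}} (unbinned) or by the expected count
#' \eqn{\lambda_{uv} = C_u^T X C_v} (binned).
#'
#' @param X a \code{\link{mark_pair_matrix}} (or plain probability matrix).
#' @param assignment a \code{\link{mark_assignment}}.
#' @param pairs data frame with columns \code{chrom1, pos1, chrom2, pos2}
#'   (a \code{contact_records} works).
#' @param type \code{"probability"} or \code{"rate"}.
#' @return numeric vector of per-pair scores, aligned with \code{pairs}.
#' @export
predict_probabilities <- function(X, assignment, pairs,
                                  type = c("probability", "rate")) {
  type <- match.arg(type)
  if (inherits(X, "mark_pair_matrix")) X <- X$X
  idx <- assignment$index
  key <- .site_key(idx$chrom, idx$pos)
  i <- match(.site_key(pairs$chrom1, pairs$pos1), key)
  j <- match(.site_key(pairs$chrom2, pairs$pos2), key)
  if (anyNA(i) || anyNA(j)) stop("pair endpoints missing from the site index")
  A <- assignment$counts
  storage.mode(A) <- "double"
  if (type == "rate")
    return(.pair_s(A[i, , drop = FALSE], A[j, , drop = FALSE], X))
  Z <- x_to_z(X)
  s <- .pair_s(A[i, , drop = FALSE], A[j, , drop = FALSE], Z)
  -expm1(-s)
}

#' @export
predict.hicdecomp <- function(object, pairs = NULL, assignment = NULL, ...) {
  if (is.null(pairs)) pairs <- object$contacts
  if (is.null(assignment)) assignment <- object$assignment
  predict_probabilities(object$X, assignment, pairs,
                        type = if (object$binned) "rate" else "probability")
}

#' @export
residuals.hicdecomp <- function(object, pairs = NULL, observed = NULL, ...) {
  if (is.null(pairs)) {
    pairs <- object$contacts
    observed <- if (object$binned) pairs$count else rep(1, nrow(pairs))
  } else if (is.null(observed)) {
    stop("observed outcomes must be supplied with explicit pairs")
  }
  observed - predict(object, pairs)
}

#' @export
plot.hicdecomp <- function(x, main = "mark-pair interaction probabilities",
                           ...) {
  X <- x$X$X
  M <- ncol(X)
  graphics::image(seq_len(M), seq_len(M), t(X[M:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "", main = main,
                  zlim = c(0, max(X, 1e-12)), ...)
  graphics::axis(1, at = seq_len(M), labels = colnames(X), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(M), labels = rev(rownames(X)), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' @export
simulate.hicdecomp <- function(object, nsim = 1, seed = NULL, ...) {
  old <- if (!is.null(seed)) .save_rng(seed) else NULL
  if (!is.null(seed)) on.exit(.restore_rng(old))
  out <- replicate(nsim, .sample_contacts_from(object$X$X, object$assignment,
                                               binned = object$binned),
                   simplify = FALSE)
  if (nsim == 1L) out[[1L]] else out
}

#' @export
logLik.hicdecomp <- function(object, ...) {
  ll <- if (object$binned)
    log_likelihood_binned(object$X, object$contacts, object$assignment,
                          object$spec)
  else suppressWarnings(
    log_likelihood_unbinned(object$Z, object$contacts, object$assignment,
                            object$spec, object$exclude))
  structure(ll, df = sum(upper.tri(object$Z, diag = TRUE)), class = "logLik")
}
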