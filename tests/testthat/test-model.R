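test_that("edge probability follows the independent mark-pair firing model", {
  X0 <- matrix(0, 2, 2)
  expect_equal(edge_probability(c(1, 1), c(1, 0), X0), 0)

  X1 <- matrix(0.5, 1, 1)
  expect_equal(edge_probability(1, 1, X1), 0.5)

  # two active pairs: 1 - (1 - 0.5)(1 - 0.2) = 0.6
  X <- matrix(c(0.5, 0.2, 0.2, 0.1), 2, 2)
  expect_equal(edge_probability(c(1, 1), c(1, 0), X), 0.6)

  # a certain mark pair forces probability one (limit case)
  Xc <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(edge_probability(c(1, 0), c(1, 0), Xc), 1)
})

test_that("the product and exponential forms of the edge probability agree", {
  set.seed(11)
  for (r in 1:50) {
    M <- sample(2:6, 1)
    X <- matrix(runif(M * M, 0, 0.8), M, M)
    X <- (X + t(X)) / 2
    cu <- rbinom(M, 3, 0.5)
    cv <- rbinom(M, 3, 0.5)
    p_prod <- 1 - prod((1 - X)^outer(cu, cv))
    p_pkg <- edge_probability(cu, cv, X)
    p_exp <- -expm1(-drop(cu %*% x_to_z(X) %*% cv))
    expect_equal(p_pkg, p_prod, tolerance = 1e-12)
    expect_equal(p_pkg, p_exp, tolerance = 1e-12)
  }
})

test_that("edge probability is monotone in X and in the mark vectors", {
  set.seed(12)
  M <- 4
  X <- matrix(runif(M * M, 0, 0.4), M, M); X <- (X + t(X)) / 2
  cu <- c(1, 0, 2, 1); cv <- c(0, 1, 1, 1)
  p0 <- edge_probability(cu, cv, X)
  Xup <- X; Xup[2, 3] <- Xup[3, 2] <- Xup[2, 3] + 0.3
  expect_gte(edge_probability(cu, cv, Xup), p0)
  expect_gte(edge_probability(cu + 1, cv, X), p0)
  expect_gte(edge_probability(cu, cv + c(1, 0, 0, 0), X), p0)
})

test_that("x/z transforms are inverse bijections", {
  expect_equal(z_to_x(matrix(0, 1, 1)), matrix(0, 1, 1))
  expect_equal(x_to_z(matrix(0.5, 1, 1)), matrix(log(2), 1, 1))
  # at z = 20, x sits within eps(1) of 1, so the recoverable precision of z
  # is ~ eps * e^z; 1e-6 is machine precision for the x representation there
  z <- matrix(seq(0, 20, length.out = 25), 5, 5)
  expect_equal(x_to_z(z_to_x(z)), z, tolerance = 1e-6)
  expect_error(x_to_z(matrix(1, 1, 1)), "\\[0, 1\\)")
  expect_error(z_to_x(matrix(-0.1, 1, 1)), "nonnegative")
})

test_that("unbinned log-likelihood matches closed forms", {
  # no edges, Z = 0 -> 0
  idx <- site_index(rep("chr1", 3), c(0L, 10L, 20L))
  asg <- mark_assignment(matrix(1L, 3, 1), "m", idx)
  none <- contact_records(character(), integer(), character(), integer())
  expect_equal(log_likelihood_unbinned(matrix(0, 1, 1), none, asg), 0)

  # one mark, one edge with s = log 2 and no non-edge pairs -> -log 2
  idx2 <- site_index(rep("chr1", 2), c(0L, 10L))
  asg2 <- mark_assignment(matrix(1L, 2, 1), "m", idx2)
  e2 <- contact_records("chr1", 0L, "chr1", 10L)
  expect_equal(log_likelihood_unbinned(matrix(log(2), 1, 1), e2, asg2),
               -log(2))
})

test_that("aggregate non-edge computation equals the brute-force double loop", {
  set.seed(21)
  for (r in 1:20) {
    inst <- random_tiny_instance(n_sites = sample(5:30, 1),
                                 n_marks = sample(2:5, 1))
    M <- ncol(inst$counts)
    Z <- matrix(runif(M * M, 0, 1.5), M, M); Z <- (Z + t(Z)) / 2
    got <- suppressWarnings(
      log_likelihood_unbinned(Z, inst$contacts, inst$assignment))
    want <- bf_loglik(Z, inst$counts, inst$chroms, inst$edges)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("an edge between mark-free sites is clamped with a warning", {
  idx <- site_index(rep("chr1", 3), c(0L, 10L, 20L))
  asg <- mark_assignment(matrix(c(1L, 0L, 0L), 3, 1), "m", idx)
  e <- contact_records("chr1", 10L, "chr1", 20L)
  expect_warning(ll <- log_likelihood_unbinned(matrix(1, 1, 1), e, asg),
                 "clamp")
  expect_true(is.finite(ll))
})

test_that("the penalized objective adds nuclear and L1 norms", {
  idx <- site_index(rep("chr1", 2), c(0L, 10L))
  asg <- mark_assignment(matrix(0L, 2, 1), "m", idx)  # mark-free: no data terms
  none <- contact_records(character(), integer(), character(), integer())
  expect_equal(objective(matrix(0, 1, 1), none, asg, objective_spec(1, 1)), 0)
  expect_equal(objective(matrix(1, 1, 1), none, asg, objective_spec(1, 1)), 2)
})

test_that("the transformed objective is convex (Jensen spot-check)", {
  set.seed(31)
  inst <- random_tiny_instance(n_sites = 12, n_marks = 3)
  spec <- objective_spec(0.3, 0.2)
  f <- function(Z) suppressWarnings(
    objective(Z, inst$contacts, inst$assignment, spec))
  for (r in 1:30) {
    Za <- matrix(runif(9, 0, 2), 3, 3); Za <- (Za + t(Za)) / 2
    Zb <- matrix(runif(9, 0, 2), 3, 3); Zb <- (Zb + t(Zb)) / 2
    for (t in c(0.25, 0.5, 0.75))
      expect_lte(f(t * Za + (1 - t) * Zb),
                 t * f(Za) + (1 - t) * f(Zb) + 1e-9)
  }
})

test_that("Poisson-binomial pmf matches enumeration and sums to one", {
  expect_equal(poisson_binomial_pmf(c(0.5, 0.5), 1), 0.5)
  expect_equal(poisson_binomial_pmf(c(0.5, 0.5), 0), 0.25)
  expect_equal(poisson_binomial_pmf(rep(0, 4), 0), 1)
  expect_equal(poisson_binomial_pmf(rep(0, 4), 2), 0)
  expect_equal(poisson_binomial_pmf(c(0.3, 0.3), 5), 0)  # k > T

  set.seed(41)
  for (r in 1:10) {
    T <- sample(1:9, 1)
    p <- runif(T)
    pmf <- poisson_binomial_pmf(p, 0:T)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    for (k in 0:T)
      expect_equal(pmf[k + 1], pb_enumerate(p, k), tolerance = 1e-12)
  }
})

test_that("Le Cam Poisson approximation obeys the total-variation bound", {
  expect_equal(lecam_poisson_pmf(0, 0), 1)
  expect_equal(lecam_poisson_pmf(1, 0), exp(-1))
  set.seed(51)
  for (r in 1:20) {
    T <- sample(2:10, 1)
    p <- runif(T, 0, 0.4)
    lam <- sum(p)
    pb <- poisson_binomial_pmf(p, 0:T)
    po <- dpois(0:T, lam)
    tv <- 0.5 * (sum(abs(pb - po)) + ppois(T, lam, lower.tail = FALSE))
    expect_lte(tv, sum(p^2) + 1e-12)
  }
})

test_that("binned log-likelihood matches the brute-force pairwise loop", {
  # all rates zero, all counts zero -> 0
  idx <- site_index(rep("chr1", 3), c(0L, 1000L, 2000L), resolution = 1000L)
  asg <- mark_assignment(matrix(c(2L, 1L, 0L), 3, 1), "m", idx)
  none <- contact_records(character(), integer(), character(), integer(),
                          binned = TRUE, resolution = 1000L)
  expect_equal(log_likelihood_binned(matrix(0, 1, 1), none, asg), 0)

  # single pair at the Poisson mode lambda = k: k log k - k - log k!
  idx2 <- site_index(rep("chr1", 2), c(0L, 1000L), resolution = 1000L)
  asg2 <- mark_assignment(matrix(c(2L, 2L), 2, 1), "m", idx2)
  k <- 2L
  ctc2 <- contact_records("chr1", 0L, "chr1", 1000L, k,
                          binned = TRUE, resolution = 1000L)
  X2 <- matrix(k / 4, 1, 1)  # lambda = 4 x = k
  expect_equal(log_likelihood_binned(X2, ctc2, asg2),
               k * log(k) - k - lfactorial(k))

  set.seed(61)
  for (r in 1:10) {
    n <- sample(5:20, 1); M <- sample(2:4, 1)
    counts <- matrix(rpois(n * M, 0.8), n, M)
    idx <- site_index(rep("chr1", n), (seq_len(n) - 1L) * 1000L,
                      resolution = 1000L)
    asg <- mark_assignment(counts, paste0("m", 1:M), idx)
    X <- matrix(runif(M * M, 0, 0.5), M, M); X <- (X + t(X)) / 2
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    sel <- pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE]
    kk <- rpois(nrow(sel), 2) + 1L
    ctc <- if (nrow(sel))
      contact_records(rep("chr1", nrow(sel)), (sel[, 1] - 1L) * 1000L,
                      rep("chr1", nrow(sel)), (sel[, 2] - 1L) * 1000L, kk,
                      binned = TRUE, resolution = 1000L) else none
    got <- log_likelihood_binned(X, ctc, asg)
    want <- bf_loglik_binned(X, counts, rep("chr1", n), sel, kk)
    expect_equal(got, want, tolerance = 1e-9)
  }
})
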