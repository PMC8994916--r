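#' Ground-truth mark-pair matrix for simulation
#'
#' Builds a known symmetric mark-pair probability matrix X_true, either with
#' a prescribed sparse support (a requested fraction of nonzero entries) or
#' with block/community structure (high probabilities within mark groups,
#' low between), which yields a low-rank-plus-sparse target -- the regime
#' the penalties are designed for.  Per-mark occurrence densities are drawn
#' once from Uniform(0.05, 0.3) to mimic realistic sparsity heterogeneity
#' of peak tracks.
#'
#' @param n_marks number of marks |M|.
#' @param sparsity fraction of upper-triangle entries that are nonzero when
#'   no block structure is given (in [0, 1]).
#' @param block_structure optional list with elements \code{groups} (list of
#'   mark index vectors), \code{within} and \code{between} (probabilities).
#' @param seed integer seed.
#' @param n_sites default number of restriction sites for downstream
#'   sampling.
#' @param mark_density optional per-mark Bernoulli occurrence rates
#'   (defaults to Uniform(0.05, 0.3) draws).
#' @param value_range range of nonzero interaction probabilities for the
#'   sparse-support option.
#' @param spacing distance in bp between consecutive synthetic restriction
#'   sites (default 4 kb, a typical restriction-fragment scale).
#' @return an object of class \code{"synthetic_truth"}: X_true (a
#'   \code{\link{mark_pair_matrix}}), catalog, n_sites, mark_density,
#'   spacing and seed.
#' @export
make_truth <- function(n_marks, sparsity = 0.2, block_structure = NULL,
                       seed = 1L, n_sites = 500L, mark_density = NULL,
                       value_range = c(0.1, 0.5), spacing = 4000L) {
  if (sparsity < 0 || sparsity > 1) stop("sparsity must lie in [0, 1]")
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  catalog <- mark_catalog(sprintf("mark%02d", seq_len(n_marks)))
  X <- matrix(0, n_marks, n_marks)
  if (is.null(block_structure)) {
    ut <- which(upper.tri(X, diag = TRUE))
    nnz <- round(sparsity * length(ut))
    pick <- if (nnz > 0) sample(ut, nnz) else integer()
    X[pick] <- runif(length(pick), value_range[1], value_range[2])
    X[lower.tri(X)] <- t(X)[lower.tri(X)]
  } else {
    between <- if (is.null(block_structure$between)) 0 else
      block_structure$between
    X[] <- between
    for (g in block_structure$groups)
      X[g, g] <- block_structure$within
  }
  if (is.null(mark_density)) mark_density <- runif(n_marks, 0.05, 0.3)
  structure(list(X = mark_pair_matrix(X, catalog), catalog = catalog,
                 n_sites = as.integer(n_sites),
                 mark_density = mark_density,
                 spacing = as.integer(spacing), seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic truth: %d marks, %d sites, %.0f%% nonzero mark pairs\n",
              length(x$catalog), x$n_sites,
              100 * mean(x$X$X[upper.tri(x$X$X, diag = TRUE)] > 0)))
  invisible(x)
}

#' Sample a mark assignment from a synthetic truth
#'
#' Unbinned: each (site, mark) indicator is Bernoulli with the truth's
#' per-mark density.  Binned: counts are Poisson with rate density *
#' \code{sites_per_bin}, emulating the aggregation of several restriction
#' sites into one bin.
#'
#' @param truth a \code{\link{make_truth}} object.
#' @param n_sites number of sites (default the truth's).
#' @param seed integer seed (default derived from the truth's seed).
#' @param binned sample Poisson per-bin counts instead of indicators.
#' @param resolution bin width when \code{binned} (default 4 *
#'   \code{truth$spacing}).
#' @param sites_per_bin expected sites per bin for the binned rate.
#' @param chrom chromosome name for the synthetic index.
#' @return a \code{\link{mark_assignment}}.
#' @export
sample_assignment <- function(truth, n_sites = truth$n_sites,
                              seed = truth$seed + 1L, binned = FALSE,
                              resolution = 4L * truth$spacing,
                              sites_per_bin = 4, chrom = "chrS") {
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  M <- length(truth$catalog)
  if (binned) {
    counts <- vapply(seq_len(M), function(m)
      rpois(n_sites, truth$mark_density[m] * sites_per_bin),
      integer(n_sites))
    idx <- site_index(rep(chrom, n_sites),
                      (seq_len(n_sites) - 1L) * resolution,
                      resolution = resolution)
  } else {
    counts <- vapply(seq_len(M), function(m)
      rbinom(n_sites, 1L, truth$mark_density[m]), integer(n_sites))
    idx <- site_index(rep(chrom, n_sites),
                      seq_len(n_sites) * truth$spacing)
  }
  mark_assignment(counts, truth$catalog, idx)
}

# internal sampler shared with simulate.hicdecomp: X on probability scale
.sample_contacts_from <- function(X, assignment, binned = FALSE,
                                  mode = c("bernoulli", "lecam", "exact")) {
  mode <- match.arg(mode)
  idx <- assignment$index
  A <- assignment$counts
  storage.mode(A) <- "double"
  res <- attr(idx, "resolution")
  out <- vector("list", length(unique(idx$chrom)))
  names(out) <- unique(idx$chrom)
  for (chr in unique(idx$chrom)) {
    rows <- which(idx$chrom == chr)
    n <- length(rows)
    if (n < 2) next
    Ac <- A[rows, , drop = FALSE]
    if (mode == "bernoulli") {
      S <- Ac %*% x_to_z(X) %*% t(Ac)
      P <- -expm1(-S)
      U <- matrix(runif(n * n), n, n)
      hit <- which(upper.tri(P) & U < P, arr.ind = TRUE)
      if (!nrow(hit)) next
      out[[chr]] <- data.frame(chrom1 = chr, pos1 = idx$pos[rows[hit[, 1]]],
                               chrom2 = chr, pos2 = idx$pos[rows[hit[, 2]]],
                               count = 1L, stringsAsFactors = FALSE)
    } else if (mode == "lecam") {
      L <- Ac %*% X %*% t(Ac)
      ut <- which(upper.tri(L), arr.ind = TRUE)
      k <- rpois(nrow(ut), L[ut])
      pos <- k > 0
      if (!any(pos)) next
      out[[chr]] <- data.frame(chrom1 = chr, pos1 = idx$pos[rows[ut[pos, 1]]],
                               chrom2 = chr, pos2 = idx$pos[rows[ut[pos, 2]]],
                               count = k[pos], stringsAsFactors = FALSE)
    } else {  # exact Poisson-binomial: binomial draw per mark pair
      ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
      xv <- as.vector(X)
      recs <- lapply(seq_len(nrow(ut)), function(r) {
        w <- outer(Ac[ut[r, 1], ], Ac[ut[r, 2], ])  # slot multiplicities
        sz <- as.vector(w)
        k <- sum(rbinom(length(sz), sz, xv))
        k
      })
      k <- unlist(recs)
      pos <- k > 0
      if (!any(pos)) next
      out[[chr]] <- data.frame(chrom1 = chr, pos1 = idx$pos[rows[ut[pos, 1]]],
                               chrom2 = chr, pos2 = idx$pos[rows[ut[pos, 2]]],
                               count = k[pos], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(df))
    df <- data.frame(chrom1 = character(), pos1 = integer(),
                     chrom2 = character(), pos2 = integer(),
                     count = integer(), stringsAsFactors = FALSE)
  contact_records(df$chrom1, df$pos1, df$chrom2, df$pos2, df$count,
                  binned = binned, resolution = res)
}

#' Sample a contact graph from a synthetic truth
#'
#' Forward simulation of the generative model: every unordered
#' within-chromosome pair is sampled independently.  \code{"unbinned"} draws
#' a Bernoulli edge with the model probability
#' \eqn{1 - e^{-C_u^T Z C_v}}; \code{"binned-exact"} draws Poisson-binomial
#' counts by firing each slot independently; \code{"binned-lecam"} draws
#' Poisson counts with rate \eqn{C_u^T X C_v}.
#'
#' @param truth a \code{\link{make_truth}} object.
#' @param assignment a \code{\link{mark_assignment}} (as from
#'   \code{\link{sample_assignment}}).
#' @param mode one of \code{"unbinned"}, \code{"binned-exact"},
#'   \code{"binned-lecam"}.
#' @param seed integer seed (default derived from the truth's seed).
#' @return a \code{\link{contact_records}} object.
#' @export
sample_contacts <- function(truth, assignment,
                            mode = c("unbinned", "binned-exact",
                                     "binned-lecam"),
                            seed = truth$seed + 2L) {
  mode <- match.arg(mode)
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  .sample_contacts_from(truth$X$X, assignment,
                        binned = mode != "unbinned",
                        mode = switch(mode, unbinned = "bernoulli",
                                      `binned-exact` = "exact",
                                      `binned-lecam` = "lecam"))
}

#' Generate the reference fixture suite
#'
#' Three fully seeded datasets written through the package's file formats,
#' each with its ground truth attached: \code{tiny} (3 marks, 8 sites;
#' solvable by brute-force oracles), \code{small} (6 marks, 500 sites; used
#' for parameter-recovery checks) and \code{medium} (16 marks, 3000 sites;
#' a scaled-down genome-wide catalog).
#'
#' @param seed integer seed.
#' @param dir output directory (created if missing).
#' @param sizes subset of \code{c("tiny", "small", "medium")}.
#' @return named list per size: file paths (\code{*_file}) plus the
#'   in-memory \code{truth}, \code{assignment} and \code{contacts}.
#' @export
make_fixture_suite <- function(seed = 1L, dir = tempfile("fixtures"),
                               sizes = c("tiny", "small", "medium")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- list(
    tiny = list(n_marks = 3L, n_sites = 8L, sparsity = 0.5,
                block = NULL),
    small = list(n_marks = 6L, n_sites = 500L, sparsity = NA,
                 block = list(groups = list(1:3, 4:6), within = 0.4,
                              between = 0)),
    medium = list(n_marks = 16L, n_sites = 3000L, sparsity = 0.05,
                  block = NULL))
  out <- list()
  for (sz in sizes) {
    p <- params[[sz]]
    truth <- make_truth(p$n_marks,
                        sparsity = if (is.na(p$sparsity)) 0.2 else p$sparsity,
                        block_structure = p$block,
                        seed = seed + match(sz, names(params)),
                        n_sites = p$n_sites)
    asg <- sample_assignment(truth)
    ctc <- sample_contacts(truth, asg)
    paths <- list(assignment_file = file.path(dir, paste0(sz, "_assignment.tsv")),
                  contacts_file = file.path(dir, paste0(sz, "_contacts.txt")),
                  truth_file = file.path(dir, paste0(sz, "_truth.tsv")),
                  config_file = file.path(dir, paste0(sz, "_config.txt")))
    write_assignment(asg, paths$assignment_file)
    write_contacts(ctc, paths$contacts_file)
    write_markpair_matrix(truth$X, paths$truth_file)
    write_config(list(size = sz, n_marks = p$n_marks, n_sites = p$n_sites,
                      seed = truth$seed, spacing = truth$spacing,
                      mark_density = paste(format(truth$mark_density),
                                           collapse = ",")),
                 paths$config_file)
    out[[sz]] <- c(paths, list(truth = truth, assignment = asg,
                               contacts = ctc))
  }
  out
}
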