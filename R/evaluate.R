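#' ROC curve and AUC for contact prediction
#'
#' Sweeps the score threshold from high to low and reports the ROC points
#' and the area under the curve by trapezoidal integration; tied scores are
#' handled by rank averaging, so the AUC equals the Wilcoxon rank statistic.
#'
#' @param scores numeric per-pair prediction scores.
#' @param truth binary per-pair labels (1 = observed contact).
#' @return a list with \code{auc} and a data frame \code{roc} of
#'   (threshold, fpr, tpr) points.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth)) stop("scores and truth lengths differ")
  np <- as.numeric(sum(truth == 1L))
  nn <- as.numeric(sum(truth == 0L))
  if (np == 0L) stop("degenerate truth: no positive pairs")
  if (nn == 0L) stop("degenerate truth: no negative pairs")
  r <- rank(scores)
  auc <- (sum(r[truth == 1L]) - np * (np + 1) / 2) / (np * nn)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- truth[o]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last <- !duplicated(s, fromLast = TRUE)  # one point per distinct threshold
  roc <- data.frame(threshold = s[last], fpr = fp[last] / nn,
                    tpr = tp[last] / np)
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), roc)
  list(auc = auc, roc = roc)
}

#' Distance-decay baseline
#'
#' The null predictor that scores a pair only by genomic distance:
#' \eqn{P(u, v \text{ interact}) = \alpha d(u,v)^{-\beta}} clipped to
#' [0, 1].  The exponent is fixed; the scale alpha is learned on the
#' training set by maximizing the Bernoulli likelihood of the labels
#' (a 1-D search).  Ranking metrics such as AUC are invariant to alpha.
#'
#' @param d positive training distances.
#' @param y binary training labels.
#' @param beta fixed decay exponent (conventional values 1, 1.5, 2).
#' @return an object of class \code{"decay_baseline"} with elements
#'   \code{alpha}, \code{beta}.
#' @export
fit_distance_decay <- function(d, y, beta = 1) {
  if (any(d <= 0)) stop("distances must be positive")
  y <- as.numeric(y)
  base <- d^(-beta)
  eps <- 1e-12
  nll <- function(log_alpha) {
    p <- pmin(pmax(exp(log_alpha) * base, eps), 1 - eps)
    -sum(y * log(p) + (1 - y) * log1p(-p))
  }
  if (all(y == 0)) {
    alpha <- 0
  } else {
    hi <- log(1 / min(base))  # alpha at which the largest p saturates
    opt <- optimize(nll, lower = hi - 40, upper = hi + 5)
    alpha <- exp(opt$minimum)
  }
  structure(list(alpha = alpha, beta = beta), class = "decay_baseline")
}

#' @export
predict.decay_baseline <- function(object, d, ...) {
  pmin(pmax(object$alpha * d^(-object$beta), 0), 1)
}

#' A/B compartment calls from a contact or probability matrix
#'
#' The standard first-eigenvector method: the input matrix is converted to
#' its column correlation matrix, centered, and the sign pattern of the
#' leading principal component splits the bins into two compartments.
#' Zero loadings join the positive class; a global sign flip gives the same
#' partition.
#'
#' @param mat square symmetric numeric matrix (>= 2 bins).
#' @return integer vector of labels in {1, 2}, one per bin.
#' @export
compartment_calls <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat) || nrow(mat) < 2)
    stop("need a square matrix with at least 2 bins")
  sds <- apply(mat, 2, sd)
  if (any(sds == 0) || any(!is.finite(sds)))
    stop("degenerate input: constant rows/columns have no correlation structure")
  C <- cor(mat)
  pc <- prcomp(C, center = TRUE, scale. = FALSE)
  ev <- pc$rotation[, 1]
  ifelse(ev >= 0, 1L, 2L)
}

#' Normalized variation of information between two partitions
#'
#' \eqn{VI(p, q) = H(p) + H(q) - 2 I(p; q)} with natural-log entropies over
#' the joint label contingency table, normalized by \eqn{\log n} so the
#' result lies in [0, 1]; 0 means identical partitions, larger is worse.
#'
#' @param p,q integer label vectors over the same bin index.
#' @return the normalized variation of information.
#' @export
nvi <- function(p, q) {
  if (length(p) != length(q)) stop("partitions must cover the same index")
  n <- length(p)
  if (n < 2) return(0)
  joint <- table(p, q) / n
  hp <- -sum(ifelse(rowSums(joint) > 0,
                    rowSums(joint) * log(rowSums(joint)), 0))
  hq <- -sum(ifelse(colSums(joint) > 0,
                    colSums(joint) * log(colSums(joint)), 0))
  pj <- joint[joint > 0]
  hpq <- -sum(pj * log(pj))
  vi <- 2 * hpq - hp - hq  # = H(p) + H(q) - 2 I(p;q)
  max(0, vi) / log(n)
}

#' Confusion counts between true and predicted domain boundaries
#'
#' Matches each true boundary to at most one predicted boundary within
#' \code{tol_bins} (greedy, nearest pairs first); a matched true boundary is
#' a true positive, unmatched predicted boundaries are false positives,
#' unmatched true boundaries false negatives.
#'
#' @param true_boundaries,pred_boundaries boundary positions on a common
#'   bin grid.
#' @param tol_bins matching tolerance in bins (default 0: exact).
#' @return a list with TP, FP, FN, TPR, FNR.
#' @export
boundary_confusion <- function(true_boundaries, pred_boundaries,
                               tol_bins = 0L) {
  tb <- sort(unique(true_boundaries))
  pb <- sort(unique(pred_boundaries))
  if (length(tb) == 0L) stop("no true boundaries supplied")
  cand <- NULL
  if (length(pb)) {
    cand <- expand.grid(ti = seq_along(tb), pi = seq_along(pb))
    cand$d <- abs(tb[cand$ti] - pb[cand$pi])
    cand <- cand[cand$d <= tol_bins, , drop = FALSE]
    cand <- cand[order(cand$d, cand$ti, cand$pi), , drop = FALSE]
  }
  used_t <- logical(length(tb)); used_p <- logical(length(pb))
  if (!is.null(cand)) for (r in seq_len(nrow(cand))) {
    ti <- cand$ti[r]; pi <- cand$pi[r]
    if (!used_t[ti] && !used_p[pi]) {
      used_t[ti] <- TRUE
      used_p[pi] <- TRUE
    }
  }
  tp <- sum(used_t)
  tpr <- tp / length(tb)
  list(TP = tp, FP = sum(!used_p), FN = sum(!used_t),
       TPR = tpr, FNR = 1 - tpr)
}

#' Stability between two fitted mark-pair matrices
#'
#' Spearman rank correlation over the upper-triangle entries (diagonal
#' included) of two mark-pair matrices on the same catalog -- the replicate
#' stability statistic (e.g. across restriction enzymes or resolutions).
#'
#' @param X_a,X_b \code{\link{mark_pair_matrix}} objects (or plain
#'   matrices) over the same catalog order.
#' @return Spearman's rho.
#' @export
stability_correlation <- function(X_a, X_b) {
  if (inherits(X_a, "mark_pair_matrix")) X_a <- X_a$X
  if (inherits(X_b, "mark_pair_matrix")) X_b <- X_b$X
  if (!all(dim(X_a) == dim(X_b))) stop("matrices must share the catalog")
  ut <- upper.tri(X_a, diag = TRUE)
  cor(X_a[ut], X_b[ut], method = "spearman")
}

# ---- pair universes and cross-validation -----------------------------------

.all_pairs_chrom <- function(index, chr) {
  rows <- which(index$chrom == chr)
  if (length(rows) < 2) return(NULL)
  ut <- which(upper.tri(diag(length(rows))), arr.ind = TRUE)
  data.frame(chrom1 = chr, pos1 = index$pos[rows[ut[, 1]]],
             chrom2 = chr, pos2 = index$pos[rows[ut[, 2]]],
             stringsAsFactors = FALSE)
}

#' Build the scored pair universe (positives + sampled negatives)
#'
#' Positive pairs are the observed contacts.  Negative pairs are
#' within-chromosome non-edges: all of them when there are at most
#' \code{ratio} times the positive count, otherwise a seeded uniform sample
#' of exactly \code{ratio} times the positive count.
#'
#' @param contacts \code{\link{contact_records}} (the positives).
#' @param index the \code{\link{site_index}}.
#' @param ratio negative:positive ratio cap.
#' @param seed integer seed for the subsample.
#' @return a data frame of pairs with a \code{label} column (1/0).
#' @export
scored_pair_universe <- function(contacts, index, ratio = 10, seed = 1L) {
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  neg <- list()
  for (chr in unique(index$chrom)) {
    rows <- which(index$chrom == chr)
    n <- length(rows)
    if (n < 2) next
    pos <- index$pos[rows]
    sel <- contacts$chrom1 == chr & contacts$chrom2 == chr
    # encode an unordered pair (a < b) of local site ranks as one integer
    a <- as.numeric(match(contacts$pos1[sel], pos))
    b <- as.numeric(match(contacts$pos2[sel], pos))
    pos_code <- (a - 1) * n + b
    ut <- as.numeric(which(upper.tri(matrix(FALSE, n, n))))
    # column-major index k has row r < col c; re-encode as (r-1)*n + c
    ut <- ((ut - 1) %% n) * n + (ut - 1) %/% n + 1
    neg_code <- setdiff(ut, pos_code)
    neg[[chr]] <- data.frame(
      chrom1 = chr, pos1 = pos[(neg_code - 1) %/% n + 1],
      chrom2 = chr, pos2 = pos[(neg_code - 1) %% n + 1],
      stringsAsFactors = FALSE)
  }
  neg <- do.call(rbind, neg)
  npos <- nrow(contacts)
  if (!is.null(neg) && nrow(neg) > ratio * npos)
    neg <- neg[sample.int(nrow(neg), ratio * npos), , drop = FALSE]
  pos <- as.data.frame(contacts)[, c("chrom1", "pos1", "chrom2", "pos2")]
  out <- rbind(cbind(pos, label = 1L),
               if (!is.null(neg)) cbind(neg, label = 0L))
  rownames(out) <- NULL
  out
}

.subset_chroms <- function(assignment, contacts, chroms) {
  keep <- assignment$index$chrom %in% chroms
  idx <- site_index(assignment$index$chrom[keep],
                    assignment$index$pos[keep],
                    resolution = attr(assignment$index, "resolution"))
  asg <- mark_assignment(assignment$counts[keep, , drop = FALSE],
                         assignment$catalog, idx)
  ck <- contacts$chrom1 %in% chroms & contacts$chrom2 %in% chroms
  ctc <- contacts[ck, , drop = FALSE]
  class(ctc) <- class(contacts)
  attr(ctc, "binned") <- attr(contacts, "binned")
  attr(ctc, "resolution") <- attr(contacts, "resolution")
  list(assignment = asg, contacts = ctc)
}

# pairs coming from scored_pair_universe are already normalized (u < v,
# unique), so skip the full contact_records normalization
.pairs_as_contacts <- function(pairs) {
  df <- data.frame(chrom1 = pairs$chrom1, pos1 = pairs$pos1,
                   chrom2 = pairs$chrom2, pos2 = pairs$pos2,
                   count = 1L, stringsAsFactors = FALSE)
  class(df) <- c("contact_records", "data.frame")
  df
}

#' Nested cross-validation for the regularization weights
#'
#' Fivefold-outer / fourfold-inner nested cross-validation (defaults).  In
#' \code{"same-chromosome"} mode the outer folds are random partitions of
#' the scored pair universe (positives plus sampled negatives); in
#' \code{"leave-one-chromosome-out"} mode each outer fold is one chromosome
#' and the model trains on the remaining chromosomes.  Inner folds select
#' the (lambda1, lambda2) pair maximizing mean inner AUC, ties broken
#' toward the more regularized pair.  Held-out pairs are excluded from the
#' training likelihood (neither edges nor non-edge background).
#'
#' @param contacts unbinned \code{\link{contact_records}}.
#' @param assignment unbinned \code{\link{mark_assignment}}.
#' @param lambda_grid list of c(lambda1, lambda2) pairs.
#' @param outer_k,inner_k fold counts (>= 2).
#' @param mode \code{"same-chromosome"} or \code{"leave-one-chromosome-out"}.
#' @param seed integer seed (folds and negative sampling are deterministic
#'   given the seed).
#' @param neg_ratio negative:positive sampling ratio for the universe.
#' @param ... fitting arguments forwarded to \code{\link{hicdecomp}}
#'   (e.g. \code{max_iter}, \code{tol}, \code{rho}).
#' @return a list: \code{lambda} (the overall chosen pair), \code{per_fold}
#'   data frame of per-outer-fold choices and held-out AUCs, and
#'   \code{inner_scores} (mean inner AUC per fold x grid point).
#' @export
nested_cv <- function(contacts, assignment, lambda_grid, outer_k = 5L,
                      inner_k = 4L,
                      mode = c("same-chromosome", "leave-one-chromosome-out"),
                      seed = 1L, neg_ratio = 10, ...) {
  mode <- match.arg(mode)
  if (outer_k < 2 || inner_k < 2) stop("fold counts must be >= 2")
  if (!length(lambda_grid)) stop("empty lambda grid")
  grid <- do.call(rbind, lapply(lambda_grid, function(l) l[1:2]))
  # tie-break order: more regularized pairs first
  reg_order <- order(grid[, 1] + grid[, 2], grid[, 1], decreasing = TRUE)

  fit_score <- function(train_contacts, train_assignment, exclude_pairs,
                        test_pairs, lambda, test_assignment) {
    fit <- hicdecomp(train_contacts, train_assignment,
                     lambda1 = lambda[1], lambda2 = lambda[2],
                     exclude = if (nrow(exclude_pairs))
                       .pairs_as_contacts(exclude_pairs) else NULL, ...)
    sc <- predict(fit, test_pairs, assignment = test_assignment)
    roc_auc(sc, test_pairs$label)$auc
  }

  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  universe <- scored_pair_universe(contacts, assignment$index,
                                   ratio = neg_ratio,
                                   seed = sample.int(2^30, 1))
  if (mode == "same-chromosome") {
    fold_of <- sample(rep_len(seq_len(outer_k), nrow(universe)))
    outer_ids <- seq_len(outer_k)
  } else {
    chroms <- unique(assignment$index$chrom)
    if (length(chroms) < 2)
      stop("leave-one-chromosome-out needs at least 2 chromosomes")
    fold_of <- match(universe$chrom1, chroms)
    outer_ids <- seq_along(chroms)
  }
  inner_seed <- sample.int(2^30, length(outer_ids))

  per_fold <- list()
  inner_scores <- matrix(NA_real_, length(outer_ids), nrow(grid))
  for (f in outer_ids) {
    test <- universe[fold_of == f, , drop = FALSE]
    train <- universe[fold_of != f, , drop = FALSE]
    if (!nrow(test) || !any(test$label == 1) || !any(test$label == 0)) next
    if (mode == "leave-one-chromosome-out") {
      chroms <- unique(assignment$index$chrom)
      sub <- .subset_chroms(assignment, contacts, chroms[-f])
      tr_contacts <- sub$contacts; tr_assignment <- sub$assignment
      train <- train[train$chrom1 %in% chroms[-f], , drop = FALSE]
      # scoring the held-out chromosome needs its sites: use the full index
      test_assignment <- assignment
    } else {
      tr_contacts <- contacts; tr_assignment <- assignment
      test_assignment <- assignment
    }
    set.seed(inner_seed[f])
    ifold <- sample(rep_len(seq_len(inner_k), nrow(train)))
    means <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      aucs <- numeric(0)
      for (i in seq_len(inner_k)) {
        itest <- train[ifold == i, , drop = FALSE]
        if (!any(itest$label == 1) || !any(itest$label == 0)) next
        held <- if (mode == "leave-one-chromosome-out") itest[, 1:4] else
          rbind(test[, 1:4], itest[, 1:4])
        fit1 <- tryCatch(
          fit_score(tr_contacts, tr_assignment, held, itest, grid[g, ],
                    test_assignment),
          error = function(e) NA_real_)
        aucs <- c(aucs, fit1)
      }
      means[g] <- mean(aucs, na.rm = TRUE)
    }
    inner_scores[f, ] <- means
    best <- reg_order[which.max(means[reg_order])]
    outer_excl <- if (mode == "leave-one-chromosome-out")
      test[0, 1:4] else test[, 1:4]
    outer_auc <- fit_score(tr_contacts, tr_assignment, outer_excl,
                           test, grid[best, ], test_assignment)
    per_fold[[length(per_fold) + 1L]] <-
      data.frame(fold = f, lambda1 = grid[best, 1], lambda2 = grid[best, 2],
                 auc = outer_auc)
  }
  per_fold <- do.call(rbind, per_fold)
  # overall choice: the most frequently selected pair, ties toward regularized
  key <- paste(per_fold$lambda1, per_fold$lambda2)
  tab <- table(key)
  winners <- names(tab)[tab == max(tab)]
  gkey <- paste(grid[, 1], grid[, 2])
  chosen <- reg_order[gkey[reg_order] %in% winners][1]
  list(lambda = grid[chosen, ], per_fold = per_fold,
       inner_scores = inner_scores, grid = grid)
}

# ---- perturbations ---------------------------------------------------------

#' Mask marks inside a genomic region
#'
#' Zeroes the selected mark columns for every site/bin whose position lies
#' in [start, end) on the region's chromosome; everything else is
#' unchanged.  Emulates in-silico deletion of binding sites (e.g. CTCF
#' masking at a TAD boundary).
#'
#' @param assignment a \code{\link{mark_assignment}}.
#' @param region list or vector (chrom, start, end).
#' @param marks character vector of mark names, or \code{"all"}.
#' @return the masked \code{\link{mark_assignment}}.
#' @export
mask_marks <- function(assignment, region, marks = "all") {
  chrom <- as.character(region[[1]])
  start <- as.numeric(region[[2]]); end <- as.numeric(region[[3]])
  cols <- if (identical(marks, "all")) seq_along(assignment$catalog) else {
    m <- match(marks, as.character(assignment$catalog))
    if (anyNA(m)) stop("unknown mark(s): ",
                       paste(marks[is.na(m)], collapse = ", "))
    m
  }
  idx <- assignment$index
  rows <- idx$chrom == chrom & idx$pos >= start & idx$pos < end
  counts <- assignment$counts
  counts[rows, cols] <- 0L
  mark_assignment(counts, assignment$catalog, idx)
}

#' Excise a genomic region and rejoin the flanks
#'
#' Removes the sites/bins inside [start, end) on one chromosome, shifts all
#' downstream coordinates left by the region length, and drops contacts
#' incident to the removed sites (shifting the surviving coordinates the
#' same way).  Emulates a structural deletion.
#'
#' @param assignment a \code{\link{mark_assignment}}.
#' @param contacts a \code{\link{contact_records}}.
#' @param region list or vector (chrom, start, end).
#' @return list with the excised \code{assignment} and \code{contacts}.
#' @export
delete_region <- function(assignment, contacts, region) {
  chrom <- as.character(region[[1]])
  start <- as.numeric(region[[2]]); end <- as.numeric(region[[3]])
  if (end < start) stop("region end before start")
  len <- end - start
  idx <- assignment$index
  inside <- idx$chrom == chrom & idx$pos >= start & idx$pos < end
  shift <- function(ch, pos)
    as.integer(ifelse(ch == chrom & pos >= end, pos - len, pos))
  new_idx <- site_index(idx$chrom[!inside], shift(idx$chrom, idx$pos)[!inside],
                        resolution = attr(idx, "resolution"))
  counts <- assignment$counts[!inside, , drop = FALSE]
  o <- match(.site_key(new_idx$chrom, new_idx$pos),
             .site_key(idx$chrom[!inside], shift(idx$chrom, idx$pos)[!inside]))
  asg <- mark_assignment(counts[o, , drop = FALSE], assignment$catalog,
                         new_idx)
  drop1 <- contacts$chrom1 == chrom & contacts$pos1 >= start &
    contacts$pos1 < end
  drop2 <- contacts$chrom2 == chrom & contacts$pos2 >= start &
    contacts$pos2 < end
  keep <- !(drop1 | drop2)
  ctc <- contact_records(contacts$chrom1[keep],
                         shift(contacts$chrom1, contacts$pos1)[keep],
                         contacts$chrom2[keep],
                         shift(contacts$chrom2, contacts$pos2)[keep],
                         contacts$count[keep],
                         binned = isTRUE(attr(contacts, "binned")),
                         resolution = attr(contacts, "resolution"))
  list(assignment = asg, contacts = ctc)
}
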