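#' Domain containers
#'
#' The model works on four in-memory structures: a mark catalog (an ordered
#' character vector of mark names), a site index (ordered genomic positions or
#' bins), a mark assignment (sites x marks count matrix), and contact records
#' (an undirected interaction graph stored as pairs with u < v).  All
#' coordinates are 0-based; bins are half-open [start, start + resolution).
#'
#' @name hicdecomp-types
NULL

#' Construct a mark catalog
#'
#' @param names character vector of unique mark identifiers.  The order is
#'   fixed: rows/columns of every fitted mark-pair matrix are addressed by it.
#' @return a character vector of class \code{"mark_catalog"}.
#' @export
mark_catalog <- function(names) {
  names <- as.character(names)
  if (length(names) == 0L) stop("mark catalog must contain at least one mark")
  if (anyDuplicated(names)) stop("mark names must be unique")
  structure(names, class = "mark_catalog")
}

#' Construct a site index
#'
#' An ordered set of genomic positions (unbinned restriction sites) or bins.
#' Sites are sorted by (chrom, pos); positions must be unique per chromosome.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based positions (site coordinate, or bin
#'   start when \code{resolution} is given).
#' @param resolution bin width in bp, or \code{NULL} for unbinned sites.
#' @return a data frame of class \code{"site_index"} with columns
#'   \code{chrom}, \code{pos} and attribute \code{resolution}.
#' @export
site_index <- function(chrom, pos, resolution = NULL) {
  if (length(chrom) != length(pos)) stop("chrom and pos lengths differ")
  pos <- as.integer(pos)
  if (any(pos < 0L)) stop("positions must be nonnegative")
  if (!is.null(resolution)) {
    resolution <- as.integer(resolution)
    if (resolution <= 0L) stop("resolution must be positive")
    if (any(pos %% resolution != 0L)) stop("bin starts must be multiples of the resolution")
  }
  df <- data.frame(chrom = as.character(chrom), pos = pos,
                   stringsAsFactors = FALSE)
  o <- order(df$chrom, df$pos)
  df <- df[o, , drop = FALSE]
  if (anyDuplicated(df)) stop("duplicate positions within a chromosome")
  rownames(df) <- NULL
  attr(df, "resolution") <- resolution
  class(df) <- c("site_index", "data.frame")
  df
}

#' @export
print.site_index <- function(x, ...) {
  res <- attr(x, "resolution")
  cat(sprintf("site index: %d %s on %d chromosome(s)\n", nrow(x),
              if (is.null(res)) "sites" else sprintf("bins (resolution %d bp)", res),
              length(unique(x$chrom))))
  invisible(x)
}

.site_key <- function(chrom, pos) paste(chrom, as.integer(pos), sep = ":")

#' Construct a mark assignment
#'
#' The per-site mark count matrix C: row u is the vector \eqn{C_u} of mark
#' counts at site/bin u.  Unbinned entries are indicators in {0, 1}; binned
#' entries are nonnegative integer counts.
#'
#' @param counts numeric matrix, |sites| x |marks|, nonnegative integers.
#' @param catalog a \code{\link{mark_catalog}} (or character vector).
#' @param index a \code{\link{site_index}} with \code{nrow(counts)} rows.
#' @return an object of class \code{"mark_assignment"}.
#' @export
mark_assignment <- function(counts, catalog, index) {
  counts <- as.matrix(counts)
  if (!inherits(catalog, "mark_catalog")) catalog <- mark_catalog(catalog)
  if (ncol(counts) != length(catalog))
    stop("counts must have one column per catalog mark")
  if (nrow(counts) != nrow(index))
    stop("counts must have one row per index site")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("mark counts must be nonnegative integers")
  binned <- !is.null(attr(index, "resolution"))
  if (!binned && any(counts > 1))
    stop("unbinned mark assignments must be binary")
  colnames(counts) <- as.character(catalog)
  structure(list(counts = counts, catalog = catalog, index = index,
                 binned = binned),
            class = "mark_assignment")
}

#' @export
print.mark_assignment <- function(x, ...) {
  cat(sprintf("mark assignment: %d %s x %d marks, %.1f%% nonzero\n",
              nrow(x$counts), if (x$binned) "bins" else "sites",
              ncol(x$counts), 100 * mean(x$counts > 0)))
  invisible(x)
}

#' Construct contact records
#'
#' The undirected interaction graph G = (V, E).  Pairs are normalized so the
#' (chrom, pos)-lexicographically smaller end comes first; duplicate pairs
#' have their counts summed; self-pairs are rejected.
#'
#' @param chrom1,pos1,chrom2,pos2 endpoint coordinates (0-based).
#' @param count positive integer interaction counts (default 1 each).
#' @param binned logical; whether coordinates are bin starts.
#' @param resolution bin width in bp when \code{binned}.
#' @return a data frame of class \code{"contact_records"} with columns
#'   \code{chrom1, pos1, chrom2, pos2, count}.
#' @export
contact_records <- function(chrom1, pos1, chrom2, pos2, count = NULL,
                            binned = FALSE, resolution = NULL) {
  n <- length(pos1)
  if (is.null(count)) count <- rep(1L, n)
  if (any(count <= 0) || any(count != round(count)))
    stop("contact counts must be positive integers")
  chrom1 <- as.character(chrom1); chrom2 <- as.character(chrom2)
  pos1 <- as.integer(pos1); pos2 <- as.integer(pos2)
  self <- chrom1 == chrom2 & pos1 == pos2
  if (any(self)) {
    warning(sprintf("dropped %d self-pair(s)", sum(self)))
    keep <- !self
    chrom1 <- chrom1[keep]; pos1 <- pos1[keep]
    chrom2 <- chrom2[keep]; pos2 <- pos2[keep]
    count <- count[keep]
  }
  swap <- chrom2 < chrom1 | (chrom1 == chrom2 & pos2 < pos1)
  if (any(swap)) {
    tmpc <- chrom1[swap]; tmpp <- pos1[swap]
    chrom1[swap] <- chrom2[swap]; pos1[swap] <- pos2[swap]
    chrom2[swap] <- tmpc; pos2[swap] <- tmpp
  }
  df <- data.frame(chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2,
                   pos2 = pos2, count = as.integer(count),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    key <- paste(df$chrom1, df$pos1, df$chrom2, df$pos2)
    agg <- rowsum(df$count, key, reorder = FALSE)
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    df$count <- as.integer(agg[match(key[first], rownames(agg)), 1L])
    df <- df[order(df$chrom1, df$pos1, df$chrom2, df$pos2), , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "binned") <- binned
  attr(df, "resolution") <- resolution
  class(df) <- c("contact_records", "data.frame")
  df
}

#' @export
print.contact_records <- function(x, ...) {
  cat(sprintf("contact records: %d pair(s), total count %d%s\n",
              nrow(x), if (nrow(x)) sum(x$count) else 0L,
              if (isTRUE(attr(x, "binned"))) sprintf(" (binned at %s bp)",
                attr(x, "resolution")) else ""))
  invisible(x)
}

#' Construct a mark-pair interaction probability matrix
#'
#' Stores the symmetric matrix X of interaction probabilities between mark
#' pairs, with entries in [0, 1).  The transformed matrix Z with
#' \eqn{x = 1 - e^{-z}} is available through \code{\link{x_to_z}}.
#'
#' @param X symmetric numeric matrix with entries in [0, 1).
#' @param catalog a \code{\link{mark_catalog}} naming rows/columns.
#' @return an object of class \code{"mark_pair_matrix"}.
#' @export
mark_pair_matrix <- function(X, catalog) {
  X <- as.matrix(X)
  if (!inherits(catalog, "mark_catalog")) catalog <- mark_catalog(catalog)
  if (nrow(X) != length(catalog) || ncol(X) != length(catalog))
    stop("X must be |M| x |M| over the catalog")
  if (any(X < 0) || any(X >= 1)) stop("entries of X must lie in [0, 1)")
  if (max(abs(X - t(X))) > 1e-8) stop("X must be symmetric")
  X <- (X + t(X)) / 2
  dimnames(X) <- list(as.character(catalog), as.character(catalog))
  structure(list(X = X, catalog = catalog), class = "mark_pair_matrix")
}

#' @export
print.mark_pair_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("mark-pair interaction probabilities (%d marks):\n",
              length(x$catalog)))
  print(round(x$X, digits))
  invisible(x)
}

#' Transform probabilities to the convex parameterization and back
#'
#' The change of variables \eqn{x = 1 - e^{-z}} maps probabilities in [0, 1)
#' bijectively to nonnegative reals and makes the penalized negative
#' log-likelihood convex in Z.
#'
#' @param X matrix (or \code{mark_pair_matrix}) with entries in [0, 1).
#' @param Z matrix with nonnegative entries.
#' @return the transformed matrix.
#' @export
x_to_z <- function(X) {
  if (inherits(X, "mark_pair_matrix")) X <- X$X
  if (any(X < 0) || any(X >= 1)) stop("x entries must lie in [0, 1)")
  -log1p(-X)
}

#' @rdname x_to_z
#' @export
z_to_x <- function(Z) {
  if (any(Z < 0)) stop("z entries must be nonnegative")
  -expm1(-Z)
}
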