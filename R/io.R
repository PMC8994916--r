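#' Read chromatin-mark peaks from a BED3+ file
#'
#' Parses the first three columns (chrom, start, end) of a BED file; extra
#' columns are ignored.  Intervals are 0-based half-open.
#'
#' @param path path to a tab-separated BED3+ file.
#' @param mark_name mark identifier attached to the result.
#' @return a data frame with columns \code{chrom, start, end}, sorted by
#'   (chrom, start), with attribute \code{mark}.
#' @export
read_peaks_bed <- function(path, mark_name) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "mark") <- mark_name
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 3L)
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                 idx[bad[1]], path))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: non-integer coordinates",
                 idx[bad[1]], path))
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("invalid interval on line %d in %s: end <= start",
                 idx[bad[1]], path))
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mark") <- mark_name
  out
}

#' Read a contact-pair file
#'
#' Whitespace-separated records \code{chromA posA chromB posB [count]} (count
#' defaults to 1).  Pairs are normalized to u < v, duplicates have their
#' counts summed, and self-pairs are dropped with a warning.
#'
#' @param path path to the contact file.
#' @param binned logical; whether the coordinates are bin starts.
#' @param resolution bin width in bp when \code{binned}.
#' @return a \code{\link{contact_records}} object.
#' @export
read_contacts <- function(path, binned = FALSE, resolution = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines))
    return(contact_records(character(), integer(), character(), integer(),
                           binned = binned, resolution = resolution))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- vapply(fields, length, 0L)
  if (any(nf < 4L))
    stop(sprintf("malformed contact line %d: fewer than 4 fields",
                 which(nf < 4L)[1]))
  chrom1 <- vapply(fields, `[[`, "", 1L)
  pos1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  chrom2 <- vapply(fields, `[[`, "", 3L)
  pos2 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  count <- ifelse(nf >= 5L,
                  suppressWarnings(as.numeric(vapply(fields, function(f)
                    if (length(f) >= 5L) f[[5L]] else "1", ""))), 1)
  if (anyNA(pos1) || anyNA(pos2) || anyNA(count))
    stop("malformed contact line: non-numeric coordinate or count")
  if (any(count < 0)) stop("negative contact counts are not allowed")
  contact_records(chrom1, pos1, chrom2, pos2, count,
                  binned = binned, resolution = resolution)
}

#' Write contact records
#'
#' @param contacts a \code{\link{contact_records}} object.
#' @param path output path (5-column whitespace-separated text).
#' @export
write_contacts <- function(contacts, path) {
  df <- as.data.frame(contacts)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map mark peaks to restriction sites
#'
#' A mark belongs to a site when some peak of that mark lies within
#' \code{max_dist} bp of the site position: distance 0 when the position
#' falls inside the (half-open) peak interval, otherwise the gap to the
#' nearest peak edge; inclusive at exactly \code{max_dist}.
#'
#' @param peaks named list of peak data frames (one per mark, as from
#'   \code{\link{read_peaks_bed}}).  Names define the mark catalog order.
#' @param sites an unbinned \code{\link{site_index}}.
#' @param max_dist maximum site-to-peak distance in bp (default 100).
#' @return an unbinned \code{\link{mark_assignment}} with binary entries.
#' @export
map_marks_to_sites <- function(peaks, sites, max_dist = 100L) {
  if (!is.null(attr(sites, "resolution")))
    stop("map_marks_to_sites expects unbinned sites")
  if (max_dist < 0) stop("max_dist must be nonnegative")
  catalog <- mark_catalog(names(peaks))
  counts <- matrix(0L, nrow(sites), length(catalog))
  site_chroms <- unique(sites$chrom)
  for (m in seq_along(peaks)) {
    pk <- peaks[[m]]
    if (!nrow(pk)) next
    missing_chr <- setdiff(unique(pk$chrom), site_chroms)
    if (length(missing_chr))
      warning(sprintf("mark %s: chromosome(s) %s absent from site index; ignored",
                      catalog[m], paste(missing_chr, collapse = ", ")))
    for (chr in intersect(unique(pk$chrom), site_chroms)) {
      su <- which(sites$chrom == chr)
      p <- pk[pk$chrom == chr, , drop = FALSE]
      pos <- sites$pos[su]
      hit <- logical(length(su))
      for (i in seq_len(nrow(p))) {
        # distance 0 inside the peak; gap to the nearest edge coordinate
        # (start or end) outside
        d <- pmax(p$start[i] - pos, pos - p$end[i], 0L)
        hit <- hit | (d <= max_dist)
      }
      counts[su[hit], m] <- 1L
    }
  }
  mark_assignment(counts, catalog, sites)
}

.bin_start <- function(pos, resolution) (pos %/% resolution) * resolution

#' Bin a mark assignment
#'
#' Aggregates site-level indicators into per-bin counts at a fixed
#' resolution: the bin count for mark m is the sum of indicators over member
#' sites.  Bins covering no site with any mark are still retained.
#'
#' @param assignment an unbinned \code{\link{mark_assignment}}.
#' @param resolution bin width in bp.
#' @return a binned \code{\link{mark_assignment}}.
#' @export
bin_assignment <- function(assignment, resolution) {
  if (assignment$binned) stop("assignment is already binned")
  idx <- assignment$index
  bstart <- .bin_start(idx$pos, resolution)
  key <- .site_key(idx$chrom, bstart)
  ukey <- unique(key)
  counts <- rowsum(assignment$counts, key, reorder = FALSE)
  counts <- counts[match(ukey, rownames(counts)), , drop = FALSE]
  parts <- strsplit(ukey, ":", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.integer(vapply(parts, `[[`, "", 2L))
  bidx <- site_index(chrom, start, resolution = resolution)
  o <- match(.site_key(bidx$chrom, bidx$pos), ukey)
  mark_assignment(counts[o, , drop = FALSE], assignment$catalog, bidx)
}

#' Bin contact records
#'
#' Sums member-pair counts into bin pairs; pairs whose two ends fall in the
#' same bin are dropped (the model's likelihood runs over distinct nodes),
#' with the dropped total reported via attribute \code{"intra_bin_count"}.
#'
#' @param contacts unbinned \code{\link{contact_records}}.
#' @param resolution bin width in bp.
#' @return binned \code{\link{contact_records}}.
#' @export
bin_contacts <- function(contacts, resolution) {
  if (isTRUE(attr(contacts, "binned"))) stop("contacts are already binned")
  b1 <- .bin_start(contacts$pos1, resolution)
  b2 <- .bin_start(contacts$pos2, resolution)
  intra <- contacts$chrom1 == contacts$chrom2 & b1 == b2
  dropped <- sum(contacts$count[intra])
  if (dropped > 0)
    message(sprintf("bin_contacts: dropped %d intra-bin contact(s)", dropped))
  keep <- !intra
  out <- contact_records(contacts$chrom1[keep], b1[keep],
                         contacts$chrom2[keep], b2[keep],
                         contacts$count[keep],
                         binned = TRUE, resolution = resolution)
  attr(out, "intra_bin_count") <- dropped
  out
}

#' Binarize binned signal tracks from RPKM values
#'
#' Per bin: average the replicate RPKM values, apply the log(1 + value)
#' transform (natural log), and threshold at 0.5 (inclusive) into {0, 1}.
#' Averaging precedes the transform.
#'
#' @param values numeric matrix of nonnegative per-bin signal, bins x
#'   replicates (a vector is treated as a single replicate).
#' @param threshold binarization cutoff on the log scale (default 0.5).
#' @return integer vector of per-bin indicators.
#' @export
rpkm_log_binarize <- function(values, threshold = 0.5) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("RPKM values must be nonnegative")
  avg <- rowMeans(values)
  as.integer(log1p(avg) >= threshold)
}

#' Serialize / read a mark-pair matrix
#'
#' Labeled tab-separated square matrix with a header row/column of mark
#' names.
#'
#' @param x a \code{\link{mark_pair_matrix}}.
#' @param path file path.
#' @export
write_markpair_matrix <- function(x, path) {
  write.table(format(x$X, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_markpair_matrix
#' @export
read_markpair_matrix <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE))
  mark_pair_matrix(m, mark_catalog(rownames(m)))
}

#' Write / read a mark assignment as a tab-separated table
#'
#' Columns: chrom, pos, then one column per mark.  Binned assignments carry
#' the resolution in a \code{# resolution=} header line.
#'
#' @param assignment a \code{\link{mark_assignment}}.
#' @param path file path.
#' @export
write_assignment <- function(assignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  res <- attr(assignment$index, "resolution")
  if (!is.null(res)) writeLines(sprintf("# resolution=%d", res), con)
  df <- cbind(assignment$index[, c("chrom", "pos")],
              as.data.frame(assignment$counts))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  first <- readLines(path, n = 1L)
  res <- NULL
  skip <- 0L
  if (grepl("^# resolution=", first)) {
    res <- as.integer(sub("^# resolution=", "", first))
    skip <- 1L
  }
  df <- read.table(path, sep = "\t", header = TRUE, skip = skip,
                   check.names = FALSE, stringsAsFactors = FALSE)
  idx <- site_index(df$chrom, df$pos, resolution = res)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  o <- match(.site_key(idx$chrom, idx$pos), .site_key(df$chrom, df$pos))
  mark_assignment(counts[o, , drop = FALSE], mark_catalog(colnames(counts)), idx)
}

#' Read a key-value configuration file
#'
#' Lines of the form \code{key = value} or \code{key value}; '#' starts a
#' comment.  Values are parsed as numbers where possible.
#'
#' @param path file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[= \t]+")[[1]]
    if (length(parts) < 2) stop("malformed config line: ", ln)
    val <- paste(parts[-1], collapse = " ")
    num <- suppressWarnings(as.numeric(val))
    out[[parts[1]]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config named list.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) paste(format(v), collapse = ","), "")),
             path)
  invisible(path)
}
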