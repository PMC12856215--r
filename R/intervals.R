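# Interval algebra on BED-convention coordinates.
#
# Every interval in this package is a row of a plain data.frame with columns
# chrom / start / end / strand / score / name, where start is 0-based
# inclusive, end is 0-based exclusive (half-open, as in BED and in rMATS
# "*_0base" columns), and strand is one of "+", "-", "*" (unstranded).
# Book-ended intervals ([100,200) and [200,300)) share no base.

#' Construct a genomic-interval table
#'
#' Builds the canonical interval data.frame used throughout the package:
#' 0-based half-open coordinates, strand one of `"+"`, `"-"`, `"*"`.
#' Arguments are recycled to a common length and validated.
#'
#' @param chrom Chromosome names (character).
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions (`end > start`).
#' @param strand `"+"`, `"-"` or `"*"` (unstranded). BED `"."` is accepted
#'   and mapped to `"*"`.
#' @param score Optional non-negative score (read count, PCR-duplicate
#'   count); `NA` when absent.
#' @param name Optional label; `NA` when absent.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `score`, `name`.
#' @examples
#' gi("chr1", c(100, 150), c(200, 250), "+")
#' @export
gi <- function(chrom, start, end, strand = "*", score = NA_real_,
               name = NA_character_) {
  n <- max(length(chrom), length(start), length(end), length(strand),
           length(score), length(name))
  if (n == 0) return(empty_gi())
  x <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    score = rep_len(as.numeric(score), n),
    name = rep_len(as.character(name), n),
    stringsAsFactors = FALSE
  )
  x$strand[x$strand %in% c(".", "")] <- "*"
  validate_gi(x)
  x
}

#' Empty interval table
#' @return A zero-row interval data.frame with the canonical columns.
#' @export
empty_gi <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             strand = character(0), score = numeric(0), name = character(0),
             stringsAsFactors = FALSE)
}

#' Validate an interval table
#'
#' Checks the structural invariants: required columns present, `0 <= start
#' < end`, strand in `{+, -, *}`, and (when `sizes` is given) every
#' chromosome known with `end <= length`.
#'
#' @param x Interval data.frame.
#' @param sizes Optional named numeric vector of chromosome lengths.
#' @return `x`, invisibly. Errors name the first offending record.
#' @export
validate_gi <- function(x, sizes = NULL) {
  req <- c("chrom", "start", "end", "strand")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("interval table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!(x$start >= 0 & x$end > x$start))
  if (length(bad))
    stop(sprintf("invalid interval at row %d: %s:%s-%s (need 0 <= start < end)",
                 bad[1], x$chrom[bad[1]], format(x$start[bad[1]]),
                 format(x$end[bad[1]])))
  bad <- which(!x$strand %in% c("+", "-", "*"))
  if (length(bad))
    stop(sprintf("invalid strand '%s' at row %d", x$strand[bad[1]], bad[1]))
  if (!is.null(sizes)) {
    unk <- setdiff(unique(x$chrom), names(sizes))
    if (length(unk))
      stop("unknown chromosome(s): ", paste(unk, collapse = ", "))
    bad <- which(x$end > sizes[x$chrom])
    if (length(bad))
      stop(sprintf("interval at row %d extends past the end of %s",
                   bad[1], x$chrom[bad[1]]))
  }
  invisible(x)
}

#' Sort intervals by chromosome, start, end
#' @param x Interval data.frame.
#' @return `x` reordered; row names dropped.
#' @export
gi_sort <- function(x) {
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

# Vectorised "does each query overlap any subject" on one chromosome
# stratum.  Subjects need not be disjoint: with subjects sorted by start and
# a running max of ends, query [qs,qe) hits iff some subject start < qe and
# the running max end among those subjects exceeds qs.
.any_hit <- function(qs, qe, ss, se) {
  if (length(ss) == 0 || length(qs) == 0) return(rep(FALSE, length(qs)))
  o <- order(ss)
  ss <- ss[o]
  se <- cummax(se[o])
  k <- findInterval(qe - 1, ss)  # integer coords: ss <= qe-1  <=>  ss < qe
  hit <- k >= 1
  hit[hit] <- se[k[hit]] > qs[hit]
  hit
}

#' Merge overlapping and book-ended intervals
#'
#' Returns the sorted, pairwise-disjoint intervals covering exactly the same
#' base set as the input (per strand when `strand_aware`). Intervals whose
#' end equals the next start (book-ended) are merged into one, mirroring the
#' default `bedtools merge` behaviour.
#'
#' @param x Interval data.frame.
#' @param strand_aware Merge within strand; requires concrete strands.
#' @param score_fun Optional function applied to the member scores of each
#'   merged cluster (e.g. `sum` for the FLASH-CLIP PCR-duplicate recipe);
#'   when `NULL` the merged score is `NA`.
#' @return Merged interval data.frame. Without `strand_aware` the output
#'   strand is the members' common strand, or `"*"` if they disagree.
#' @export
gi_merge <- function(x, strand_aware = FALSE, score_fun = NULL) {
  validate_gi(x)
  if (nrow(x) == 0) return(empty_gi())
  if (strand_aware && any(x$strand == "*"))
    stop("strand-aware merge requires a concrete strand for every interval")
  key <- if (strand_aware) paste0(x$chrom, "\r", x$strand) else x$chrom
  o <- order(key, x$start, x$end)
  x <- x[o, , drop = FALSE]
  key <- key[o]
  n <- nrow(x)
  new_stratum <- c(TRUE, key[-1] != key[-n])
  run_max <- stats::ave(x$end, cumsum(new_stratum), FUN = cummax)
  new_cluster <- new_stratum | x$start > c(-Inf, run_max[-n])
  cl <- cumsum(new_cluster)
  first <- which(new_cluster)
  starts <- x$start[first]
  ends <- as.numeric(tapply(x$end, cl, max))
  strand <- vapply(split(x$strand, cl), function(s) {
    u <- unique(s)
    if (length(u) == 1) u else "*"
  }, character(1))
  score <- if (is.null(score_fun)) NA_real_ else
    as.numeric(tapply(x$score, cl, score_fun))
  gi(x$chrom[first], starts, ends, strand, score)
}

#' Test each query interval for overlap with any subject interval
#'
#' Half-open semantics: at least one shared base is required, so book-ended
#' intervals do not overlap. When `strand_aware`, a query on `"+"` matches
#' subjects on `"+"` or `"*"` (and symmetrically); unstranded queries match
#' any subject, so unstranded data is never silently dropped.
#'
#' @param query Interval data.frame.
#' @param subjects Interval data.frame (any order; need not be merged).
#' @param strand_aware Require compatible strands.
#' @return Logical vector, one element per query row.
#' @export
gi_overlaps_any <- function(query, subjects, strand_aware = FALSE) {
  validate_gi(query)
  validate_gi(subjects)
  res <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(subjects) == 0) return(res)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    in_ch <- subjects$chrom == ch
    if (!any(in_ch)) next
    if (!strand_aware) {
      res[qi] <- .any_hit(query$start[qi], query$end[qi],
                          subjects$start[in_ch], subjects$end[in_ch])
    } else {
      for (std in c("+", "-", "*")) {
        qq <- qi[query$strand[qi] == std]
        if (!length(qq)) next
        keep <- in_ch & (if (std == "*") TRUE else
                           subjects$strand %in% c(std, "*"))
        res[qq] <- .any_hit(query$start[qq], query$end[qq],
                            subjects$start[keep], subjects$end[keep])
      }
    }
  }
  res
}

#' Expand intervals by a symmetric flank, clipped to the chromosome
#'
#' The `bedtools slop` operation: each interval grows by `flank` bp on both
#' sides, truncated at position 0 and at the chromosome length.
#'
#' @param x Interval data.frame.
#' @param sizes Named numeric vector of chromosome lengths.
#' @param flank Non-negative flank in bp (default 200, the workflow's
#'   near-splice-site window).
#' @return Expanded interval data.frame; strand, score, name preserved.
#' @export
gi_expand <- function(x, sizes, flank = 200) {
  stopifnot(flank >= 0)
  validate_gi(x)
  if (nrow(x) == 0) return(x)
  unk <- setdiff(unique(x$chrom), names(sizes))
  if (length(unk))
    stop("unknown chromosome(s): ", paste(unk, collapse = ", "))
  x$start <- pmax(0, x$start - flank)
  x$end <- pmin(as.numeric(sizes[x$chrom]), x$end + flank)
  x
}

# Subtract merged sorted y-intervals from merged sorted x-intervals within
# one stratum; returns list(start, end).
.subtract_stratum <- function(xs, xe, ys, ye) {
  out_s <- numeric(0)
  out_e <- numeric(0)
  ny <- length(ys)
  j <- 1
  for (i in seq_along(xs)) {
    cur <- xs[i]
    while (j <= ny && ye[j] <= cur) j <- j + 1
    k <- j
    while (k <= ny && ys[k] < xe[i] && cur < xe[i]) {
      if (ys[k] > cur) {
        out_s <- c(out_s, cur)
        out_e <- c(out_e, ys[k])
      }
      cur <- max(cur, ye[k])
      k <- k + 1
    }
    if (cur < xe[i]) {
      out_s <- c(out_s, cur)
      out_e <- c(out_e, xe[i])
    }
  }
  list(start = out_s, end = out_e)
}

#' Subtract one interval set from another
#'
#' Removes from `x` every base covered by `y`, stratified by exact
#' (chromosome, strand) pairs. Both sets are merged internally first.
#'
#' @param x,y Interval data.frames.
#' @return Interval data.frame covering `bases(x) \ bases(y)`.
#' @export
gi_subtract <- function(x, y) {
  x <- gi_merge(x, strand_aware = !any(x$strand == "*") && nrow(x) > 0)
  y <- gi_merge(y, strand_aware = !any(y$strand == "*") && nrow(y) > 0)
  if (nrow(x) == 0) return(empty_gi())
  if (nrow(y) == 0) return(x)
  pieces <- lapply(split(seq_len(nrow(x)),
                         paste0(x$chrom, "\r", x$strand)), function(ix) {
    ch <- x$chrom[ix[1]]
    st <- x$strand[ix[1]]
    iy <- which(y$chrom == ch & y$strand == st)
    z <- .subtract_stratum(x$start[ix], x$end[ix], y$start[iy], y$end[iy])
    if (length(z$start) == 0) return(empty_gi())
    gi(ch, z$start, z$end, st)
  })
  gi_sort(do.call(rbind, pieces))
}

#' Total number of bases covered by an interval set
#' @param x Interval data.frame.
#' @param strand_aware Count per-strand coverage separately.
#' @return Number of covered bases (double).
#' @export
gi_coverage <- function(x, strand_aware = FALSE) {
  m <- gi_merge(x, strand_aware = strand_aware)
  sum(m$end - m$start)
}
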