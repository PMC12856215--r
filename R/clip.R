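# Replicate-consensus recipes for CLIP interval files.
#
# Three dataset-specific recipes reduce replicated binding-site /
# crosslink-cluster BED files to one consensus set:
#   parclip   - filter clusters by ReadCount, require cross-replicate
#               overlap, merge.
#   hitsclip  - merge crosslink sites within each replicate, require
#               cross-replicate overlap, merge.
#   flashclip - merge within replicate summing PCR-duplicate scores, keep
#               summed score >= threshold, require cross-replicate overlap,
#               merge.
# "Intersect across biological repeats" is read strictly: an interval is
# kept only if it overlaps (>= 1 bp) a retained interval in EVERY other
# replicate.  Overlap is strand-aware whenever strands are present
# (unstranded intervals match either strand).

.auto_strand_aware <- function(x) nrow(x) > 0 && !any(x$strand == "*")

.check_replicates <- function(replicates) {
  if (!is.list(replicates) || length(replicates) < 2)
    stop("consensus requires >= 2 replicates")
  lapply(replicates, validate_gi)
  invisible(replicates)
}

.require_scores <- function(replicates, what) {
  for (i in seq_along(replicates)) {
    x <- replicates[[i]]
    if (nrow(x) > 0 && any(is.na(x$score)))
      stop("replicate ", i, " has sites without a ", what,
           " score; the recipe filters on it")
  }
}

# Keep, from every replicate, the intervals overlapping >= 1 interval in
# each other replicate; return their union (unmerged).
.cross_replicate_keep <- function(replicates) {
  kept <- lapply(seq_along(replicates), function(i) {
    x <- replicates[[i]]
    if (nrow(x) == 0) return(empty_gi())
    keep <- rep(TRUE, nrow(x))
    for (j in seq_along(replicates)[-i]) {
      keep <- keep & gi_overlaps_any(x, replicates[[j]], strand_aware = TRUE)
      if (!any(keep)) break
    }
    x[keep, , drop = FALSE]
  })
  do.call(rbind, kept)
}

.final_merge <- function(x) {
  if (nrow(x) == 0) return(empty_gi())
  gi_merge(x, strand_aware = .auto_strand_aware(x))
}

#' PAR-CLIP consensus: ReadCount filter, cross-replicate overlap, merge
#'
#' Per replicate, binding clusters with `score < min_read_count` are
#' dropped; a cluster is then retained only if it overlaps a retained
#' cluster in every other replicate, and the union of retained clusters is
#' merged. The default threshold keeps a cluster with ReadCount exactly 40.
#'
#' @param replicates List (length >= 2) of interval data.frames whose
#'   `score` column is the cluster ReadCount.
#' @param min_read_count Minimum ReadCount (default 40); the filter keeps
#'   `score >= min_read_count`.
#' @return Merged consensus interval data.frame.
#' @export
consensus_parclip <- function(replicates, min_read_count = 40) {
  .check_replicates(replicates)
  .require_scores(replicates, "ReadCount")
  filtered <- lapply(replicates, function(x)
    x[!is.na(x$score) & x$score >= min_read_count, , drop = FALSE])
  .final_merge(.cross_replicate_keep(filtered))
}

#' HITS-CLIP consensus: merge within replicate, cross-replicate overlap, merge
#'
#' Overlapping (and book-ended) crosslink sites are merged within each
#' replicate; merged intervals present in every replicate (by >= 1 bp
#' overlap) are collected and merged again.
#'
#' @param replicates List (length >= 2) of interval data.frames.
#' @return Merged consensus interval data.frame.
#' @export
consensus_hitsclip <- function(replicates) {
  .check_replicates(replicates)
  merged <- lapply(replicates, function(x)
    gi_merge(x, strand_aware = .auto_strand_aware(x)))
  .final_merge(.cross_replicate_keep(merged))
}

#' FLASH-CLIP consensus: merge summing scores, score filter, overlap, merge
#'
#' Crosslink sites are merged within each replicate with the PCR-duplicate
#' counts in the score column summed over merged members; merged sites with
#' summed score below `min_score` are dropped; survivors intersecting every
#' other replicate are collected and merged. Two touching sites with scores
#' 4 and 6 therefore survive the default threshold as one site of score 10.
#'
#' @param replicates List (length >= 2) of interval data.frames with
#'   PCR-duplicate counts in `score`.
#' @param min_score Minimum summed score (default 10); keeps
#'   `score >= min_score`.
#' @return Merged consensus interval data.frame.
#' @export
consensus_flashclip <- function(replicates, min_score = 10) {
  .check_replicates(replicates)
  .require_scores(replicates, "PCR-duplicate")
  merged <- lapply(replicates, function(x) {
    m <- gi_merge(x, strand_aware = .auto_strand_aware(x), score_fun = sum)
    m[!is.na(m$score) & m$score >= min_score, , drop = FALSE]
  })
  .final_merge(.cross_replicate_keep(merged))
}

#' Run a CLIP consensus recipe by name
#'
#' @param replicates List (length >= 2) of interval data.frames.
#' @param recipe One of `"parclip"`, `"hitsclip"`, `"flashclip"`.
#' @param min_read_count ReadCount threshold for the parclip recipe.
#' @param min_score Summed-score threshold for the flashclip recipe.
#' @return Merged consensus interval data.frame.
#' @export
clip_consensus <- function(replicates,
                           recipe = c("parclip", "hitsclip", "flashclip"),
                           min_read_count = 40, min_score = 10) {
  recipe <- match.arg(recipe)
  switch(recipe,
         parclip = consensus_parclip(replicates, min_read_count),
         hitsclip = consensus_hitsclip(replicates),
         flashclip = consensus_flashclip(replicates, min_score))
}
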