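# Strand-specific, feature-type-preserving permutation test of CLIP
# binding-site enrichment in splicing-associated regions.
#
# Sites are first classified as exonic or intronic against the merged
# feature space (ambiguous sites, touching both, are randomly assigned so
# the original exon/intron composition is preserved).  Each null iteration
# re-places every site uniformly at random within feature intervals of the
# same type, chromosome and strand, never overlapping the original
# coordinates, and recomputes the overlap statistic.  The Monte Carlo
# p-value uses the standard add-one estimator.

#' Classify binding sites as exonic or intronic
#'
#' A site overlapping only exonic space is exonic; only intronic space,
#' intronic. Sites overlapping both are flagged `ambiguous` and randomly
#' assigned to a category with probability equal to the exonic fraction
#' among unambiguous sites (0.5 when there are none), preserving the
#' original composition in expectation. Sites touching neither feature
#' type (intergenic) are excluded from shuffling and returned separately.
#'
#' Consumes the current RNG stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param sites Interval data.frame.
#' @param space A `feature_space` from [build_feature_space()].
#' @return List with `labeled` (sites plus `context` and `ambiguous`
#'   columns) and `excluded` (intergenic sites).
#' @export
classify_sites <- function(sites, space) {
  validate_gi(sites)
  stopifnot(inherits(space, "feature_space"))
  if (nrow(sites) == 0)
    return(list(labeled = cbind(sites, context = character(0),
                                ambiguous = logical(0)),
                excluded = sites))
  in_ex <- gi_overlaps_any(sites, space$exonic, strand_aware = TRUE)
  in_in <- gi_overlaps_any(sites, space$intronic, strand_aware = TRUE)
  context <- rep(NA_character_, nrow(sites))
  context[in_ex & !in_in] <- "exonic"
  context[in_in & !in_ex] <- "intronic"
  ambiguous <- in_ex & in_in
  n_unamb_ex <- sum(in_ex & !in_in)
  n_unamb <- n_unamb_ex + sum(in_in & !in_ex)
  p_ex <- if (n_unamb > 0) n_unamb_ex / n_unamb else 0.5
  if (any(ambiguous))
    context[ambiguous] <- ifelse(stats::runif(sum(ambiguous)) < p_ex,
                                 "exonic", "intronic")
  intergenic <- !in_ex & !in_in
  labeled <- cbind(sites[!intergenic, , drop = FALSE],
                   context = context[!intergenic],
                   ambiguous = ambiguous[!intergenic])
  rownames(labeled) <- NULL
  list(labeled = labeled, excluded = sites[intergenic, , drop = FALSE])
}

# merge plain numeric ranges (half-open), dropping empties
.merge_ranges <- function(s, e) {
  keep <- e > s
  s <- s[keep]
  e <- e[keep]
  if (!length(s)) return(list(start = numeric(0), end = numeric(0)))
  o <- order(s)
  s <- s[o]
  e <- cummax(e[o])
  new <- c(TRUE, s[-1] > e[-length(e)])
  list(start = s[new],
       end = as.numeric(tapply(e, cumsum(new), max)))
}

#' Constrained shuffle of classified sites
#'
#' Re-places every labeled site uniformly at random over all positions that
#' keep its length, chromosome, strand and feature context (fully inside
#' one exonic or intronic interval of its type) and do not overlap
#' `exclude` (normally the original site coordinates). The admissible
#' start space is computed exactly -- candidate feature intervals minus the
#' exclusion footprint, in start-coordinate space -- so the draw is
#' uniform over every valid placement and a forced single slot is always
#' found. Shuffled sites may overlap one another. A site with no
#' admissible placement at all is skipped with a warning and counted in
#' the skip tally.
#'
#' Consumes the current RNG stream.
#'
#' @param labeled Output `$labeled` of [classify_sites()].
#' @param space A `feature_space`.
#' @param exclude Interval data.frame of forbidden coordinates.
#' @return List with `shuffled` (interval data.frame, `context` kept) and
#'   `n_skipped`.
#' @export
constrained_shuffle <- function(labeled, space, exclude = empty_gi()) {
  .shuffle_draw(.shuffle_plan(labeled, space, exclude), labeled)
}

# Precompute the admissible start space per (chromosome, strand, context,
# length) group.  The space is invariant across permutation iterations, so
# the planner runs once and each iteration only draws uniform integers.
.shuffle_plan <- function(labeled, space, exclude = empty_gi()) {
  stopifnot(inherits(space, "feature_space"))
  if (!"context" %in% names(labeled))
    stop("'labeled' must carry a context column (run classify_sites first)")
  n <- nrow(labeled)
  lens <- labeled$end - labeled$start
  has_excl <- nrow(exclude) > 0
  key <- paste(labeled$chrom, labeled$strand, labeled$context, sep = "\r")
  groups <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    ch <- labeled$chrom[idx[1]]
    std <- labeled$strand[idx[1]]
    ctx <- labeled$context[idx[1]]
    pool <- if (ctx == "exonic") space$exonic else space$intronic
    keep <- pool$chrom == ch &
      (std == "*" | pool$strand == "*" | pool$strand == std)
    cs_start <- pool$start[keep]
    cs_end <- pool$end[keep]
    if (has_excl) {
      ek <- exclude$chrom == ch &
        (std == "*" | exclude$strand == "*" | exclude$strand == std)
      ex <- .merge_ranges(exclude$start[ek], exclude$end[ek])
    } else {
      ex <- list(start = numeric(0), end = numeric(0))
    }
    for (L in unique(lens[idx])) {
      ii <- idx[lens[idx] == L]
      # valid starts inside candidates, as half-open ranges [s, e - L + 1)
      allowed <- list(start = cs_start, end = cs_end - L + 1)
      if (length(ex$start)) {
        # a start st collides with exclusion [a, b) iff st in [a-L+1, b);
        # re-merge because the left expansion can make ranges overlap
        exL <- .merge_ranges(ex$start - L + 1, ex$end)
        allowed <- .subtract_stratum(
          allowed$start[allowed$end > allowed$start],
          allowed$end[allowed$end > allowed$start],
          exL$start, exL$end)
      }
      cnt <- pmax(allowed$end - allowed$start, 0)
      tot <- sum(cnt)
      groups[[length(groups) + 1]] <-
        list(idx = ii, starts = allowed$start[cnt > 0],
             bounds = c(0, cumsum(cnt[cnt > 0])), tot = tot)
    }
  }
  list(n = n, lens = lens, groups = groups)
}

# one uniform draw over a precomputed plan; consumes the RNG stream
.shuffle_draw <- function(plan, labeled) {
  out_start <- rep(NA_real_, plan$n)
  for (g in plan$groups) {
    if (g$tot == 0) next  # no admissible placement -> skipped
    r <- floor(stats::runif(length(g$idx)) * g$tot) + 1
    r[r > g$tot] <- g$tot
    j <- findInterval(r - 0.5, g$bounds)
    out_start[g$idx] <- g$starts[j] + (r - g$bounds[j] - 1)
  }
  skipped <- is.na(out_start)
  if (any(skipped))
    warning(sum(skipped),
            " site(s) had no admissible placement and were skipped")
  shuffled <- labeled[!skipped, , drop = FALSE]
  shuffled$start <- out_start[!skipped]
  shuffled$end <- shuffled$start + plan$lens[!skipped]
  rownames(shuffled) <- NULL
  list(shuffled = shuffled, n_skipped = sum(skipped))
}

#' Monte Carlo p-value with add-one correction
#'
#' `p = (1 + #\{null >= observed\}) / (N + 1)`, one-sided for enrichment;
#' ties count as exceedances. An observed value beating all of 500 nulls
#' gives `1/501`.
#'
#' @param observed Observed overlap count.
#' @param null_counts Numeric vector of per-iteration null counts.
#' @return p-value in `(0, 1]`.
#' @export
monte_carlo_p <- function(observed, null_counts) {
  if (length(null_counts) == 0) stop("empty null distribution")
  (1 + sum(null_counts >= observed)) / (length(null_counts) + 1)
}

#' Permutation test of binding-site enrichment at splice-event regions
#'
#' Computes the observed overlap of `sites` with the flank-expanded regions
#' of the significance-filtered `events`, then builds a null distribution
#' by `n_iter` constrained shuffles (classification drawn once per run, or
#' per iteration with `reclassify_each_iter`). The per-iteration statistic
#' is the number of shuffled sites overlapping the regions
#' (`stat = "sites"`, the default) or the number of events hit
#' (`stat = "events"`); the observed statistic is the matching component of
#' the observed overlap and includes intergenic sites, which cannot be
#' shuffled (their count is reported so the discrepancy is visible).
#'
#' Iterations draw independent sub-seeds from the master seed, so the same
#' seed always reproduces the identical result.
#'
#' @param events Significance-filtered splice-event data.frame.
#' @param sites Consensus binding-site interval data.frame.
#' @param space A `feature_space` matching the event annotation.
#' @param sizes Named numeric vector of chromosome lengths.
#' @param n_iter Number of permutation iterations (default 500).
#' @param flank Region expansion in bp (default 200).
#' @param seed Integer master seed; `NULL` continues the current RNG
#'   stream.
#' @param stat Overlap statistic, `"sites"` or `"events"`.
#' @param strand_aware Strand-aware intersection (default `TRUE`).
#' @param reclassify_each_iter Redraw ambiguous-site assignment every
#'   iteration.
#' @return An object of class `enrichment_result`: observed overlap, null
#'   counts, Monte Carlo p-value, fold enrichment (observed over null
#'   mean; `NA` when the null mean is 0), seed and skip tallies.
#' @export
permutation_enrichment <- function(events, sites, space, sizes,
                                   n_iter = 500, flank = 200, seed = NULL,
                                   stat = c("sites", "events"),
                                   strand_aware = TRUE,
                                   reclassify_each_iter = FALSE) {
  stat <- match.arg(stat)
  stopifnot(n_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  obs <- observed_overlap(events, sites, sizes, flank = flank,
                          strand_aware = strand_aware)
  observed_count <- if (stat == "sites") obs$n_sites_hit else
    obs$n_events_hit
  cls <- classify_sites(sites, space)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
  regions <- gi_expand(event_regions(events), sizes, flank)
  plan <- .shuffle_plan(cls$labeled, space, exclude = sites)
  null_counts <- integer(n_iter)
  n_skipped <- 0L
  for (it in seq_len(n_iter)) {
    set.seed(iter_seeds[it])
    if (reclassify_each_iter) {
      lab <- classify_sites(sites, space)$labeled
      sh <- constrained_shuffle(lab, space, exclude = sites)
    } else {
      lab <- cls$labeled
      sh <- .shuffle_draw(plan, lab)
    }
    if (nrow(lab) > 0 && nrow(sh$shuffled) == 0)
      stop("all sites were skipped in iteration ", it,
           "; the feature space cannot host the site lengths")
    n_skipped <- n_skipped + sh$n_skipped
    null_counts[it] <- if (stat == "sites") {
      sum(gi_overlaps_any(sh$shuffled, regions,
                          strand_aware = strand_aware))
    } else {
      hit <- gi_overlaps_any(regions, sh$shuffled,
                             strand_aware = strand_aware)
      length(unique(regions$name[hit]))
    }
  }
  res <- list(observed = obs, statistic = stat,
              observed_count = observed_count,
              null_counts = null_counts, n_iter = n_iter,
              p_value = monte_carlo_p(observed_count, null_counts),
              fold_enrichment = if (mean(null_counts) > 0)
                observed_count / mean(null_counts) else NA_real_,
              seed = if (is.null(seed)) NA_integer_ else seed,
              flank = flank,
              n_intergenic = nrow(cls$excluded),
              n_skipped = n_skipped)
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "permutation enrichment (%s statistic, %d iterations)\n", x$statistic,
    x$n_iter))
  cat(sprintf("  observed: %d   null mean: %.2f (sd %.2f)\n",
              x$observed_count, mean(x$null_counts),
              stats::sd(x$null_counts)))
  cat(sprintf("  fold enrichment: %s   Monte Carlo p = %.4g\n",
              ifelse(is.na(x$fold_enrichment), "NA",
                     sprintf("%.2f", x$fold_enrichment)), x$p_value))
  if (x$n_intergenic > 0 || x$n_skipped > 0)
    cat(sprintf("  intergenic sites kept in observed only: %d; skipped placements: %d\n",
                x$n_intergenic, x$n_skipped))
  invisible(x)
}

#' Serialize an enrichment result to JSON
#'
#' Writes observed statistics, the null summary and full null counts, the
#' p-value, fold enrichment, seed and skip tallies. Two runs with the same
#' seed produce byte-identical files.
#'
#' @param x An `enrichment_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_json <- function(x, path) {
  stopifnot(inherits(x, "enrichment_result"))
  obj <- list(
    statistic = x$statistic,
    observed = unclass(x$observed),
    observed_count = x$observed_count,
    n_iter = x$n_iter,
    null_mean = mean(x$null_counts),
    null_sd = stats::sd(x$null_counts),
    null_quantiles = as.list(stats::quantile(
      x$null_counts, c(0.025, 0.25, 0.5, 0.75, 0.975), names = TRUE)),
    null_counts = x$null_counts,
    p_value = x$p_value,
    fold_enrichment = x$fold_enrichment,
    seed = x$seed,
    flank = x$flank,
    n_intergenic = x$n_intergenic,
    n_skipped = x$n_skipped)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
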