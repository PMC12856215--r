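# rMATS-style differential alternative-splicing events.
#
# Events live in a data.frame with one row per event:
#   event_id, event_type (SE/RI/MXE/A5SS/A3SS), gene_id, chrom, strand,
#   t1_start/t1_end, t2_start/t2_end   target coordinates (skipped exon;
#                                      retained intron; the two MXE exons;
#                                      long/short splice-site exons),
#   f1_start/f1_end, f2_start/f2_end   flanking exon coordinates,
#   psi1, psi2                         mean inclusion levels per group,
#   delta_psi                          psi1 - psi2 (IncLevelDifference),
#   p_value, fdr                       per-event significance,
#   inc1, inc2                         raw comma-separated IncLevel lists.
# Coordinates are 0-based half-open, directly as in the rMATS "*_0base"
# columns.  Unused coordinate slots are NA (e.g. t2 for SE).

EVENT_TYPES <- c("SE", "RI", "MXE", "A5SS", "A3SS")

.event_cols <- c("event_id", "event_type", "gene_id", "chrom", "strand",
                 "t1_start", "t1_end", "t2_start", "t2_end",
                 "f1_start", "f1_end", "f2_start", "f2_end",
                 "psi1", "psi2", "delta_psi", "p_value", "fdr",
                 "inc1", "inc2")

# which coordinate slots each event type must populate
.required_slots <- list(
  SE = c("t1", "f1", "f2"),
  RI = c("t1", "f1", "f2"),
  MXE = c("t1", "t2", "f1", "f2"),
  A5SS = c("t1", "t2", "f1"),
  A3SS = c("t1", "t2", "f1")
)

#' Validate a splice-event table
#'
#' Checks event types, inclusion levels in \[0, 1\], consistency of
#' `delta_psi` with the group means, concrete strands, and that the
#' coordinate slots required by each event type are populated and valid.
#'
#' @param events Splice-event data.frame.
#' @return `events`, invisibly.
#' @export
validate_events <- function(events) {
  miss <- setdiff(.event_cols, names(events))
  if (length(miss))
    stop("event table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(events) == 0) return(invisible(events))
  bad <- which(!events$event_type %in% EVENT_TYPES)
  if (length(bad))
    stop("unknown event type '", events$event_type[bad[1]], "' at row ",
         bad[1])
  if (any(!events$strand %in% c("+", "-")))
    stop("event strands must be '+' or '-'")
  for (v in c("psi1", "psi2")) {
    bad <- which(!is.na(events[[v]]) &
                   (events[[v]] < 0 | events[[v]] > 1))
    if (length(bad))
      stop(v, " outside [0,1] at row ", bad[1])
  }
  dd <- abs(events$delta_psi - (events$psi1 - events$psi2))
  if (any(dd > 0.02, na.rm = TRUE))
    warning("delta_psi disagrees with psi1 - psi2 beyond rounding for ",
            sum(dd > 0.02, na.rm = TRUE), " event(s)")
  for (i in seq_len(nrow(events))) {
    for (slot in .required_slots[[events$event_type[i]]]) {
      s <- events[[paste0(slot, "_start")]][i]
      e <- events[[paste0(slot, "_end")]][i]
      if (is.na(s) || is.na(e) || s < 0 || e <= s)
        stop("event ", events$event_id[i], " (", events$event_type[i],
             ") lacks a valid '", slot, "' coordinate pair")
    }
  }
  invisible(events)
}

#' Mean of a comma-separated rMATS IncLevel replicate list
#'
#' `"0.5,NA,0.7"` gives `0.6`: missing replicates are skipped, and a list
#' with no usable replicate gives `NA`.
#'
#' @param s Character vector of comma-separated inclusion-level lists.
#' @return Numeric vector of per-list means.
#' @export
parse_inc_levels <- function(s) {
  vapply(strsplit(as.character(s), ","), function(v) {
    v <- suppressWarnings(as.numeric(v))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

# per-dialect coordinate column names
.rmats_coord_cols <- list(
  SE = c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
         "downstreamES", "downstreamEE"),
  RI = c("riExonStart_0base", "riExonEnd", "upstreamES", "upstreamEE",
         "downstreamES", "downstreamEE"),
  MXE = c("1stExonStart_0base", "1stExonEnd", "2ndExonStart_0base",
          "2ndExonEnd", "upstreamES", "upstreamEE", "downstreamES",
          "downstreamEE"),
  A5SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  A3SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE")
)

#' Read an rMATS result table
#'
#' Parses one tab-separated rMATS output file (JC/JCEC layout) of the given
#' event type into the package's splice-event data.frame. Group mean
#' inclusion levels are computed from the comma-separated `IncLevel1` /
#' `IncLevel2` replicate lists with missing (`NA`) entries skipped;
#' coordinates are taken as 0-based half-open exactly as stored.
#'
#' For alternative splice-site events the long exon (variable plus common
#' region) is kept as the first target coordinate and the short (common)
#' exon as the second; region extraction uses the long exon together with
#' the flanking exon.
#'
#' @param path Path to the rMATS table.
#' @param event_type One of `"SE"`, `"RI"`, `"MXE"`, `"A5SS"`, `"A3SS"`.
#' @return Splice-event data.frame (see [validate_events()]).
#' @export
read_rmats_table <- function(path, event_type = c("SE", "RI", "MXE",
                                                  "A5SS", "A3SS")) {
  event_type <- match.arg(event_type)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  req <- c("GeneID", "chr", "strand", "PValue", "FDR", "IncLevel1",
           "IncLevel2", "IncLevelDifference",
           .rmats_coord_cols[[event_type]])
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("rMATS ", event_type, " table lacks column(s): ",
         paste(miss, collapse = ", "))
  fdr <- suppressWarnings(as.numeric(tab$FDR))
  if (any(is.na(fdr) & !is.na(tab$FDR) & tab$FDR != "NA"))
    stop("non-numeric FDR value in ", path)
  n <- nrow(tab)
  num <- function(col) as.numeric(tab[[col]])
  co <- switch(event_type,
    SE = list(t1s = num("exonStart_0base"), t1e = num("exonEnd"),
              t2s = rep(NA_real_, n), t2e = rep(NA_real_, n),
              f1s = num("upstreamES"), f1e = num("upstreamEE"),
              f2s = num("downstreamES"), f2e = num("downstreamEE")),
    RI = list(t1s = num("upstreamEE"), t1e = num("downstreamES"),
              t2s = rep(NA_real_, n), t2e = rep(NA_real_, n),
              f1s = num("upstreamES"), f1e = num("upstreamEE"),
              f2s = num("downstreamES"), f2e = num("downstreamEE")),
    MXE = list(t1s = num("1stExonStart_0base"), t1e = num("1stExonEnd"),
               t2s = num("2ndExonStart_0base"), t2e = num("2ndExonEnd"),
               f1s = num("upstreamES"), f1e = num("upstreamEE"),
               f2s = num("downstreamES"), f2e = num("downstreamEE")),
    list(t1s = num("longExonStart_0base"), t1e = num("longExonEnd"),
         t2s = num("shortES"), t2e = num("shortEE"),
         f1s = num("flankingES"), f1e = num("flankingEE"),
         f2s = rep(NA_real_, n), f2e = rep(NA_real_, n)))
  id <- if ("ID" %in% names(tab)) as.character(tab$ID) else
    as.character(seq_len(n))
  events <- data.frame(
    event_id = paste0(event_type, "_", id),
    event_type = rep(event_type, n),
    gene_id = as.character(tab$GeneID),
    chrom = as.character(tab$chr),
    strand = as.character(tab$strand),
    t1_start = co$t1s, t1_end = co$t1e,
    t2_start = co$t2s, t2_end = co$t2e,
    f1_start = co$f1s, f1_end = co$f1e,
    f2_start = co$f2s, f2_end = co$f2e,
    psi1 = parse_inc_levels(tab$IncLevel1),
    psi2 = parse_inc_levels(tab$IncLevel2),
    delta_psi = as.numeric(tab$IncLevelDifference),
    p_value = suppressWarnings(as.numeric(tab$PValue)),
    fdr = fdr,
    inc1 = as.character(tab$IncLevel1),
    inc2 = as.character(tab$IncLevel2),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  validate_events(events)
  events
}

#' Write a splice-event table in the rMATS dialect
#'
#' Inverse of [read_rmats_table()]: emits one tab-separated file in the
#' coordinate-column layout of the events' type. All events must share one
#' type.
#'
#' @param events Splice-event data.frame of a single event type.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rmats_table <- function(events, path) {
  validate_events(events)
  ty <- unique(events$event_type)
  if (length(ty) != 1)
    stop("write_rmats_table needs a single event type, got: ",
         paste(ty, collapse = ", "))
  n <- nrow(events)
  co <- switch(ty,
    SE = data.frame(`exonStart_0base` = events$t1_start,
                    exonEnd = events$t1_end,
                    upstreamES = events$f1_start,
                    upstreamEE = events$f1_end,
                    downstreamES = events$f2_start,
                    downstreamEE = events$f2_end, check.names = FALSE),
    RI = data.frame(`riExonStart_0base` = events$f1_start,
                    riExonEnd = events$f2_end,
                    upstreamES = events$f1_start,
                    upstreamEE = events$f1_end,
                    downstreamES = events$f2_start,
                    downstreamEE = events$f2_end, check.names = FALSE),
    MXE = data.frame(`1stExonStart_0base` = events$t1_start,
                     `1stExonEnd` = events$t1_end,
                     `2ndExonStart_0base` = events$t2_start,
                     `2ndExonEnd` = events$t2_end,
                     upstreamES = events$f1_start,
                     upstreamEE = events$f1_end,
                     downstreamES = events$f2_start,
                     downstreamEE = events$f2_end, check.names = FALSE),
    data.frame(`longExonStart_0base` = events$t1_start,
               longExonEnd = events$t1_end,
               shortES = events$t2_start, shortEE = events$t2_end,
               flankingES = events$f1_start, flankingEE = events$f1_end,
               check.names = FALSE))
  inc1 <- ifelse(is.na(events$inc1), as.character(events$psi1), events$inc1)
  inc2 <- ifelse(is.na(events$inc2), as.character(events$psi2), events$inc2)
  out <- cbind(
    data.frame(ID = sub(paste0("^", ty, "_"), "", events$event_id),
               GeneID = events$gene_id, geneSymbol = events$gene_id,
               chr = events$chrom, strand = events$strand,
               check.names = FALSE),
    co,
    data.frame(PValue = events$p_value, FDR = events$fdr,
               IncLevel1 = inc1, IncLevel2 = inc2,
               IncLevelDifference = events$delta_psi, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Significance-filter splice events
#'
#' Keeps events with `fdr < max_fdr` and `|delta_psi| > min_abs_dpsi`, both
#' strict, so an event with FDR exactly 0.05 (or |dPSI| exactly at the
#' threshold) is excluded. `min_abs_dpsi = 0` reproduces the FDR-only lists
#' used for set logic; `min_abs_dpsi = 0.1` the stricter heatmap filter.
#'
#' @param events Splice-event data.frame.
#' @param max_fdr FDR threshold (default 0.05).
#' @param min_abs_dpsi Absolute inclusion-difference threshold (default 0).
#' @return Filtered splice-event data.frame.
#' @export
filter_events <- function(events, max_fdr = 0.05, min_abs_dpsi = 0) {
  stopifnot(max_fdr >= 0, max_fdr <= 1, min_abs_dpsi >= 0,
            min_abs_dpsi <= 1)
  keep <- !is.na(events$fdr) & events$fdr < max_fdr &
    !is.na(events$delta_psi) & abs(events$delta_psi) > min_abs_dpsi
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Splicing-associated regions of each event
#'
#' Returns, per event, the target and flanking intervals whose
#' neighbourhood defines the binding-site overlap test: SE gives the
#' skipped exon plus both flanking exons; RI the retained intron plus both
#' flanking exons; MXE both alternative exons plus both flanks; A5SS/A3SS
#' the long (variable + common region) exon plus the flanking exon.
#' Duplicate intervals within an event are removed.
#'
#' @param events Splice-event data.frame.
#' @return Interval data.frame with `name` set to the event id.
#' @export
event_regions <- function(events) {
  validate_events(events)
  if (nrow(events) == 0) return(empty_gi())
  slot_map <- list(SE = c("t1", "f1", "f2"), RI = c("t1", "f1", "f2"),
                   MXE = c("t1", "t2", "f1", "f2"),
                   A5SS = c("t1", "f1"), A3SS = c("t1", "f1"))
  rows <- lapply(seq_len(nrow(events)), function(i) {
    slots <- slot_map[[events$event_type[i]]]
    s <- vapply(slots, function(k) events[[paste0(k, "_start")]][i],
                numeric(1))
    e <- vapply(slots, function(k) events[[paste0(k, "_end")]][i],
                numeric(1))
    keep <- !duplicated(paste(s, e))
    gi(events$chrom[i], s[keep], e[keep], events$strand[i],
       name = events$event_id[i])
  })
  do.call(rbind, rows)
}

#' Observed overlap between splice-event regions and binding sites
#'
#' Each event's regions are expanded by `flank` bp (clipped to the
#' chromosome) and treated as one merged footprint. `n_events_hit` counts
#' events whose footprint overlaps at least one site; `n_sites_hit` counts
#' sites overlapping the union of all footprints. With `strand_aware`,
#' unstranded sites match either strand.
#'
#' @param events Significance-filtered splice-event data.frame.
#' @param sites Interval data.frame of consensus binding sites.
#' @param sizes Named numeric vector of chromosome lengths.
#' @param flank Expansion in bp (default 200).
#' @param strand_aware Require compatible strands (default `TRUE`).
#' @return An object of class `observed_overlap`: list with `n_events`,
#'   `n_events_hit`, `fraction_events_hit`, `n_sites`, `n_sites_hit`.
#' @export
observed_overlap <- function(events, sites, sizes, flank = 200,
                             strand_aware = TRUE) {
  validate_gi(sites)
  regions <- event_regions(events)
  regions <- gi_expand(regions, sizes, flank)
  n_events <- nrow(events)
  if (n_events == 0 || nrow(sites) == 0) {
    res <- list(n_events = n_events, n_events_hit = 0L,
                fraction_events_hit = if (n_events) 0 else NA_real_,
                n_sites = nrow(sites), n_sites_hit = 0L)
    class(res) <- "observed_overlap"
    return(res)
  }
  region_hit <- gi_overlaps_any(regions, sites, strand_aware = strand_aware)
  events_hit <- unique(regions$name[region_hit])
  site_hit <- gi_overlaps_any(sites, regions, strand_aware = strand_aware)
  res <- list(n_events = n_events,
              n_events_hit = length(events_hit),
              fraction_events_hit = length(events_hit) / n_events,
              n_sites = nrow(sites),
              n_sites_hit = sum(site_hit))
  class(res) <- "observed_overlap"
  res
}

#' @export
print.observed_overlap <- function(x, ...) {
  cat(sprintf("observed overlap: %d/%d events hit (%.1f%%), %d/%d sites hit\n",
              x$n_events_hit, x$n_events, 100 * x$fraction_events_hit,
              x$n_sites_hit, x$n_sites))
  invisible(x)
}

#' Count events per splicing class
#'
#' @param events Splice-event data.frame.
#' @return Named integer vector over SE, RI, MXE, A5SS, A3SS (zero for
#'   absent classes); the counts sum to `nrow(events)`.
#' @export
event_type_counts <- function(events) {
  tab <- table(factor(events$event_type, levels = EVENT_TYPES))
  stats::setNames(as.integer(tab), EVENT_TYPES)
}

#' Canonical key identifying an event across contrasts
#'
#' Combines type, chromosome, strand and the target coordinates, the
#' granularity at which event-level Venn comparisons are made.
#'
#' @param events Splice-event data.frame.
#' @return Character vector of keys, one per event.
#' @export
event_key <- function(events) {
  paste(events$event_type, events$chrom, events$strand,
        events$t1_start, events$t1_end,
        ifelse(is.na(events$t2_start), "", events$t2_start),
        ifelse(is.na(events$t2_end), "", events$t2_end), sep = ":")
}

#' Event-by-contrast matrix of inclusion-level differences
#'
#' Rows are the union of event keys over all contrasts; a cell holds the
#' event's `delta_psi` in that contrast, or `NA` where the event is absent
#' (absence is not zero change).
#'
#' @param contrast_events Named list of splice-event data.frames, one per
#'   contrast.
#' @return Numeric matrix, rownames = event keys, colnames = contrasts.
#' @export
delta_psi_matrix <- function(contrast_events) {
  stopifnot(is.list(contrast_events), length(contrast_events) >= 1,
            !is.null(names(contrast_events)))
  keys <- lapply(contrast_events, event_key)
  for (nm in names(contrast_events)) {
    if (anyDuplicated(keys[[nm]]))
      stop("duplicate event key within contrast '", nm, "'")
  }
  all_keys <- sort(unique(unlist(keys)))
  m <- matrix(NA_real_, nrow = length(all_keys),
              ncol = length(contrast_events),
              dimnames = list(all_keys, names(contrast_events)))
  for (nm in names(contrast_events)) {
    m[keys[[nm]], nm] <- contrast_events[[nm]]$delta_psi
  }
  m
}
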