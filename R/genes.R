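# Gene models and the exon/intron feature space.
#
# A gene model is an exon table: one row per exon with gene_id / chrom /
# strand / start / end.  The feature space derived from it is the placement
# domain of the permutation test: merged exonic intervals plus merged
# intronic intervals (per-gene gaps between consecutive exons), made
# disjoint by giving exons precedence wherever overlapping genes disagree.

#' Validate a gene-model exon table
#'
#' Requires every gene to have at least one valid exon, a single chromosome
#' and a single concrete strand; exons of one gene must be pairwise
#' disjoint (book-ended exons are allowed to touch but not overlap).
#'
#' @param genes Gene-model data.frame (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`).
#' @return `genes`, invisibly; errors name the offending gene.
#' @export
validate_genes <- function(genes) {
  req <- c("gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(genes))
  if (length(miss))
    stop("gene table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(genes) == 0) return(invisible(genes))
  validate_gi(genes[, c("chrom", "start", "end", "strand")])
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene strands must be '+' or '-'")
  for (g in split(genes, genes$gene_id)) {
    id <- g$gene_id[1]
    if (length(unique(g$chrom)) > 1 || length(unique(g$strand)) > 1)
      stop("gene ", id, " spans multiple chromosomes or strands")
    o <- order(g$start)
    if (any(g$start[o][-1] < g$end[o][-nrow(g)]))
      stop("gene ", id, " has overlapping exons")
  }
  invisible(genes)
}

#' Transcript start site of each gene
#'
#' The TSS is the first exon start on the `+` strand and the last exon end
#' minus one on the `-` strand (a 0-based position).
#'
#' @param genes Gene-model data.frame.
#' @return data.frame with `gene_id`, `chrom`, `strand`, `tss`.
#' @export
gene_tss <- function(genes) {
  validate_genes(genes)
  if (nrow(genes) == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), tss = numeric(0)))
  out <- do.call(rbind, lapply(split(genes, genes$gene_id), function(g) {
    tss <- if (g$strand[1] == "+") min(g$start) else max(g$end) - 1
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1], tss = tss, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Build the exon/intron feature space
#'
#' Merges all exons per (chromosome, strand); introns are the gaps between
#' consecutive exons of each gene, merged and then stripped of any base
#' that is also exonic on the same (chromosome, strand). The two sets are
#' therefore disjoint, which the constrained shuffle relies on.
#'
#' @param genes Gene-model data.frame.
#' @return An object of class `feature_space`: a list with merged interval
#'   tables `exonic` and `intronic`.
#' @export
build_feature_space <- function(genes) {
  validate_genes(genes)
  if (nrow(genes) == 0) {
    fs <- list(exonic = empty_gi(), intronic = empty_gi())
    class(fs) <- "feature_space"
    return(fs)
  }
  exonic <- gi_merge(gi(genes$chrom, genes$start, genes$end, genes$strand),
                     strand_aware = TRUE)
  introns <- lapply(split(genes, genes$gene_id), function(g) {
    m <- gi_merge(gi(g$chrom, g$start, g$end, g$strand), strand_aware = TRUE)
    if (nrow(m) < 2) return(empty_gi())
    gi(m$chrom[1], m$end[-nrow(m)], m$start[-1], m$strand[1])
  })
  introns <- do.call(rbind, introns)
  intronic <- if (is.null(introns) || nrow(introns) == 0) empty_gi() else
    gi_subtract(gi_merge(introns, strand_aware = TRUE), exonic)
  fs <- list(exonic = gi_sort(exonic), intronic = gi_sort(intronic))
  class(fs) <- "feature_space"
  fs
}

#' @export
print.feature_space <- function(x, ...) {
  cat("feature space:",
      nrow(x$exonic), "exonic intervals (",
      format(sum(x$exonic$end - x$exonic$start), big.mark = ","), "bp ),",
      nrow(x$intronic), "intronic intervals (",
      format(sum(x$intronic$end - x$intronic$start), big.mark = ","),
      "bp )\n")
  invisible(x)
}

#' Genes whose promoter window contains a peak
#'
#' A gene is reported when any peak overlaps the window
#' `[tss - half_width, tss + half_width)` on the gene's chromosome. Windows
#' are treated as unstranded because ChIP peaks carry no strand.
#'
#' @param peaks Interval data.frame of peaks.
#' @param genes Gene-model data.frame.
#' @param half_width Window half-width in bp (default 500, i.e. a 1000-bp
#'   region centred on the TSS).
#' @return Sorted character vector of gene ids.
#' @export
promoter_targets <- function(peaks, genes, half_width = 500) {
  stopifnot(half_width >= 0)
  validate_gi(peaks)
  if (half_width == 0) return(character(0))  # zero-width window holds no base
  tss <- gene_tss(genes)
  if (nrow(tss) == 0 || nrow(peaks) == 0) return(character(0))
  win <- gi(tss$chrom, pmax(0, tss$tss - half_width),
            tss$tss + half_width, name = tss$gene_id)
  hit <- gi_overlaps_any(win, peaks, strand_aware = FALSE)
  sort(unique(win$name[hit]))
}
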