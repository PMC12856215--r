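# Condition-dependency set logic over differential-expression and
# differential-splicing result sets: significance filtering of DESeq2-style
# tables, Venn partitions across contrasts, "unique to one contrast"
# co-dependency sets, and DEG-versus-AS gene classification.

#' Read a DESeq2-style differential-expression table
#'
#' Tab-separated with header columns `gene_id` (or `gene`),
#' `log2FoldChange`, `pvalue`, `padj`.
#'
#' @param path Path to the table.
#' @return data.frame with `gene_id`, `log2fc`, `p_value`, `padj`.
#' @export
read_deg_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab) && "gene" %in% names(tab))
    names(tab)[names(tab) == "gene"] <- "gene_id"
  req <- c("gene_id", "log2FoldChange", "pvalue", "padj")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("DEG table lacks column(s): ", paste(miss, collapse = ", "))
  data.frame(gene_id = as.character(tab$gene_id),
             log2fc = as.numeric(tab$log2FoldChange),
             p_value = as.numeric(tab$pvalue),
             padj = as.numeric(tab$padj),
             stringsAsFactors = FALSE)
}

#' Significant differentially expressed genes
#'
#' Keeps genes with `padj < max_padj` and `|log2fc| > min_abs_log2fc`
#' (both strict, so padj exactly 0.05 or |log2FC| exactly 0.58 is
#' excluded). `NA` adjusted p-values (independent-filtering casualties in
#' DESeq2 output) are never significant.
#'
#' @param records DEG data.frame (`gene_id`, `log2fc`, `padj`).
#' @param max_padj Adjusted-p threshold (default 0.05).
#' @param min_abs_log2fc Absolute log2 fold-change threshold (default
#'   0.58, i.e. a 1.5-fold change).
#' @return Character vector of significant gene ids.
#' @export
filter_degs <- function(records, max_padj = 0.05, min_abs_log2fc = 0.58) {
  stopifnot(max_padj >= 0, min_abs_log2fc >= 0)
  if (anyDuplicated(records$gene_id))
    stop("duplicate gene_id in DEG table: ",
         records$gene_id[duplicated(records$gene_id)][1])
  keep <- !is.na(records$padj) & records$padj < max_padj &
    !is.na(records$log2fc) & abs(records$log2fc) > min_abs_log2fc
  records$gene_id[keep]
}

#' Venn partition of named identifier sets
#'
#' Assigns every identifier to exactly one of the `2^k - 1` membership
#' signatures. Signatures are named by the member sets joined with `&`
#' (e.g. `"A&B"`); all signatures are present in the output, empty ones as
#' zero-length vectors, so the regions are pairwise disjoint and their
#' union is the union of the inputs.
#'
#' @param sets Named list (length >= 2) of character vectors.
#' @return Named list of character vectors, one per signature.
#' @export
venn_partition <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)),
            all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  ids <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) ids %in% s,
                   logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1)
  sig_of <- apply(member, 1, function(m)
    paste(names(sets)[m], collapse = "&"))
  k <- length(sets)
  signatures <- unlist(lapply(seq_len(k), function(m) {
    combn(names(sets), m, paste, collapse = "&")
  }))
  out <- lapply(stats::setNames(signatures, signatures), function(sg)
    sort(ids[sig_of == sg]))
  out
}

#' Identifiers unique to one contrast
#'
#' The co-dependency selection: members of `sets[[target]]` found in no
#' other contrast's set (events or genes regulated only when both
#' perturbations coincide).
#'
#' @param sets Named list of character vectors.
#' @param target Name of the contrast of interest.
#' @return Sorted character vector.
#' @export
codependent_set <- function(sets, target) {
  if (!target %in% names(sets))
    stop("unknown contrast '", target, "'; available: ",
         paste(names(sets), collapse = ", "))
  others <- unique(unlist(sets[setdiff(names(sets), target)],
                          use.names = FALSE))
  sort(setdiff(unique(sets[[target]]), others))
}

#' Classify genes as DEG-only, AS-only, or both
#'
#' Partitions the union of a differential-expression gene set and an
#' alternative-splicing gene set and reports the percentage regulated via
#' one mechanism only versus via both; the two percentages sum to 100.
#'
#' @param deg_genes Character vector of DEG gene ids.
#' @param as_genes Character vector of differentially spliced gene ids.
#' @return List with `deg_only`, `as_only`, `both`, `pct_non_overlapping`,
#'   `pct_both`.
#' @export
deg_as_overlap <- function(deg_genes, as_genes) {
  deg_genes <- unique(deg_genes)
  as_genes <- unique(as_genes)
  if (length(deg_genes) == 0 && length(as_genes) == 0)
    stop("both gene sets are empty")
  both <- sort(intersect(deg_genes, as_genes))
  deg_only <- sort(setdiff(deg_genes, as_genes))
  as_only <- sort(setdiff(as_genes, deg_genes))
  n_union <- length(both) + length(deg_only) + length(as_only)
  list(deg_only = deg_only, as_only = as_only, both = both,
       pct_non_overlapping = 100 * (length(deg_only) + length(as_only)) /
         n_union,
       pct_both = 100 * length(both) / n_union)
}

#' Source genes of significant splice events
#'
#' @param events Splice-event data.frame (already significance-filtered).
#' @return Sorted character vector of distinct gene ids.
#' @export
as_gene_set <- function(events) {
  if (nrow(events) == 0) return(character(0))
  bad <- which(is.na(events$gene_id) | !nzchar(events$gene_id))
  if (length(bad))
    stop("event ", events$event_id[bad[1]], " lacks a gene_id")
  sort(unique(events$gene_id))
}
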