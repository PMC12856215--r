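# Readers and writers for the small tab-separated formats the pipeline
# exchanges: BED3-6, chromosome sizes, and the minimal exon table used for
# gene models.  All coordinates stay 0-based half-open on disk and in
# memory, so ingest is a straight copy.

#' Read a BED file (3-6 columns)
#'
#' Tolerates 3 to 6 tab-separated columns (chrom, start, end, name, score,
#' strand). Lines starting with `#`, `track` or `browser` are skipped.
#' Missing name/score are `NA`; a `.` or absent strand becomes `"*"`.
#'
#' @param path Path to a BED file.
#' @return Interval data.frame (see [gi()]).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) &
                   nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_gi())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 3))
    stop("BED line with fewer than 3 fields: ", lines[which(ncol < 3)[1]])
  pick <- function(i) vapply(parts, function(p)
    if (length(p) >= i) p[i] else NA_character_, character(1))
  score <- suppressWarnings(as.numeric(pick(5)))
  strand <- pick(6)
  strand[is.na(strand)] <- "*"
  name <- pick(4)
  name[name %in% "."] <- NA_character_
  gi(pick(1), as.numeric(pick(2)), as.numeric(pick(3)), strand, score, name)
}

#' Write a BED6 file
#' @param x Interval data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_gi(x)
  out <- data.frame(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = ifelse(is.na(x$name), ".", x$name),
    score = ifelse(is.na(x$score), ".",
                   format(x$score, scientific = FALSE, trim = TRUE)),
    strand = ifelse(x$strand == "*", ".", x$strand),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromosome-sizes file
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path Path to the file.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (any(tab$length < 1)) stop("chromosome lengths must be >= 1")
  stats::setNames(tab$length, tab$chrom)
}

#' Write a chromosome-sizes file
#' @param sizes Named numeric vector of lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(
    data.frame(names(sizes),
               format(sizes, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-model exon table
#'
#' The minimal gene-model format: tab-separated with header columns
#' `gene_id`, `chrom`, `strand`, `exon_start`, `exon_end` (0-based
#' half-open), one row per exon.
#'
#' @param path Path to the table.
#' @return Gene-model data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, validated by [validate_genes()].
#' @export
read_exon_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "strand", "exon_start", "exon_end")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("exon table lacks column(s): ", paste(miss, collapse = ", "))
  genes <- data.frame(gene_id = as.character(tab$gene_id),
                      chrom = as.character(tab$chrom),
                      strand = as.character(tab$strand),
                      start = as.numeric(tab$exon_start),
                      end = as.numeric(tab$exon_end),
                      stringsAsFactors = FALSE)
  validate_genes(genes)
  genes
}

#' Write a gene-model exon table
#' @param genes Gene-model data.frame (see [read_exon_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exon_table <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand,
                    exon_start = format(genes$start, scientific = FALSE,
                                        trim = TRUE),
                    exon_end = format(genes$end, scientific = FALSE,
                                      trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
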