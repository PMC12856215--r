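# Brute-force oracles, independent of the package's interval algebra:
# everything here works on explicit per-base position sets.

# keys of every covered base; strand included in the key when strand_aware
covered_bases <- function(x, strand_aware = FALSE) {
  if (nrow(x) == 0) return(character(0))
  unlist(lapply(seq_len(nrow(x)), function(i) {
    pos <- seq.int(x$start[i], x$end[i] - 1)
    if (strand_aware) paste0(x$chrom[i], ":", x$strand[i], ":", pos)
    else paste0(x$chrom[i], ":", pos)
  }), use.names = FALSE)
}

# strand compatibility under the package's wildcard rule
strand_compat <- function(a, b) a == "*" | b == "*" | a == b

# does interval x[i,] share >= 1 base with any row of y (brute force)?
brute_overlap_one <- function(xi, y) {
  if (nrow(y) == 0) return(FALSE)
  same <- y$chrom == xi$chrom & strand_compat(xi$strand, y$strand)
  any(same & y$start < xi$end & y$end > xi$start)
}

brute_overlaps_any <- function(x, y, strand_aware = TRUE) {
  vapply(seq_len(nrow(x)), function(i) {
    yi <- y
    if (!strand_aware) {
      xi <- x[i, , drop = FALSE]
      xi$strand <- "*"
      brute_overlap_one(xi, yi)
    } else brute_overlap_one(x[i, , drop = FALSE], yi)
  }, logical(1))
}

# random interval generator (concrete strands, scores 1..100)
random_gi <- function(n, chroms = c("chrA", "chrB"), max_pos = 10000,
                      max_len = 300, strands = c("+", "-")) {
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(len, function(l)
    sample.int(max_pos - l, 1) - 1, numeric(1))
  gi(sample(chroms, n, replace = TRUE), start, start + len,
     sample(strands, n, replace = TRUE),
     score = sample.int(100, n, replace = TRUE))
}

# brute-force consensus: keep intervals of each preprocessed set that
# overlap every other set, take the union base set
brute_consensus_bases <- function(sets) {
  kept <- lapply(seq_along(sets), function(i) {
    x <- sets[[i]]
    if (nrow(x) == 0) return(x)
    keep <- vapply(seq_len(nrow(x)), function(r)
      all(vapply(seq_along(sets)[-i], function(j)
        brute_overlap_one(x[r, , drop = FALSE], sets[[j]]), logical(1))),
      logical(1))
    x[keep, , drop = FALSE]
  })
  sort(unique(covered_bases(do.call(rbind, kept), strand_aware = TRUE)))
}

# independent Benjamini-Hochberg implementation
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# brute-force Venn membership signatures
brute_venn <- function(sets) {
  ids <- unique(unlist(sets))
  out <- list()
  for (id in ids) {
    sig <- paste(names(sets)[vapply(sets, function(s) id %in% s,
                                    logical(1))], collapse = "&")
    out[[sig]] <- sort(c(out[[sig]], id))
  }
  out
}

# small standard fixture: two genes on one chromosome, opposite strands
toy_genes <- function() {
  rbind(
    data.frame(gene_id = "gA", chrom = "chr1", strand = "+",
               start = c(100, 300, 600, 900),
               end = c(200, 400, 700, 1000)),
    data.frame(gene_id = "gB", chrom = "chr1", strand = "-",
               start = c(2000, 2400, 2800), end = c(2100, 2500, 2900)))
}

toy_sizes <- function() c(chr1 = 10000, chr2 = 10000)
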