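# rMATS tables, significance filters, event regions, observed overlap

write_se_fixture <- function(path) {
  writeLines(c(
    paste("ID", "GeneID", "geneSymbol", "chr", "strand", "exonStart_0base",
          "exonEnd", "upstreamES", "upstreamEE", "downstreamES",
          "downstreamEE", "PValue", "FDR", "IncLevel1", "IncLevel2",
          "IncLevelDifference", sep = "\t"),
    paste("1", "gX", "GX", "chr1", "+", "300", "400", "100", "200", "600",
          "700", "0.001", "0.01", "0.8,0.9,0.85", "0.2,0.3,0.25", "0.6",
          sep = "\t"),
    paste("2", "gY", "GY", "chr2", "-", "1300", "1400", "1100", "1200",
          "1600", "1700", "0.2", "0.4", "0.5,NA,0.7", "0.55,0.6,NA",
          "0.025", sep = "\t")), path)
}

test_that("the rMATS reader parses coordinates and replicate PSI lists", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_se_fixture(p)
  ev <- read_rmats_table(p, "SE")
  expect_equal(nrow(ev), 2)
  expect_equal(ev$t1_start, c(300, 1300))
  expect_equal(ev$f2_end, c(700, 1700))
  expect_equal(ev$psi1, c(0.85, 0.6))  # "0.5,NA,0.7" -> 0.6
  expect_equal(ev$psi2[2], 0.575)
  expect_equal(ev$fdr, c(0.01, 0.4))
  expect_equal(ev$event_id, c("SE_1", "SE_2"))
})

test_that("reader errors are informative", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_se_fixture(p)
  tab <- read.delim(p, check.names = FALSE)
  tab$FDR <- NULL
  write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_rmats_table(p, "SE"), "FDR")
  write_se_fixture(p)
  tab <- read.delim(p, check.names = FALSE)
  tab$FDR[1] <- "oops"
  write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_rmats_table(p, "SE"), "non-numeric FDR")
})

test_that("write/read round trips preserve every field for all 5 types", {
  g <- simulate_genome(sim_config(n_chrom = 2, chrom_length = 2e5,
                                  n_genes = 40), seed = 2)
  ev <- simulate_events(g$genes,
                        sim_config(n_events = c(SE = 10, RI = 8, MXE = 5,
                                                A5SS = 5, A3SS = 5)),
                        "A", seed = 3)$tables$A
  for (ty in unique(ev$event_type)) {
    sub <- ev[ev$event_type == ty, ]
    rownames(sub) <- NULL
    p <- withr::local_tempfile(fileext = ".tsv")
    write_rmats_table(sub, p)
    back <- read_rmats_table(p, ty)
    for (col in c("event_id", "gene_id", "chrom", "strand", "t1_start",
                  "t1_end", "t2_start", "t2_end", "f1_start", "f1_end",
                  "f2_start", "f2_end", "inc1", "inc2")) {
      expect_equal(back[[col]], sub[[col]], info = paste(ty, col))
    }
    expect_equal(back$fdr, sub$fdr, tolerance = 1e-12)
    # group means recomputed from the 4-decimal replicate lists
    expect_equal(back$psi1, sub$psi1, tolerance = 1e-3)
  }
  expect_error(write_rmats_table(ev, withr::local_tempfile()),
               "single event type")
})

test_that("significance filter uses strict thresholds", {
  ev <- data.frame(event_id = paste0("SE_", 1:4), event_type = "SE",
                   gene_id = "g", chrom = "chr1", strand = "+",
                   t1_start = 300, t1_end = 400, t2_start = NA,
                   t2_end = NA, f1_start = 100, f1_end = 200,
                   f2_start = 600, f2_end = 700,
                   psi1 = 0.5, psi2 = 0.4, delta_psi = c(0.1, 0.2, 0.2, 0.2),
                   p_value = 0.01, fdr = c(0.01, 0.05, 0.049, NA),
                   inc1 = "0.5", inc2 = "0.4")
  suppressWarnings({
    kept <- filter_events(ev, 0.05, 0.1)
  })
  # row 1: dPSI exactly 0.1 -> out; row 2: FDR exactly 0.05 -> out;
  # row 4: NA FDR -> out
  expect_equal(kept$event_id, "SE_3")
  # nested thresholds
  set.seed(4)
  g <- simulate_genome(sim_config(n_chrom = 1, chrom_length = 4e5,
                                  n_genes = 30), seed = 5)
  big <- simulate_events(g$genes,
                         sim_config(n_events = c(SE = 60, RI = 0, MXE = 0,
                                                 A5SS = 0, A3SS = 0)),
                         "A", seed = 6)$tables$A
  strict <- filter_events(big, 0.05, 0.1)
  loose <- filter_events(big, 0.05, 0)
  expect_true(all(strict$event_id %in% loose$event_id))
  # brute-force row filter equivalence
  expect_equal(loose$event_id,
               big$event_id[!is.na(big$fdr) & big$fdr < 0.05 &
                              abs(big$delta_psi) > 0])
})

test_that("event regions per type", {
  g <- simulate_genome(sim_config(n_chrom = 2, chrom_length = 2e5,
                                  n_genes = 40), seed = 2)
  ev <- simulate_events(g$genes,
                        sim_config(n_events = c(SE = 6, RI = 6, MXE = 4,
                                                A5SS = 4, A3SS = 4)),
                        "A", seed = 8)$tables$A
  counts <- vapply(split(event_regions(ev)$name, event_regions(ev)$name),
                   length, integer(1))
  expect_true(all(counts[grep("^SE", names(counts))] == 3))
  expect_true(all(counts[grep("^RI", names(counts))] == 3))
  expect_true(all(counts[grep("^MXE", names(counts))] == 4))
  expect_true(all(counts[grep("^A[35]SS", names(counts))] == 2))
  # regions stay on the event's chromosome and strand
  reg <- event_regions(ev)
  byid <- split(reg, reg$name)
  for (id in names(byid)) {
    e <- ev[ev$event_id == id, ]
    expect_true(all(byid[[id]]$chrom == e$chrom))
    expect_true(all(byid[[id]]$strand == e$strand))
  }
  # an MXE without its second target is rejected
  bad <- ev[ev$event_type == "MXE", ][1, ]
  bad$t2_start <- NA
  expect_error(event_regions(bad), "t2")
})

test_that("observed overlap counts events and sites correctly", {
  ev <- data.frame(event_id = "SE_1", event_type = "SE", gene_id = "g",
                   chrom = "chr1", strand = "+",
                   t1_start = 3000, t1_end = 3100, t2_start = NA,
                   t2_end = NA, f1_start = 2500, f1_end = 2600,
                   f2_start = 3500, f2_end = 3600,
                   psi1 = 0.5, psi2 = 0.3, delta_psi = 0.2,
                   p_value = 0.001, fdr = 0.01, inc1 = "0.5", inc2 = "0.3")
  sizes <- c(chr1 = 10000)
  # no sites
  o <- observed_overlap(ev, empty_gi(), sizes)
  expect_equal(o$n_events_hit + o$n_sites_hit, 0)
  # a site 150 bp downstream of the downstream flank: only reached with
  # the 200 bp expansion
  site <- gi("chr1", 3750, 3780, "+")
  expect_equal(observed_overlap(ev, site, sizes, flank = 0)$n_events_hit, 0)
  o <- observed_overlap(ev, site, sizes, flank = 200)
  expect_equal(o$n_events_hit, 1)
  expect_equal(o$n_sites_hit, 1)
  expect_equal(o$fraction_events_hit, 1)
  # strand awareness with wildcard sites
  minus <- site
  minus$strand <- "-"
  expect_equal(observed_overlap(ev, minus, sizes)$n_events_hit, 0)
  star <- site
  star$strand <- "*"
  expect_equal(observed_overlap(ev, star, sizes)$n_events_hit, 1)
})

test_that("observed overlap matches the per-base oracle and is monotone in flank", {
  g <- simulate_genome(sim_config(n_chrom = 2, chrom_length = 1.5e5,
                                  n_genes = 30), seed = 12)
  ev <- simulate_events(g$genes,
                        sim_config(n_events = c(SE = 30, RI = 10, MXE = 5,
                                                A5SS = 5, A3SS = 5)),
                        "A", seed = 13)$tables$A
  set.seed(14)
  prev <- -1
  for (fl in c(0, 100, 200, 500)) {
    sites <- random_gi(150, chroms = names(g$sizes), max_pos = 1.5e5,
                       max_len = 60, strands = c("+", "-", "*"))
    o <- observed_overlap(ev, sites, g$sizes, flank = fl)
    # brute force on the expanded regions
    reg <- gi_expand(event_regions(ev), g$sizes, fl)
    hits <- brute_overlaps_any(reg, sites, strand_aware = TRUE)
    expect_equal(o$n_events_hit, length(unique(reg$name[hits])))
    expect_equal(o$n_sites_hit,
                 sum(brute_overlaps_any(sites, reg, strand_aware = TRUE)))
  }
  # monotonicity with the same site set
  sites <- random_gi(150, chroms = names(g$sizes), max_pos = 1.5e5,
                     max_len = 60)
  fr <- vapply(c(0, 100, 200, 500), function(fl)
    observed_overlap(ev, sites, g$sizes, flank = fl)$fraction_events_hit,
    numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("event type counts partition the table", {
  expect_equal(sum(event_type_counts(data.frame(event_type = character(0)))),
               0)
  ev <- data.frame(event_type = c("SE", "SE", "SE", "RI"))
  expect_equal(event_type_counts(ev),
               c(SE = 3L, RI = 1L, MXE = 0L, A5SS = 0L, A3SS = 0L))
})

test_that("delta-PSI matrix marks absent cells NA and rejects duplicates", {
  g <- simulate_genome(sim_config(n_chrom = 1, chrom_length = 4e5,
                                  n_genes = 30), seed = 15)
  tabs <- simulate_events(g$genes,
                          sim_config(n_events = c(SE = 20, RI = 0, MXE = 0,
                                                  A5SS = 0, A3SS = 0)),
                          c("A", "B"), seed = 16)$tables
  sigA <- filter_events(tabs$A)
  sigB <- filter_events(tabs$B)
  m <- delta_psi_matrix(list(A = sigA, B = sigB))
  expect_equal(nrow(m), length(union(event_key(sigA), event_key(sigB))))
  onlyA <- setdiff(event_key(sigA), event_key(sigB))
  if (length(onlyA)) {
    expect_true(all(is.na(m[onlyA, "B"])))
    expect_equal(m[onlyA, "A"],
                 setNames(sigA$delta_psi[match(onlyA, event_key(sigA))],
                          onlyA))
  }
  # single contrast -> single column
  expect_equal(ncol(delta_psi_matrix(list(A = sigA))), 1)
  # TSV round trip with explicit NA token
  p <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(event_key = rownames(m), m, check.names = FALSE),
              p, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  back <- read.delim(p, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]),
               unname(m) |> `dimnames<-`(list(NULL, colnames(m))),
               ignore_attr = FALSE)
  expect_error(delta_psi_matrix(list(A = rbind(sigA, sigA))),
               "duplicate event key")
})
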