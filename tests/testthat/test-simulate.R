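# synthetic-data generators: determinism, invariants, calibration, power

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(n_chrom = 2, chrom_length = 1e5, n_genes = 20,
                    n_events = c(SE = 10, RI = 5, MXE = 2, A5SS = 2,
                                 A3SS = 2), n_sites = 30)
  g1 <- simulate_genome(cfg, seed = 5)
  g2 <- simulate_genome(cfg, seed = 5)
  expect_identical(g1, g2)
  e1 <- simulate_events(g1$genes, cfg, c("A", "B"), seed = 6)
  e2 <- simulate_events(g1$genes, cfg, c("A", "B"), seed = 6)
  expect_identical(e1, e2)
  fs <- build_feature_space(g1$genes)
  c1 <- simulate_clip(fs, empty_gi(), sim_config(n_sites = 30,
                                                 enrichment = 0),
                      seed = 7)
  c2 <- simulate_clip(fs, empty_gi(), sim_config(n_sites = 30,
                                                 enrichment = 0),
                      seed = 7)
  expect_identical(c1, c2)
  expect_identical(simulate_deg_table(g1$genes, cfg, seed = 8),
                   simulate_deg_table(g1$genes, cfg, seed = 8))
  expect_identical(simulate_ct(cfg, 2, seed = 9),
                   simulate_ct(cfg, 2, seed = 9))
  expect_error(sim_config(bogus = 1), "unknown sim_config")
})

test_that("simulated genomes respect their own geometry", {
  cfg <- sim_config(n_chrom = 2, chrom_length = 1e5, n_genes = 24)
  g <- simulate_genome(cfg, seed = 11)
  expect_true(all(g$genes$end <= g$sizes[g$genes$chrom]))
  expect_true(all(g$genes$start >= 0))
  # genes never overlap, even across strands
  m <- gi_merge(gi(g$genes$chrom, g$genes$start, g$genes$end))
  per_gene <- vapply(split(g$genes, g$genes$gene_id), function(x)
    max(x$end) - min(x$start), numeric(1))
  expect_true(all(c("+", "-") %in% g$genes$strand))
  # empty genome
  g0 <- simulate_genome(sim_config(n_genes = 0), seed = 1)
  expect_equal(nrow(g0$genes), 0)
  # infeasible packing errors
  expect_error(simulate_genome(sim_config(n_chrom = 1,
                                          chrom_length = 5000,
                                          n_genes = 50), seed = 1),
               "do not fit")
})

test_that("event tables are calibrated under the null and powered under signal", {
  g <- simulate_genome(sim_config(n_chrom = 2, chrom_length = 8e5,
                                  n_genes = 150), seed = 21)
  cfg0 <- sim_config(n_events = c(SE = 250, RI = 0, MXE = 0, A5SS = 0,
                                  A3SS = 0), prop_signal = 0)
  # pool raw p-values over three independent tables
  ps <- unlist(lapply(1:3, function(i)
    simulate_events(g$genes, cfg0, "A", seed = 30 + i)$tables$A$p_value))
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
  # power: dPSI 0.3, logit noise 0.05, 3 replicates
  cfg1 <- sim_config(n_events = c(SE = 200, RI = 0, MXE = 0, A5SS = 0,
                                  A3SS = 0), prop_signal = 0.3,
                     dpsi_effect = 0.3, psi_noise_sd = 0.05,
                     contrast_signal_prob = 1)
  sim <- simulate_events(g$genes, cfg1, "A", seed = 41)
  sig_ids <- filter_events(sim$tables$A)$event_id
  truth <- sim$truth
  recall <- mean(truth$event_id[truth$is_signal] %in% sig_ids)
  expect_gte(recall, 0.8)
  # replicate PSI values stay in [0, 1]
  all_psi <- unlist(lapply(strsplit(c(sim$tables$A$inc1,
                                      sim$tables$A$inc2), ","),
                           as.numeric))
  expect_true(all(all_psi >= 0 & all_psi <= 1))
  # truth labels line up with the planted direction
  sig_truth <- truth[truth$is_signal, ]
  dp <- sim$tables$A$delta_psi[match(sig_truth$event_id,
                                     sim$tables$A$event_id)]
  expect_gt(stats::cor(dp, sig_truth$true_dpsi), 0.9)
})

test_that("clip simulation: jitter-free replicates and planted placement", {
  g <- simulate_genome(sim_config(n_chrom = 2, chrom_length = 1e5,
                                  n_genes = 25), seed = 51)
  fs <- build_feature_space(g$genes)
  # jitter 0, no noise sites -> identical replicate coordinates and
  # consensus equal to the merged common set
  cfg <- sim_config(n_sites = 40, enrichment = 0, replicate_jitter = 0,
                    noise_site_rate = 0, n_clip_replicates = 3)
  clip <- simulate_clip(fs, empty_gi(), cfg, seed = 52)
  expect_equal(clip$replicates[[1]][, 1:4], clip$replicates[[2]][, 1:4])
  cons <- consensus_hitsclip(clip$replicates)
  common <- clip$truth[, names(empty_gi())]
  expect_setequal(covered_bases(cons, TRUE),
                  unique(covered_bases(common, TRUE)))
  # every site sits inside the feature space
  pool <- rbind(fs$exonic, fs$intronic)
  inside <- vapply(seq_len(nrow(common)), function(i)
    any(pool$chrom == common$chrom[i] & pool$strand == common$strand[i] &
          pool$start <= common$start[i] & pool$end >= common$end[i]),
    logical(1))
  expect_true(all(inside))
  expect_error(simulate_clip(fs, empty_gi(),
                             sim_config(enrichment = 0.5), seed = 1),
               "target_regions")
  # with planted enrichment, targeted sites overlap their regions
  ev <- simulate_events(g$genes,
                        sim_config(n_events = c(SE = 30, RI = 0, MXE = 0,
                                                A5SS = 0, A3SS = 0),
                                   prop_signal = 0.5),
                        "A", seed = 53)$tables$A
  regions <- gi_expand(event_regions(filter_events(ev)), g$sizes, 200)
  cfg2 <- sim_config(n_sites = 100, enrichment = 0.4)
  clip2 <- simulate_clip(fs, regions, cfg2, seed = 54)
  tgt <- clip2$truth[clip2$truth$targeted, names(empty_gi())]
  expect_true(all(gi_overlaps_any(tgt, regions, strand_aware = TRUE)))
})

test_that("background placement frequency matches the exact expectation", {
  # fixed site length so the hit probability is computable by enumerating
  # every valid start in the placement model
  g <- simulate_genome(sim_config(n_chrom = 2, chrom_length = 1e5,
                                  n_genes = 25), seed = 61)
  fs <- build_feature_space(g$genes)
  ev <- simulate_events(g$genes,
                        sim_config(n_events = c(SE = 20, RI = 0, MXE = 0,
                                                A5SS = 0, A3SS = 0),
                                   prop_signal = 0.5),
                        "A", seed = 62)$tables$A
  regions <- gi_expand(event_regions(filter_events(ev)), g$sizes, 200)
  L <- 30
  pool <- rbind(fs$exonic, fs$intronic)
  # enumerate valid starts and their overlap status (the oracle)
  hit_prob <- local({
    tot <- 0
    hits <- 0
    for (i in seq_len(nrow(pool))) {
      sts <- seq.int(pool$start[i], pool$end[i] - L)
      if (pool$end[i] - pool$start[i] < L) next
      tot <- tot + length(sts)
      cand <- gi(pool$chrom[i], sts, sts + L, pool$strand[i])
      hits <- hits + sum(brute_overlaps_any(cand, regions,
                                            strand_aware = TRUE))
    }
    hits / tot
  })
  cfg <- sim_config(n_sites = 2000, enrichment = 0,
                    site_length = c(L, L))
  clip <- simulate_clip(fs, empty_gi(), cfg, seed = 63)
  common <- clip$truth[, names(empty_gi())]
  obs <- mean(gi_overlaps_any(common, regions, strand_aware = TRUE))
  # binomial 99.9% band around the exact expectation
  se <- sqrt(hit_prob * (1 - hit_prob) / 2000)
  expect_lt(abs(obs - hit_prob), 3.3 * se + 1e-9)
})

test_that("DEG simulation is calibrated and BH matches an independent oracle", {
  g <- simulate_genome(sim_config(n_chrom = 2, chrom_length = 8e5,
                                  n_genes = 150), seed = 71)
  cfg0 <- sim_config(deg_prop_signal = 0)
  ps <- unlist(lapply(1:8, function(i)
    simulate_deg_table(g$genes, cfg0, seed = 80 + i)$table$p_value))
  # 1200 null p-values: the rejection rate sits in a 3.3-sigma band
  # around the nominal 0.05 and the whole distribution is uniform
  expect_lt(abs(mean(ps < 0.05) - 0.05),
            3.3 * sqrt(0.05 * 0.95 / length(ps)))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
  # 10 sigma effect: near-perfect recall at the default thresholds
  cfg1 <- sim_config(deg_prop_signal = 0.2, deg_effect = 2,
                     lfc_null_sd = 0.2)
  sim <- simulate_deg_table(g$genes, cfg1, seed = 85)
  hits <- filter_degs(sim$table)
  expect_gte(mean(sim$truth$gene_id[sim$truth$is_signal] %in% hits), 0.95)
  # BH against the hand-written oracle
  expect_equal(sim$table$padj, brute_bh(sim$table$p_value))
})

test_that("Ct simulation embeds the planted ratio", {
  ct0 <- simulate_ct(sim_config(ct_noise_sd = 0), true_ratio = 3,
                     seed = 91)
  expect_equal(splicing_ratios(ct0)$summary$mean_ratio, 3)
  # ratio 1 means equal inclusion/exclusion dCt in expectation
  ct1 <- simulate_ct(sim_config(ct_noise_sd = 0), true_ratio = 1,
                     seed = 92)
  pr <- splicing_ratios(ct1)$per_rep
  expect_equal(pr$dct_inclusion, pr$dct_exclusion)
  expect_error(simulate_ct(sim_config(), true_ratio = -1), "true_ratio")
})
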