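# Synthetic-data generators.
#
# Every input the pipeline consumes can be generated with known truth:
# a toy genome with non-overlapping multi-exon genes, rMATS-style event
# tables with planted differential splicing, replicated CLIP site files
# with controllable planted enrichment, DESeq2-style DEG tables, and qPCR
# Ct tables.  All generators are pure functions of (config, seed).

#' Simulation configuration
#'
#' Returns the default simulation parameters, overridable by name. The
#' default scale (3 chromosomes of 1 Mb, 300 genes, 500 splice events,
#' 1000 binding sites, 2 CLIP replicates) mirrors a down-scaled bulk
#' RNA-seq / CLIP-seq experiment and keeps full-pipeline runs fast.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    # genome
    n_chrom = 3, chrom_length = 1e6, n_genes = 300,
    exons_per_gene = c(4, 10), exon_length = c(80, 300),
    intron_length = c(100, 1000), intergenic_gap = c(500, 3000),
    # splice events (counts per class; SE-dominated as in real rMATS runs)
    n_events = c(SE = 300, RI = 80, MXE = 40, A5SS = 40, A3SS = 40),
    prop_signal = 0.3, dpsi_effect = 0.3, n_replicates = 3,
    psi_noise_sd = 0.05,  # logit-scale SD
    contrast_signal_prob = 0.7,  # chance a signal event fires per contrast
    # CLIP sites
    n_sites = 1000, site_length = c(20, 50), enrichment = 0.3,
    n_clip_replicates = 2, replicate_jitter = 5, noise_site_rate = 0.2,
    readcount_mu = 80, readcount_size = 2,  # PAR-CLIP ReadCount ~ NB
    duplicate_lambda = 4,                   # FLASH PCR duplicates ~ Pois+1
    # DEG tables
    deg_prop_signal = 0.2, deg_effect = 2, lfc_null_sd = 0.2,
    # qPCR
    ct_noise_sd = 0.2, n_bio_reps = 3, n_tech_reps = 3)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$n_events <- unlist(cfg$n_events)
  if (is.null(names(cfg$n_events)) ||
      !all(names(cfg$n_events) %in% EVENT_TYPES))
    stop("n_events must be named by event type (SE/RI/MXE/A5SS/A3SS); ",
         "in a JSON config write it as an object, not an array")
  stopifnot(cfg$prop_signal >= 0, cfg$prop_signal <= 1,
            cfg$enrichment >= 0, cfg$enrichment <= 1,
            cfg$dpsi_effect > 0, cfg$dpsi_effect < 1,
            cfg$psi_noise_sd > 0)
  class(cfg) <- "sim_config"
  cfg
}

.runif_int <- function(n, lo, hi) floor(stats::runif(n) * (hi - lo + 1)) + lo

#' Simulate a toy genome and gene models
#'
#' Genes are laid down left to right per chromosome with alternating
#' exon/intron lengths drawn from the configured ranges, separated by
#' random intergenic gaps, never overlapping; strands are assigned at
#' random. Deterministic under `seed`.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed (`NULL` continues the RNG stream).
#' @return List with `sizes` (named vector) and `genes` (exon table).
#' @export
simulate_genome <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- stats::setNames(rep(config$chrom_length, config$n_chrom),
                           paste0("chr", seq_len(config$n_chrom)))
  if (config$n_genes == 0)
    return(list(sizes = sizes,
                genes = data.frame(gene_id = character(0),
                                   chrom = character(0),
                                   strand = character(0),
                                   start = numeric(0), end = numeric(0))))
  chrom_of <- rep(names(sizes), length.out = config$n_genes)
  rows <- vector("list", config$n_genes)
  cursor <- stats::setNames(rep(0, config$n_chrom), names(sizes))
  for (g in seq_len(config$n_genes)) {
    ch <- chrom_of[g]
    gap <- .runif_int(1, config$intergenic_gap[1], config$intergenic_gap[2])
    k <- .runif_int(1, config$exons_per_gene[1], config$exons_per_gene[2])
    elen <- .runif_int(k, config$exon_length[1], config$exon_length[2])
    ilen <- if (k > 1)
      .runif_int(k - 1, config$intron_length[1], config$intron_length[2])
      else numeric(0)
    start0 <- cursor[ch] + gap
    starts <- start0 + cumsum(c(0, elen[-k] + ilen))
    ends <- starts + elen
    if (ends[k] > sizes[ch])
      stop("genes do not fit on ", ch,
           "; increase chrom_length or reduce n_genes")
    cursor[ch] <- ends[k]
    rows[[g]] <- data.frame(
      gene_id = sprintf("g%04d", g), chrom = ch,
      strand = if (stats::runif(1) < 0.5) "+" else "-",
      start = starts, end = ends, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  validate_genes(genes)
  list(sizes = sizes, genes = genes)
}

# enumerate candidate event slots in the gene models
.event_slots <- function(genes, type) {
  out <- lapply(split(genes, genes$gene_id), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    k <- nrow(g)
    mk <- function(i_list) {
      if (length(i_list) == 0) return(NULL)
      do.call(rbind, lapply(i_list, function(i) {
        co <- switch(type,
          SE = c(t1s = g$start[i], t1e = g$end[i], t2s = NA, t2e = NA,
                 f1s = g$start[i - 1], f1e = g$end[i - 1],
                 f2s = g$start[i + 1], f2e = g$end[i + 1]),
          RI = c(t1s = g$end[i], t1e = g$start[i + 1], t2s = NA, t2e = NA,
                 f1s = g$start[i], f1e = g$end[i],
                 f2s = g$start[i + 1], f2e = g$end[i + 1]),
          MXE = c(t1s = g$start[i], t1e = g$end[i],
                  t2s = g$start[i + 1], t2e = g$end[i + 1],
                  f1s = g$start[i - 1], f1e = g$end[i - 1],
                  f2s = g$start[i + 2], f2e = g$end[i + 2]),
          A5SS = {
            d <- min(30, g$end[i] - g$start[i] - 10)
            c(t1s = g$start[i], t1e = g$end[i],
              t2s = g$start[i], t2e = g$end[i] - d,
              f1s = g$start[i + 1], f1e = g$end[i + 1], f2s = NA, f2e = NA)
          },
          A3SS = {
            d <- min(30, g$end[i + 1] - g$start[i + 1] - 10)
            c(t1s = g$start[i + 1], t1e = g$end[i + 1],
              t2s = g$start[i + 1] + d, t2e = g$end[i + 1],
              f1s = g$start[i], f1e = g$end[i], f2s = NA, f2e = NA)
          })
        data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
                   strand = g$strand[1], t(co), stringsAsFactors = FALSE)
      }))
    }
    idx <- switch(type,
                  SE = if (k >= 3) 2:(k - 1) else integer(0),
                  RI = if (k >= 2) 1:(k - 1) else integer(0),
                  MXE = if (k >= 4) 2:(k - 2) else integer(0),
                  A5SS = if (k >= 2) 1:(k - 1) else integer(0),
                  A3SS = if (k >= 2) 1:(k - 1) else integer(0))
    mk(as.list(idx))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Simulate rMATS-style differential-splicing tables with known truth
#'
#' Events are carved out of the gene models (a skipped exon needs three
#' consecutive exons, mutually exclusive exons four, and so on). Each
#' event gets a baseline inclusion level from Uniform(0.1, 0.9);
#' per-replicate levels are logit-normal around the group means. A
#' `prop_signal` fraction of events are true signal: in each contrast
#' where they fire (independently with `contrast_signal_prob`, at least
#' one), the treatment group mean is shifted by +/- `dpsi_effect` and
#' clipped to \[0.01, 0.99\]. P-values come from a two-sample t-test on
#' logit inclusion levels (the splicing caller's likelihood machinery is
#' out of scope; only its output shape is emulated) and are BH-adjusted
#' within each (contrast, event type) table, as the per-type output files
#' would be.
#'
#' @param genes Gene-model exon table.
#' @param config A `sim_config`.
#' @param contrasts Character vector of contrast names.
#' @param seed Integer seed.
#' @return List with `tables` (named list: contrast -> splice-event
#'   data.frame) and `truth` (event_id, event_key, contrast, is_signal,
#'   true_dpsi).
#' @export
simulate_events <- function(genes, config = sim_config(),
                            contrasts = c("treatment"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(contrasts) >= 1)
  ev_list <- list()
  for (ty in names(config$n_events)) {
    n_ty <- config$n_events[[ty]]
    if (n_ty == 0) next
    slots <- .event_slots(genes, ty)
    if (is.null(slots) || nrow(slots) < n_ty)
      stop("not enough gene structures to host ", n_ty, " ", ty,
           " events (", if (is.null(slots)) 0 else nrow(slots),
           " available)")
    pick <- sample.int(nrow(slots), n_ty)
    s <- slots[pick, , drop = FALSE]
    s$event_type <- ty
    ev_list[[ty]] <- s
  }
  ev <- do.call(rbind, ev_list)
  n <- nrow(ev)
  ev$event_id <- sprintf("%s_%d", ev$event_type, seq_len(n))
  baseline <- stats::runif(n, 0.1, 0.9)
  is_signal <- stats::runif(n) < config$prop_signal
  effect_sign <- ifelse(stats::runif(n) < 0.5, 1, -1)
  fires <- matrix(FALSE, n, length(contrasts),
                  dimnames = list(NULL, contrasts))
  for (i in which(is_signal)) {
    f <- stats::runif(length(contrasts)) < config$contrast_signal_prob
    if (!any(f)) f[sample.int(length(contrasts), 1)] <- TRUE
    fires[i, ] <- f
  }
  nr <- config$n_replicates
  sd <- config$psi_noise_sd
  tables <- list()
  truth <- list()
  for (co in contrasts) {
    mu2 <- baseline
    mu1 <- ifelse(fires[, co],
                  pmin(0.99, pmax(0.01, baseline +
                                    effect_sign * config$dpsi_effect)),
                  baseline)
    psi1m <- matrix(stats::plogis(stats::rnorm(
      n * nr, rep(stats::qlogis(mu1), nr), sd)), n, nr)
    psi2m <- matrix(stats::plogis(stats::rnorm(
      n * nr, rep(stats::qlogis(mu2), nr), sd)), n, nr)
    p <- vapply(seq_len(n), function(i)
      stats::t.test(stats::qlogis(psi1m[i, ]),
                    stats::qlogis(psi2m[i, ]))$p.value, numeric(1))
    psi1 <- rowMeans(psi1m)
    psi2 <- rowMeans(psi2m)
    events <- data.frame(
      event_id = ev$event_id, event_type = ev$event_type,
      gene_id = ev$gene_id, chrom = ev$chrom, strand = ev$strand,
      t1_start = as.numeric(ev$t1s), t1_end = as.numeric(ev$t1e),
      t2_start = as.numeric(ev$t2s), t2_end = as.numeric(ev$t2e),
      f1_start = as.numeric(ev$f1s), f1_end = as.numeric(ev$f1e),
      f2_start = as.numeric(ev$f2s), f2_end = as.numeric(ev$f2e),
      psi1 = psi1, psi2 = psi2, delta_psi = psi1 - psi2,
      p_value = p, fdr = NA_real_,
      inc1 = apply(round(psi1m, 4), 1, paste, collapse = ","),
      inc2 = apply(round(psi2m, 4), 1, paste, collapse = ","),
      stringsAsFactors = FALSE)
    for (ty in unique(events$event_type)) {
      sel <- events$event_type == ty
      events$fdr[sel] <- stats::p.adjust(events$p_value[sel],
                                         method = "BH")
    }
    validate_events(events)
    tables[[co]] <- events
    truth[[co]] <- data.frame(
      event_id = ev$event_id, event_key = event_key(events),
      contrast = co, is_signal = fires[, co],
      true_dpsi = ifelse(fires[, co], effect_sign * config$dpsi_effect, 0),
      stringsAsFactors = FALSE)
  }
  list(tables = tables, truth = do.call(rbind, truth))
}

# place sites of given lengths uniformly over the valid-start space of the
# pool intervals; returns start positions and pool row indices (NA where no
# interval can host the length)
.uniform_place <- function(lens, pool) {
  n <- length(lens)
  out_start <- rep(NA_real_, n)
  out_idx <- rep(NA_integer_, n)
  for (L in unique(lens)) {
    ii <- which(lens == L)
    cnt <- pmax(pool$end - pool$start - L + 1, 0)
    tot <- sum(cnt)
    if (tot == 0) next
    cs <- c(0, cumsum(cnt))
    r <- floor(stats::runif(length(ii)) * tot) + 1
    r[r > tot] <- tot
    j <- findInterval(r - 0.5, cs)
    out_start[ii] <- pool$start[j] + (r - cs[j] - 1)
    out_idx[ii] <- j
  }
  list(start = out_start, idx = out_idx)
}

#' Simulate replicated CLIP binding-site files
#'
#' A common site set is drawn first: with probability `enrichment` a site
#' is placed inside a randomly chosen target region (binding near a
#' regulated splice site); otherwise uniformly over the exon/intron
#' feature space. Each replicate is the common set with per-site start
#' jitter up to `replicate_jitter` bp plus `noise_site_rate * n_sites`
#' replicate-private background sites, with scores drawn per replicate
#' (`"readcount"`: negative binomial, so the ReadCount >= 40 filter bites;
#' `"duplicates"`: shifted Poisson, so summed scores straddle 10).
#'
#' @param space A `feature_space`.
#' @param target_regions Interval data.frame of (expanded) regions of the
#'   planted signal events; required when `enrichment > 0`.
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @param score_type `"readcount"` or `"duplicates"`.
#' @return List with `replicates` (list of interval data.frames) and
#'   `truth` (the common site set with a `targeted` flag).
#' @export
simulate_clip <- function(space, target_regions = empty_gi(),
                          config = sim_config(), seed = NULL,
                          score_type = c("readcount", "duplicates")) {
  score_type <- match.arg(score_type)
  stopifnot(inherits(space, "feature_space"))
  if (!is.null(seed)) set.seed(seed)
  pool <- rbind(space$exonic, space$intronic)
  if (nrow(pool) == 0) stop("empty feature space")
  if (config$enrichment > 0 && nrow(target_regions) == 0)
    stop("enrichment > 0 requires non-empty target_regions")
  n <- config$n_sites
  lens <- .runif_int(n, config$site_length[1], config$site_length[2])
  targeted <- stats::runif(n) < config$enrichment
  chrom <- character(n)
  start <- rep(NA_real_, n)
  strand <- rep("*", n)
  if (any(!targeted)) {
    bg <- .uniform_place(lens[!targeted], pool)
    if (any(is.na(bg$start)))
      stop("feature space cannot host sites of the configured lengths")
    chrom[!targeted] <- pool$chrom[bg$idx]
    start[!targeted] <- bg$start
    strand[!targeted] <- pool$strand[bg$idx]
  }
  if (any(targeted)) {
    ri <- sample.int(nrow(target_regions), sum(targeted), replace = TRUE)
    rs <- target_regions$start[ri]
    re <- target_regions$end[ri]
    L <- lens[targeted]
    hi <- pmax(rs, re - L)
    chrom[targeted] <- target_regions$chrom[ri]
    start[targeted] <- floor(stats::runif(sum(targeted)) *
                               (hi - rs + 1)) + rs
    strand[targeted] <- target_regions$strand[ri]
  }
  common <- gi(chrom, start, start + lens, strand,
               name = sprintf("site_%04d", seq_len(n)))
  draw_scores <- function(m) {
    if (score_type == "readcount")
      stats::rnbinom(m, size = config$readcount_size,
                     mu = config$readcount_mu)
    else stats::rpois(m, config$duplicate_lambda) + 1
  }
  n_noise <- round(config$noise_site_rate * n)
  replicates <- lapply(seq_len(config$n_clip_replicates), function(r) {
    jit <- if (config$replicate_jitter > 0)
      .runif_int(n, -config$replicate_jitter, config$replicate_jitter)
      else rep(0, n)
    rep_sites <- common
    rep_sites$start <- pmax(0, common$start + jit)
    rep_sites$end <- rep_sites$start + lens
    if (n_noise > 0) {
      nl <- .runif_int(n_noise, config$site_length[1],
                       config$site_length[2])
      np <- .uniform_place(nl, pool)
      noise <- gi(pool$chrom[np$idx], np$start, np$start + nl,
                  pool$strand[np$idx],
                  name = sprintf("noise_%d_%04d", r, seq_len(n_noise)))
      rep_sites <- rbind(rep_sites, noise)
    }
    rep_sites$score <- draw_scores(nrow(rep_sites))
    rep_sites
  })
  truth <- common
  truth$targeted <- targeted
  list(replicates = replicates, truth = truth)
}

#' Simulate a DESeq2-style differential-expression table
#'
#' Null genes get a log2 fold change from Normal(0, `lfc_null_sd`); a
#' `deg_prop_signal` fraction are shifted by +/- `deg_effect`. The p-value
#' is the two-sided Gaussian tail of `log2fc / lfc_null_sd` (so null
#' p-values are uniform by construction), BH-adjusted across the table.
#'
#' @param genes Gene-model exon table (supplies the gene ids).
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return List with `table` (gene_id, log2fc, p_value, padj) and `truth`
#'   (gene_id, is_signal, true_lfc).
#' @export
simulate_deg_table <- function(genes, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(genes$gene_id)
  n <- length(ids)
  is_signal <- stats::runif(n) < config$deg_prop_signal
  true_lfc <- ifelse(is_signal,
                     ifelse(stats::runif(n) < 0.5, 1, -1) *
                       config$deg_effect, 0)
  lfc <- stats::rnorm(n, true_lfc, config$lfc_null_sd)
  p <- 2 * stats::pnorm(-abs(lfc) / config$lfc_null_sd)
  list(table = data.frame(gene_id = ids, log2fc = lfc, p_value = p,
                          padj = stats::p.adjust(p, method = "BH"),
                          stringsAsFactors = FALSE),
       truth = data.frame(gene_id = ids, is_signal = is_signal,
                          true_lfc = true_lfc, stringsAsFactors = FALSE))
}

#' Write a DEG table in the DESeq2 output dialect
#'
#' @param records data.frame with `gene_id`, `log2fc`, `p_value`, `padj`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(records, path) {
  out <- data.frame(gene_id = records$gene_id,
                    log2FoldChange = records$log2fc,
                    pvalue = records$p_value, padj = records$padj)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate a qPCR Ct table for a splicing assay
#'
#' Reference (GAPDH), inclusion and exclusion targets over
#' `n_bio_reps x n_tech_reps` wells. The noiseless Ct values are chosen so
#' that the inclusion/exclusion ratio equals `true_ratio` exactly; each
#' well is then perturbed by Normal(0, `ct_noise_sd`).
#'
#' @param config A `sim_config`.
#' @param true_ratio Planted inclusion/exclusion ratio (> 0).
#' @param base_ct Noiseless reference Ct (default 20 cycles).
#' @param dct_exclusion Noiseless exclusion dCt versus the reference
#'   (default -4, i.e. the exclusion product is 16-fold rarer than GAPDH).
#' @param sample_id Sample label.
#' @param seed Integer seed.
#' @return Ct data.frame (`sample_id`, `target`, `bio_rep`, `tech_rep`,
#'   `ct`).
#' @export
simulate_ct <- function(config = sim_config(), true_ratio = 1,
                        base_ct = 20, dct_exclusion = -4,
                        sample_id = "S1", seed = NULL) {
  stopifnot(true_ratio > 0)
  if (!is.null(seed)) set.seed(seed)
  dct_inc <- dct_exclusion + log2(true_ratio)
  true_ct <- c(GAPDH = base_ct,
               inclusion = base_ct - dct_inc,
               exclusion = base_ct - dct_exclusion)
  grid <- expand.grid(target = names(true_ct),
                      bio_rep = seq_len(config$n_bio_reps),
                      tech_rep = seq_len(config$n_tech_reps),
                      stringsAsFactors = FALSE)
  grid$sample_id <- sample_id
  grid$ct <- true_ct[grid$target] +
    stats::rnorm(nrow(grid), 0, config$ct_noise_sd)
  out <- grid[order(grid$target, grid$bio_rep, grid$tech_rep),
              c("sample_id", "target", "bio_rep", "tech_rep", "ct")]
  rownames(out) <- NULL
  validate_ct(out)
  out
}
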