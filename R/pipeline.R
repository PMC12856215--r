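# End-to-end pipeline driver: simulate -> consensus -> filter -> enrich ->
# classify -> report.  Every stochastic stage draws its own sub-seed from
# the master seed, so rerunning with the same config and seed reproduces
# byte-identical result files; wall-clock timings live only in the run
# manifest.

#' Default pipeline configuration
#'
#' A toy-scale configuration exercising every stage in seconds. Fields:
#' `sim` (overrides for [sim_config()]), `contrasts`, `recipe`
#' (consensus recipe), `min_read_count`, `min_score`, `max_fdr`,
#' `min_abs_dpsi` (set-logic filter), `heatmap_min_abs_dpsi` (stricter
#' heatmap filter), `flank`, `n_iter`, `stat`, `enrich_contrast` and
#' `codependent_target` (default: the first contrast).
#'
#' @param ... Named overrides.
#' @return Configuration list.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    sim = list(n_chrom = 2, chrom_length = 4e5, n_genes = 100,
               n_events = c(SE = 80, RI = 20, MXE = 10, A5SS = 10,
                            A3SS = 10),
               n_sites = 200, enrichment = 0.2),
    contrasts = c("wt_inhibitor", "ko_inhibitor"),
    recipe = "hitsclip", min_read_count = 40, min_score = 10,
    max_fdr = 0.05, min_abs_dpsi = 0, heatmap_min_abs_dpsi = 0.1,
    flank = 200, n_iter = 100, stat = "sites",
    enrich_contrast = NULL, codependent_target = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown pipeline config field(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Run the full synthetic pipeline
#'
#' Executes, in order: genome simulation, per-contrast splice-event
#' simulation and rMATS-dialect export, significance filtering, CLIP
#' replicate simulation and consensus building, the permutation enrichment
#' test, DEG simulation and DEG/AS set classification, Venn partition and
#' co-dependency sets over event keys, and the event-by-contrast
#' delta-PSI matrix. All outputs are tab-separated or JSON files under
#' `out_dir`; a run manifest records the config, seed, per-stage timings
#' and md5 checksums of every output.
#'
#' @param config Configuration list from [default_pipeline_config()], or a
#'   path to a JSON file of overrides.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir, seed = 1) {
  if (is.character(config) && length(config) == 1)
    config <- do.call(default_pipeline_config,
                      jsonlite::read_json(config, simplifyVector = TRUE))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  contrasts <- config$contrasts
  # JSON round trips can turn absent fields into empty lists, so default
  # on length rather than NULL
  enrich_contrast <- if (length(config$enrich_contrast))
    config$enrich_contrast else contrasts[1]
  codep_target <- if (length(config$codependent_target))
    config$codependent_target else contrasts[1]
  if (!enrich_contrast %in% contrasts)
    stop("unknown enrich_contrast '", enrich_contrast, "'")
  if (!codep_target %in% contrasts)
    stop("unknown codependent_target '", codep_target, "'")
  scfg <- do.call(sim_config, as.list(config$sim))
  set.seed(seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 6)
  outputs <- character(0)
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(path) {
    outputs <<- c(outputs, path)
    path
  }

  genome <- tick("genome", simulate_genome(scfg, seed = stage_seed[1]))
  write_chrom_sizes(genome$sizes, emit(file.path(out_dir, "chrom.sizes")))
  write_exon_table(genome$genes, emit(file.path(out_dir, "exons.tsv")))
  space <- build_feature_space(genome$genes)

  sim_ev <- tick("events", simulate_events(genome$genes, scfg, contrasts,
                                           seed = stage_seed[2]))
  for (co in names(sim_ev$tables)) {
    for (ty in unique(sim_ev$tables[[co]]$event_type)) {
      ev <- sim_ev$tables[[co]]
      write_rmats_table(ev[ev$event_type == ty, , drop = FALSE],
                        emit(file.path(out_dir,
                                       sprintf("rmats_%s_%s.tsv", co, ty))))
    }
  }
  .write_json(sim_ev$truth, emit(file.path(out_dir, "truth_events.json")))

  sig <- lapply(sim_ev$tables, filter_events, max_fdr = config$max_fdr,
                min_abs_dpsi = config$min_abs_dpsi)
  target_regions <- gi_expand(event_regions(sig[[enrich_contrast]]),
                              genome$sizes, config$flank)
  clip <- tick("clip", simulate_clip(
    space, target_regions, scfg, seed = stage_seed[3],
    score_type = if (config$recipe == "flashclip") "duplicates"
                 else "readcount"))
  for (r in seq_along(clip$replicates))
    write_bed(clip$replicates[[r]],
              emit(file.path(out_dir, sprintf("clip_rep%d.bed", r))))
  consensus <- clip_consensus(clip$replicates, recipe = config$recipe,
                              min_read_count = config$min_read_count,
                              min_score = config$min_score)
  write_bed(consensus, emit(file.path(out_dir, "consensus.bed")))

  enr <- tick("enrichment", permutation_enrichment(
    sig[[enrich_contrast]], consensus, space, genome$sizes,
    n_iter = config$n_iter, flank = config$flank, seed = stage_seed[4],
    stat = config$stat))
  write_enrichment_json(enr, emit(file.path(out_dir, "enrichment.json")))

  deg <- tick("deg", simulate_deg_table(genome$genes, scfg,
                                        seed = stage_seed[5]))
  write_deg_table(deg$table, emit(file.path(out_dir, "deg.tsv")))
  deg_sig <- filter_degs(deg$table)
  as_sig <- as_gene_set(sig[[enrich_contrast]])
  overlap <- if (length(deg_sig) || length(as_sig))
    deg_as_overlap(deg_sig, as_sig) else NULL

  event_sets <- lapply(sig, event_key)
  sets_out <- list(
    venn_counts = lapply(venn_partition(event_sets), length),
    codependent_target = codep_target,
    codependent = codependent_set(event_sets, codep_target),
    deg_as = overlap)
  .write_json(sets_out, emit(file.path(out_dir, "sets.json")))

  heat <- delta_psi_matrix(lapply(sim_ev$tables, filter_events,
                                  max_fdr = config$max_fdr,
                                  min_abs_dpsi =
                                    config$heatmap_min_abs_dpsi))
  utils::write.table(
    data.frame(event_key = rownames(heat), heat, check.names = FALSE),
    emit(file.path(out_dir, "delta_psi_matrix.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")

  manifest <- list(
    tool = "clipsplice",
    version = as.character(utils::packageVersion("clipsplice")),
    seed = seed,
    config = config,
    timings = timings,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))))
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
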