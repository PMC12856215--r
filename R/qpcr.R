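# Cycle-threshold (Ct) statistics for qPCR readouts.
#
# Conventions (amplification efficiency fixed at 2, i.e. perfect doubling):
#   dCt              = Ct(reference, GAPDH) - Ct(target)
#   relative expr.   = 2 ^ dCt
#   inclusion ratio  = 2 ^ (dCt_inclusion - dCt_exclusion)
#   percent of input = 100 * input_fraction * 2 ^ (Ct_input - Ct_IP)
# Technical replicates are averaged on the Ct scale; biological replicates
# are summarised as mean +/- SD.

#' Read a Ct table
#'
#' Tab-separated with header columns `sample_id`, `target`, `bio_rep`,
#' `tech_rep`, `ct`. The (sample, target, bio_rep, tech_rep) combination
#' must be unique.
#'
#' @param path Path to the table.
#' @return Ct data.frame.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "target", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  validate_ct(tab)
  tab
}

#' Validate a Ct table
#' @param records Ct data.frame.
#' @return `records`, invisibly.
#' @export
validate_ct <- function(records) {
  if (any(!is.finite(records$ct) | records$ct <= 0))
    stop("Ct values must be finite and > 0")
  key <- paste(records$sample_id, records$target, records$bio_rep,
               records$tech_rep)
  if (anyDuplicated(key))
    stop("duplicate (sample, target, bio_rep, tech_rep): ",
         key[duplicated(key)][1])
  invisible(records)
}

#' Average technical replicates on the Ct scale
#'
#' Collapses technical replicates to one mean Ct per (sample, target,
#' biological replicate), warning when the technical SD exceeds 0.5 cycles
#' (a conventional pipetting-quality flag; nothing is dropped).
#'
#' @param records Ct data.frame.
#' @return data.frame with `sample_id`, `target`, `bio_rep`, `ct`
#'   (technical mean), `ct_sd`, `n_tech`.
#' @export
aggregate_ct <- function(records) {
  validate_ct(records)
  key <- interaction(records$sample_id, records$target, records$bio_rep,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    data.frame(sample_id = g$sample_id[1], target = g$target[1],
               bio_rep = g$bio_rep[1], ct = mean(g$ct),
               ct_sd = if (nrow(g) > 1) stats::sd(g$ct) else NA_real_,
               n_tech = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  noisy <- !is.na(out$ct_sd) & out$ct_sd > 0.5
  if (any(noisy))
    warning(sum(noisy), " (sample, target, bio_rep) group(s) have ",
            "technical SD > 0.5 cycles")
  out
}

#' Delta-Ct relative to a reference gene
#'
#' `dCt = ct_reference - ct_target`: a more abundant target (lower Ct)
#' gives a larger dCt.
#'
#' @param ct_reference Reference-gene (GAPDH) Ct.
#' @param ct_target Target Ct.
#' @return dCt (vectorised).
#' @export
delta_ct <- function(ct_reference, ct_target) ct_reference - ct_target

#' Exon inclusion/exclusion ratio
#'
#' `ratio = 2 ^ (dCt_inclusion - dCt_exclusion)`, where each dCt is
#' GAPDH-normalised ([delta_ct()]). Equal dCts give a ratio of 1.
#'
#' @param dct_inclusion dCt of the inclusion-junction primer pair.
#' @param dct_exclusion dCt of the exclusion-junction primer pair.
#' @return Positive ratio (vectorised).
#' @export
inclusion_ratio <- function(dct_inclusion, dct_exclusion)
  2^(dct_inclusion - dct_exclusion)

#' Relative expression by the delta-Ct method
#'
#' `2 ^ dCt` relative to the reference gene; adding one cycle to dCt
#' doubles the value.
#'
#' @param dct dCt value(s).
#' @return Relative expression (vectorised).
#' @export
relative_expression <- function(dct) 2^dct

#' Percent enrichment of input for ChIP/RIP qPCR
#'
#' `100 * input_fraction * 2 ^ (ct_input - ct_ip)`, where `ct_input` is the
#' Ct measured on the saved input aliquot and `input_fraction` the
#' proportion of IP material that aliquot represents (the dilution
#' adjustment). With `ct_input == ct_ip` and fraction 1 the enrichment is
#' exactly 100%.
#'
#' @param ct_input Input-aliquot Ct.
#' @param ct_ip Immunoprecipitate Ct.
#' @param input_fraction Fraction of IP material in the input aliquot, in
#'   `(0, 1]`.
#' @return Percentage (vectorised).
#' @export
percent_input <- function(ct_input, ct_ip, input_fraction) {
  if (any(input_fraction <= 0 | input_fraction > 1))
    stop("input_fraction must be in (0, 1]")
  100 * input_fraction * 2^(ct_input - ct_ip)
}

#' Per-biological-replicate splicing ratios from a Ct table
#'
#' Convenience pipeline: averages technical replicates, forms
#' GAPDH-normalised dCts for the inclusion and exclusion primer pairs, and
#' returns the inclusion/exclusion ratio per sample and biological
#' replicate together with a mean +/- SD summary per sample.
#'
#' @param records Ct data.frame.
#' @param reference Reference target name (default `"GAPDH"`).
#' @param inclusion Inclusion-primer target name.
#' @param exclusion Exclusion-primer target name.
#' @return List with `per_rep` (sample_id, bio_rep, dct_inclusion,
#'   dct_exclusion, ratio) and `summary` (sample_id, mean_ratio, sd_ratio,
#'   n).
#' @export
splicing_ratios <- function(records, reference = "GAPDH",
                            inclusion = "inclusion",
                            exclusion = "exclusion") {
  agg <- aggregate_ct(records)
  need <- c(reference, inclusion, exclusion)
  if (!all(need %in% agg$target))
    stop("Ct table lacks target(s): ",
         paste(setdiff(need, agg$target), collapse = ", "))
  wide <- stats::reshape(
    agg[agg$target %in% need, c("sample_id", "bio_rep", "target", "ct")],
    idvar = c("sample_id", "bio_rep"), timevar = "target",
    direction = "wide")
  ctcol <- function(t) wide[[paste0("ct.", t)]]
  per_rep <- data.frame(
    sample_id = wide$sample_id, bio_rep = wide$bio_rep,
    dct_inclusion = delta_ct(ctcol(reference), ctcol(inclusion)),
    dct_exclusion = delta_ct(ctcol(reference), ctcol(exclusion)),
    stringsAsFactors = FALSE)
  per_rep$ratio <- inclusion_ratio(per_rep$dct_inclusion,
                                   per_rep$dct_exclusion)
  per_rep <- per_rep[order(per_rep$sample_id, per_rep$bio_rep), ]
  rownames(per_rep) <- NULL
  summary <- do.call(rbind, lapply(split(per_rep, per_rep$sample_id),
                                   function(g) {
    data.frame(sample_id = g$sample_id[1], mean_ratio = mean(g$ratio),
               sd_ratio = if (nrow(g) > 1) stats::sd(g$ratio) else NA_real_,
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(per_rep = per_rep, summary = summary)
}

#' Compare condition groups
#'
#' Two groups: two-tailed unpaired two-sample t-test. More than two (or
#' `design = "multi"`): one-way ANOVA with Sidak-adjusted pairwise
#' comparisons computed from the pooled residual variance
#' (`p_adj = 1 - (1 - p)^m` over the m requested comparisons).
#'
#' @param values Numeric vector of per-replicate measurements.
#' @param groups Factor or character vector of condition labels.
#' @param design `"pairwise"` (exactly two groups) or `"multi"`.
#' @param comparisons For `"multi"`: list of length-2 character vectors of
#'   group names; default all pairs.
#' @return data.frame with `comparison`, `estimate` (difference in means),
#'   `p_raw`, `p_adj`.
#' @export
group_compare <- function(values, groups,
                          design = c("pairwise", "multi"),
                          comparisons = NULL) {
  design <- match.arg(design)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("every group needs >= 2 replicates")
  if (design == "pairwise") {
    if (length(tab) != 2)
      stop("pairwise design requires exactly 2 groups")
    g <- names(tab)
    tt <- stats::t.test(values[groups == g[1]], values[groups == g[2]],
                        var.equal = FALSE)
    return(data.frame(
      comparison = paste(g[1], "vs", g[2]),
      estimate = mean(values[groups == g[1]]) -
        mean(values[groups == g[2]]),
      p_raw = tt$p.value, p_adj = tt$p.value, stringsAsFactors = FALSE))
  }
  if (is.null(comparisons)) {
    comparisons <- utils::combn(names(tab), 2, simplify = FALSE)
  }
  bad <- vapply(comparisons, function(cp)
    length(cp) != 2 || !all(cp %in% names(tab)), logical(1))
  if (any(bad)) stop("comparisons must be pairs of known group names")
  fit <- stats::aov(values ~ factor(groups))
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  df <- stats::df.residual(fit)
  m <- length(comparisons)
  out <- do.call(rbind, lapply(comparisons, function(cp) {
    n1 <- tab[[cp[1]]]
    n2 <- tab[[cp[2]]]
    est <- mean(values[groups == cp[1]]) - mean(values[groups == cp[2]])
    tstat <- est / sqrt(mse * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tstat), df)
    data.frame(comparison = paste(cp[1], "vs", cp[2]), estimate = est,
               p_raw = p, p_adj = min(1, 1 - (1 - p)^m),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
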