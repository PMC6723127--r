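#' Thresholds for the depth-guided filter cascade
#'
#' Six visualization-guided filters applied in a fixed order: (A) pre-genotyping
#' pooled-depth window on log10 scale, (B) locus-level reference/alternate
#' read-count balance on log2 scale, (C) locus total-depth window, (D)
#' per-genotype depth window, (E) heterozygote allele-balance window, (F)
#' minimum called offspring per locus.  All removals use strict inequalities:
#' a value exactly at a threshold survives.
#'
#' The locus allele-balance window is asymmetric (-2.32 = 1:5 on the low side,
#' +2.6 = ~6:1 on the high side) because read alignment is biased toward
#' reads carrying reference alleles, shifting genuine heterozygous loci toward
#' positive log2(ref/alt).
#'
#' @param prefilter_log10_depth_min,prefilter_log10_depth_max keep a position
#'   iff `log10(depth)` lies inside the closed window (depth 0 always drops).
#' @param locus_log2_refalt_min,locus_log2_refalt_max closed window on
#'   `log2(pooled ref / pooled alt)` per locus.
#' @param locus_total_depth_min,locus_total_depth_max closed window on total
#'   pooled reads per locus.
#' @param genotype_depth_min,genotype_depth_max closed window on per-genotype
#'   reads; calls outside go to missing.
#' @param het_abs_log2_ratio_max heterozygous calls with
#'   `|log2(ref/alt)|` above this go to missing.
#' @param min_called_offspring keep a locus iff at least this many offspring
#'   have a call.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(prefilter_log10_depth_min = 2.0,
                          prefilter_log10_depth_max = 3.2,
                          locus_log2_refalt_min = -2.32,
                          locus_log2_refalt_max = 2.6,
                          locus_total_depth_min = 320,
                          locus_total_depth_max = 1400,
                          genotype_depth_min = 8,
                          genotype_depth_max = 40,
                          het_abs_log2_ratio_max = 3.26,
                          min_called_offspring = 50) {
  cfg <- as.list(environment())
  stopifnot(cfg$prefilter_log10_depth_min < cfg$prefilter_log10_depth_max,
            cfg$locus_log2_refalt_min < cfg$locus_log2_refalt_max,
            cfg$locus_total_depth_min < cfg$locus_total_depth_max,
            cfg$genotype_depth_min < cfg$genotype_depth_max,
            cfg$het_abs_log2_ratio_max > 0, cfg$min_called_offspring >= 0)
  class(cfg) <- "filter_config"
  cfg
}

#' Pre-genotyping position filter on pooled depth (filter A)
#'
#' Keep a position iff `log10(depth)` falls inside the configured window;
#' zero-depth positions are dropped.  A binned log10-depth histogram table is
#' attached (attribute `histogram`) for threshold-setting plots.
#'
#' @param depth_table data.frame(scaffold, position, depth), e.g. from
#'   [read_depth_table].
#' @param cfg a [filter_config].
#' @return logical keep vector, one element per depth-table row.
#' @export
prefilter_positions <- function(depth_table, cfg = filter_config()) {
  d <- depth_table$depth
  keep <- d > 0
  ld <- rep(NA_real_, length(d))
  ld[keep] <- log10(d[keep])
  keep <- keep & ld >= cfg$prefilter_log10_depth_min &
    ld <= cfg$prefilter_log10_depth_max
  keep[is.na(keep)] <- FALSE
  lv <- ld[!is.na(ld)]
  br <- seq(0, max(5, ceiling(max(c(lv, 0)) * 10) / 10) + 0.1, by = 0.1)
  counts <- tabulate(findInterval(lv, br, rightmost.closed = TRUE),
                     nbins = length(br) - 1)
  attr(keep, "histogram") <- data.frame(
    log10_depth_mid = utils::head(br, -1) + 0.05, count = counts)
  keep
}

#' Restrict a cross to positions surviving the pre-genotyping filter
#'
#' @param x a [rad_cross].
#' @param depth_table the depth table the mask refers to.
#' @param keep logical mask from [prefilter_positions].
#' @return the subsetted cross.
#' @export
apply_position_mask <- function(x, depth_table, keep) {
  ok <- paste(depth_table$scaffold[keep], depth_table$position[keep])
  subset_loci(x, paste(x$loci$scaffold, x$loci$position) %in% ok)
}

#' Locus allele-balance filter (filter B)
#'
#' Keep a locus iff `log2(pooled ref / pooled alt)` lies inside the closed
#' config window; a locus with zero pooled reads for either allele drops.
#'
#' @param x a [rad_cross].
#' @param cfg a [filter_config].
#' @return logical keep vector over loci.
#' @export
filter_loci_allele_balance <- function(x, cfg = filter_config()) {
  r <- rowSums(x$ref_depth)
  a <- rowSums(x$alt_depth)
  keep <- r > 0 & a > 0
  lr <- rep(NA_real_, length(r))
  lr[keep] <- log2(r[keep] / a[keep])
  keep & lr >= cfg$locus_log2_refalt_min & lr <= cfg$locus_log2_refalt_max &
    !is.na(lr)
}

#' Locus total-depth filter (filter C)
#'
#' Keep a locus iff its pooled read total over all samples lies inside the
#' closed `[locus_total_depth_min, locus_total_depth_max]` window.
#'
#' @inheritParams filter_loci_allele_balance
#' @return logical keep vector over loci.
#' @export
filter_loci_total_depth <- function(x, cfg = filter_config()) {
  tot <- rowSums(x$ref_depth) + rowSums(x$alt_depth)
  tot >= cfg$locus_total_depth_min & tot <= cfg$locus_total_depth_max
}

#' Per-genotype depth and heterozygote-balance filters (filters D, E)
#'
#' Sets individual genotype calls to missing when (D) their read depth falls
#' outside the closed `[genotype_depth_min, genotype_depth_max]` window, or
#' (E) they are heterozygous with `|log2(ref/alt)|` above
#' `het_abs_log2_ratio_max`.  A het with either allele at zero reads is by
#' definition mis-called and also goes to missing.  Calls are only ever
#' changed to missing, never to a different call.
#'
#' @inheritParams filter_loci_allele_balance
#' @param which apply the depth window only, the het-balance rule only, or
#'   both (the default).
#' @return the cross with filtered genotype calls.
#' @export
filter_genotypes <- function(x, cfg = filter_config(),
                             which = c("both", "depth", "het")) {
  which <- match.arg(which)
  gt <- x$gt
  if (which %in% c("both", "depth")) {
    d <- x$ref_depth + x$alt_depth
    gt[d < cfg$genotype_depth_min | d > cfg$genotype_depth_max] <- NA_character_
  }
  if (which %in% c("both", "het")) {
    het <- !is.na(gt) & gt == "AB"
    zero <- het & (x$ref_depth == 0 | x$alt_depth == 0)
    ratio <- matrix(NA_real_, nrow(gt), ncol(gt))
    ok <- het & !zero
    ratio[ok] <- abs(log2(x$ref_depth[ok] / x$alt_depth[ok]))
    gt[zero | (ok & ratio > cfg$het_abs_log2_ratio_max)] <- NA_character_
  }
  x$gt <- gt
  x
}

#' Locus missingness filter (filter F)
#'
#' Keep a locus iff at least `min_called_offspring` offspring (parents are not
#' counted) carry a genotype call.
#'
#' @inheritParams filter_loci_allele_balance
#' @return logical keep vector over loci.
#' @export
filter_missingness <- function(x, cfg = filter_config()) {
  off <- x$gt[, offspring_ids(x), drop = FALSE]
  rowSums(!is.na(off)) >= cfg$min_called_offspring
}

.audit_row <- function(step, x) {
  off <- x$gt[, offspring_ids(x), drop = FALSE]
  called <- sum(!is.na(off))
  total <- nrow(off) * ncol(off)
  data.frame(step = step, loci = nrow(x$loci), genotypes = called,
             pct_missing = if (total > 0) round(100 * (1 - called / total), 2)
                           else NA_real_,
             stringsAsFactors = FALSE)
}

#' Run the full filter cascade with an audit trail
#'
#' Applies filters A-F in order and records loci retained, called offspring
#' genotypes and percent missing after each step (the shape of the paper
#' trail a mapping study reports).  Filter A runs only when a depth table is
#' supplied.
#'
#' @param x a [rad_cross].
#' @param cfg a [filter_config].
#' @param depth_table optional pooled depth table enabling the pre-genotyping
#'   position filter.
#' @return list: `cross` (filtered) and `audit` (data.frame, one row per step).
#' @export
run_filter_cascade <- function(x, cfg = filter_config(), depth_table = NULL) {
  audit <- list(.audit_row("input", x))
  if (!is.null(depth_table)) {
    keep <- prefilter_positions(depth_table, cfg)
    x <- apply_position_mask(x, depth_table, keep)
    audit[[length(audit) + 1L]] <- .audit_row("A_prefilter_depth", x)
  }
  x <- subset_loci(x, filter_loci_allele_balance(x, cfg))
  audit[[length(audit) + 1L]] <- .audit_row("B_locus_allele_balance", x)
  x <- subset_loci(x, filter_loci_total_depth(x, cfg))
  audit[[length(audit) + 1L]] <- .audit_row("C_locus_total_depth", x)
  x <- filter_genotypes(x, cfg, which = "depth")
  audit[[length(audit) + 1L]] <- .audit_row("D_genotype_depth", x)
  x <- filter_genotypes(x, cfg, which = "het")
  audit[[length(audit) + 1L]] <- .audit_row("E_het_allele_balance", x)
  x <- subset_loci(x, filter_missingness(x, cfg))
  audit[[length(audit) + 1L]] <- .audit_row("F_locus_missingness", x)
  if (nrow(x$loci) == 0) {
    stop("filter cascade removed every locus; review the thresholds in ",
         "filter_config() against your depth distributions")
  }
  list(cross = x, audit = do.call(rbind, audit))
}
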