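#' Run the full linkage-mapping pipeline on an F1 family
#'
#' Orchestrates every stage in order: pre-genotyping depth filter, the
#' locus/genotype filter cascade, global dropout-rate estimation and
#' cross-type classification, dropout correction, segregation-distortion and
#' parent-concordance filtering, recombination-based scaffold clustering,
#' multi-group locus exclusion, chimera flagging, marker thinning,
#' double-crossover removal, sex-specific map construction, and the
#' consensus merge.  Every stage logs its in/out counts.
#'
#' @param cross a [rad_cross] (e.g. from [read_vcf_biallelic] or the
#'   simulator).
#' @param scaffold_index data.frame(scaffold, length).
#' @param depth_table optional pooled depth table enabling filter A.
#' @param filter_cfg a [filter_config].
#' @param alpha segregation-distortion significance level (two-sided).
#' @param rf_threshold scaffold linkage threshold.
#' @param min_n reliability threshold on co-called offspring for rf use.
#' @param thin_k markers kept per scaffold and cross-type class.
#' @param map_function `"haldane"` or `"kosambi"`.
#' @param gap_length AGP gap between anchored scaffolds (bp).
#' @param min_group_scaffolds clusters at least this large count as linkage
#'   groups; smaller clusters stay unplaced.
#' @param stop_after optionally halt after `"cascade"`, `"inference"`,
#'   `"correction"`, `"distortion"`, `"grouping"`, `"thinning"` or run all
#'   stages (`NULL`).
#' @param verbose log stage progress via `message()`.
#' @return list with the intermediate products of every executed stage:
#'   `audit`, `e_hat`, `classification`, `n_corrected`, `distortion_p`,
#'   `concordance`, `groups`, `chimera_flags`, `marker_table`, `sex_maps`,
#'   `consensus`, plus bookkeeping counts.
#' @export
run_pipeline <- function(cross, scaffold_index, depth_table = NULL,
                         filter_cfg = filter_config(),
                         alpha = 0.05, rf_threshold = 0.07, min_n = 20,
                         thin_k = 5, map_function = "haldane",
                         gap_length = 100L, min_group_scaffolds = 2,
                         stop_after = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message("[radmapr] ", ...)
  out <- list()

  say("filter cascade on ", nrow(cross$loci), " loci")
  fc <- run_filter_cascade(cross, filter_cfg, depth_table)
  cross <- fc$cross
  out$audit <- fc$audit
  if (identical(stop_after, "cascade")) return(out)

  counts <- genotype_counts(cross)
  say("estimating global dropout rate over ", nrow(counts), " loci")
  eg <- estimate_global_e(counts)
  out$e_hat <- eg$e
  out$e_profile <- eg$profile
  cls <- classify_loci(counts, eg$e)
  out$classification <- cls
  say(sprintf("e_hat = %.4f", eg$e))
  if (identical(stop_after, "inference")) return(out)

  corr <- correct_dropout_genotypes(cross, cls$cross_type)
  cross <- corr$cross
  out$n_corrected <- corr$n_corrected
  out$dropout_events <- corr$events
  say("corrected ", corr$n_corrected, " impossible genotypes")
  if (identical(stop_after, "correction")) return(out)

  counts <- genotype_counts(cross)
  pv <- test_segregation(counts, cls$cross_type)
  conc <- concordance_filter(cross, cls$cross_type)
  keep <- !is.na(pv) & pv >= alpha & conc$retained
  out$distortion_p <- pv
  out$concordance <- conc
  say(sum(!is.na(pv) & pv < alpha), " loci distorted, ",
      sum(!conc$retained), " parent-discordant; ", sum(keep), " retained")
  cross <- subset_loci(cross, keep)
  cls <- cls[keep, , drop = FALSE]
  conc <- conc[keep, , drop = FALSE]
  out$n_mappable <- sum(keep)
  if (identical(stop_after, "distortion")) return(out)

  # pseudo-testcross phase classes per parent
  phase <- list(
    mother = phase_class_matrix(cross, cls$cross_type, conc$het_parent, "mother"),
    father = phase_class_matrix(cross, cls$cross_type, conc$het_parent, "father"))
  loci_list <- lapply(phase, function(X) {
    i <- match(rownames(X), cross$loci$locus_id)
    data.frame(locus_id = cross$loci$locus_id[i],
               scaffold = cross$loci$scaffold[i],
               position = cross$loci$position[i], stringsAsFactors = FALSE)
  })
  say("informative markers: ", nrow(phase$mother), " maternal, ",
      nrow(phase$father), " paternal")
  for (par in c("mother", "father")) {
    phase[[par]] <- align_scaffold_phase(phase[[par]], loci_list[[par]])
    phase[[par]] <- clean_phase_singletons(phase[[par]], loci_list[[par]])
  }
  out$n_phase_cleaned <- sum(vapply(phase, attr, 0L, "n_cleaned"))
  say("blanked ", out$n_phase_cleaned, " isolated within-scaffold phase flips")
  rfs <- lapply(phase, rf_matrix, min_n = min_n)
  srf <- pooled_scaffold_rf(phase, loci_list, min_n = min_n)
  groups <- cluster_scaffolds(srf$rf, scaffold_index, threshold = rf_threshold)
  out$groups <- groups
  sizes <- table(groups$group)
  out$n_linkage_groups <- sum(sizes >= min_group_scaffolds)
  say(out$n_linkage_groups, " linkage groups (>=", min_group_scaffolds,
      " scaffolds), ", sum(sizes < min_group_scaffolds),
      " unlinked scaffolds")
  out$chimera_flags <- flag_chimeric_scaffolds(rfs, loci_list)

  for (par in c("mother", "father")) {
    keep_m <- exclude_multigroup_loci(rfs[[par]], loci_list[[par]]$scaffold,
                                      groups, threshold = rf_threshold)
    phase[[par]] <- phase[[par]][keep_m, , drop = FALSE]
    loci_list[[par]] <- loci_list[[par]][keep_m, , drop = FALSE]
  }
  if (identical(stop_after, "grouping")) { out$phase <- phase; return(out) }

  # full (unthinned) cleaned marker set: scaffold-level consensus evidence
  phase_full <- phase
  loci_full <- loci_list

  for (par in c("mother", "father")) {
    li <- loci_list[[par]]
    li$parent_class <- par
    li$n_called <- rowSums(!is.na(phase[[par]]))
    keep_t <- thin_markers(li, k = thin_k)
    phase[[par]] <- phase[[par]][keep_t, , drop = FALSE]
    loci_list[[par]] <- loci_list[[par]][keep_t, , drop = FALSE]
    keep_d <- remove_double_crossover_loci(phase[[par]], loci_list[[par]])
    phase[[par]] <- phase[[par]][keep_d, , drop = FALSE]
    loci_list[[par]] <- loci_list[[par]][keep_d, , drop = FALSE]
  }
  out$marker_table <- rbind(
    cbind(loci_list$mother, parent = "maternal"),
    cbind(loci_list$father, parent = "paternal"))
  say("after thinning/double-crossover removal: ",
      nrow(loci_list$mother), " maternal + ", nrow(loci_list$father),
      " paternal markers")
  if (identical(stop_after, "thinning")) { out$phase <- phase; return(out) }

  lg_ids <- as.integer(names(sizes)[sizes >= min_group_scaffolds])
  maps <- build_sex_maps(phase, loci_list, groups, lg_ids = lg_ids,
                         min_n = min_n, map_function = map_function,
                         phase_full = phase_full, loci_full = loci_full)
  out$sex_maps <- maps
  say("sex maps: ", length(unique(maps$maternal$lg)), " maternal LGs, ",
      length(unique(maps$paternal$lg)), " paternal LGs")

  out$consensus <- merge_maps(maps, scaffold_index, gap_length = gap_length,
                              phase = phase_full, loci_list = loci_full)
  say("consensus: ", nrow(out$consensus$placements), " scaffolds anchored (",
      sum(out$consensus$placements$orientation != "?"), " oriented), ",
      length(out$consensus$unplaced), " unplaced")
  out
}

#' Run the pipeline from a file-based configuration
#'
#' Reads the inputs named in a configuration (a YAML file or a named list:
#' `vcf`, `depth_table`, `scaffold_index`, `mother`, `father`, optional
#' `gff`, `out_dir`, plus any [run_pipeline] option such as `alpha`,
#' `rf_threshold`, `thin_k`, `map_function`, `gap_length`, `stop_after`),
#' executes [run_pipeline], and persists each stage's outputs under
#' `out_dir`: the filter audit, per-locus classification, marker table,
#' sex-specific maps and the map summary as TSV, and the consensus as AGP
#' (plus a lifted GFF when an annotation is supplied).
#'
#' @param config path to a YAML file or a named list.
#' @return the [run_pipeline] result list, invisibly.
#' @export
run_pipeline_files <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(!is.null(config$vcf), !is.null(config$scaffold_index),
            !is.null(config$mother), !is.null(config$father))
  cross <- read_vcf_biallelic(config$vcf, config$mother, config$father)
  idx <- read_scaffold_index(config$scaffold_index)
  depth <- if (!is.null(config$depth_table)) {
    read_depth_table(config$depth_table)
  }
  fc_args <- intersect(names(config), names(formals(filter_config)))
  fcfg <- do.call(filter_config, config[fc_args])
  rp_args <- intersect(names(config),
                       setdiff(names(formals(run_pipeline)),
                               c("cross", "scaffold_index", "depth_table",
                                 "filter_cfg")))
  res <- do.call(run_pipeline, c(list(cross = cross, scaffold_index = idx,
                                      depth_table = depth,
                                      filter_cfg = fcfg),
                                 config[rp_args]))
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(res$audit, "filter_audit.tsv")
  if (!is.null(res$classification)) {
    cls <- cbind(locus_id = rownames(res$classification), res$classification)
    w(cls, "crosstype_classification.tsv")
  }
  if (!is.null(res$marker_table)) w(res$marker_table, "markers.tsv")
  if (!is.null(res$sex_maps)) {
    w(res$sex_maps$maternal, "map_maternal.tsv")
    w(res$sex_maps$paternal, "map_paternal.tsv")
  }
  if (!is.null(res$consensus)) {
    write_agp(res$consensus, idx, file.path(out_dir, "consensus.agp"),
              gap_length = if (is.null(config$gap_length)) 100L
                           else as.integer(config$gap_length))
    w(map_summary(res, idx), "map_summary.tsv")
    if (!is.null(config$gff)) {
      liftover_gff(config$gff, res$consensus, idx,
                   out_path = file.path(out_dir, "lifted.gff3"))
    }
  }
  invisible(res)
}

#' Summarise a pipeline run in map-report shape
#'
#' Collects the marker, scaffold and length bookkeeping of a finished run:
#' markers per sex map, anchored / oriented / unplaced scaffold counts and
#' total bases, linkage-group count and total map lengths.
#'
#' @param res result list of [run_pipeline].
#' @param scaffold_index data.frame(scaffold, length).
#' @return data.frame of named summary statistics.
#' @export
map_summary <- function(res, scaffold_index) {
  len <- stats::setNames(scaffold_index$length, scaffold_index$scaffold)
  pl <- res$consensus$placements
  oriented <- pl$orientation != "?"
  stat <- function(name, value) data.frame(statistic = name, value = value,
                                           stringsAsFactors = FALSE)
  lg_len <- function(m) if (nrow(m)) sum(tapply(m$cM, m$lg, max)) else 0
  rbind(
    stat("linkage_groups", res$n_linkage_groups),
    stat("maternal_markers", length(unique(res$sex_maps$maternal$locus_id))),
    stat("paternal_markers", length(unique(res$sex_maps$paternal$locus_id))),
    stat("maternal_map_cM", round(lg_len(res$sex_maps$maternal), 1)),
    stat("paternal_map_cM", round(lg_len(res$sex_maps$paternal), 1)),
    stat("scaffolds_anchored", nrow(pl)),
    stat("scaffolds_oriented", sum(oriented)),
    stat("scaffolds_unplaced", length(res$consensus$unplaced)),
    stat("bases_anchored", sum(len[pl$scaffold])),
    stat("bases_unplaced", sum(len[res$consensus$unplaced])),
    stat("pct_assembly_anchored",
         round(100 * sum(len[pl$scaffold]) / sum(len), 1)))
}
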