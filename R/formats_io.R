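#' Read biallelic SNPs with allele depths from a multi-sample VCF
#'
#' Loads a FreeBayes-style VCF, keeps biallelic SNP records only (multi-allelic
#' sites and indels are skipped and counted), and returns a [rad_cross]
#' container.  Genotype calls are taken from the caller's GT field; read
#' counts come from the per-sample AD field.
#'
#' @param vcf_path path to a VCF 4.x file (plain text or bgzipped).
#' @param mother,father sample names of the two parents as they appear in the
#'   VCF header; all other samples are treated as offspring.
#' @return A [rad_cross]; the number of skipped (non-biallelic-SNP) records is
#'   attached as attribute `n_skipped`.
#' @export
read_vcf_biallelic <- function(vcf_path, mother, father) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  if (!(mother %in% samples)) stop("mother sample '", mother, "' not in VCF header")
  if (!(father %in% samples)) stop("father sample '", father, "' not in VCF header")

  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    !grepl(",", fix$ALT, fixed = TRUE)
  is_snp[is.na(is_snp)] <- FALSE
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0) {
    message("read_vcf_biallelic: skipped ", n_skipped,
            " non-biallelic-SNP record(s)")
  }
  fmt <- v@gt[is_snp, "FORMAT"]
  has_ad <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "AD" %in% f, logical(1))
  if (any(!has_ad)) {
    i <- which(!has_ad)[1L]
    stop("record ", fix$CHROM[is_snp][i], ":", fix$POS[is_snp][i],
         " lacks an AD (allele depth) FORMAT field")
  }

  # vcfR derives row ids from CHROM_POS; keep our own to stay order-safe
  gt_raw <- vcfR::extract.gt(v, element = "GT")[is_snp, , drop = FALSE]
  ad_raw <- vcfR::extract.gt(v, element = "AD")[is_snp, , drop = FALSE]

  gt <- matrix(NA_character_, nrow(gt_raw), ncol(gt_raw))
  g <- gsub("|", "/", gt_raw, fixed = TRUE)
  gt[g %in% c("0/0")] <- "AA"
  gt[g %in% c("0/1", "1/0")] <- "AB"
  gt[g %in% c("1/1")] <- "BB"

  split_ad <- function(k) {
    x <- vapply(strsplit(ifelse(is.na(ad_raw) | ad_raw == ".", "0,0", ad_raw),
                         ",", fixed = TRUE),
                function(p) suppressWarnings(as.integer(p[k])),
                integer(1))
    x[is.na(x)] <- 0L
    matrix(x, nrow(ad_raw), ncol(ad_raw))
  }
  ref_depth <- split_ad(1L)
  alt_depth <- split_ad(2L)

  ids <- fix$ID[is_snp]
  ids[is.na(ids) | ids == "."] <-
    sprintf("%s_%s", fix$CHROM[is_snp], fix$POS[is_snp])[is.na(ids) | ids == "."]
  loci <- data.frame(
    locus_id = ids,
    scaffold = fix$CHROM[is_snp],
    position = as.integer(fix$POS[is_snp]),
    ref = fix$REF[is_snp], alt = fix$ALT[is_snp],
    stringsAsFactors = FALSE)
  roles <- ifelse(samples == mother, "mother",
                  ifelse(samples == father, "father", "offspring"))
  out <- rad_cross(loci,
                   data.frame(sample_id = samples, role = roles,
                              stringsAsFactors = FALSE),
                   ref_depth, alt_depth, gt)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a cross as a minimal VCF 4.2 file
#'
#' Emits GT:AD:DP fields; used by the simulator so that the pipeline can be
#' exercised end-to-end through its file interface.
#'
#' @param x a [rad_cross].
#' @param path output file.
#' @param seed optional integer recorded as a `##radmapr_seed` header line.
#' @export
write_vcf <- function(x, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=radmapr",
               if (!is.null(seed)) paste0("##radmapr_seed=", seed),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", x$samples$sample_id), collapse = "\t"),
             con)
  gt_code <- matrix("./.", nrow(x$gt), ncol(x$gt))
  gt_code[x$gt == "AA"] <- "0/0"
  gt_code[x$gt == "AB"] <- "0/1"
  gt_code[x$gt == "BB"] <- "1/1"
  gt_code[is.na(x$gt)] <- "./."
  cells <- matrix(paste0(gt_code, ":", x$ref_depth, ",", x$alt_depth, ":",
                         x$ref_depth + x$alt_depth),
                  nrow(x$gt), ncol(x$gt))
  body <- paste(x$loci$scaffold, x$loci$position, x$loci$locus_id,
                x$loci$ref, x$loci$alt, ".", "PASS", ".", "GT:AD:DP",
                apply(cells, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a per-base pooled depth table
#'
#' Three whitespace-delimited columns: scaffold, position, pooled depth.  The
#' file is consumed in chunks so that very large tables do not need to be held
#' in memory twice; malformed lines are counted and skipped with one summary
#' warning.
#'
#' @param path input file.
#' @param chunk_size lines per read chunk.
#' @return data.frame(scaffold, position, depth); skipped-line count attached
#'   as attribute `n_skipped`.
#' @export
read_depth_table <- function(path, chunk_size = 100000L) {
  con <- file(path, "r")
  on.exit(close(con))
  parts <- list()
  n_skipped <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (length(lines) == 0L) break
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(lines) == 0L) next
    f <- strsplit(trimws(lines), "[ \t]+")
    ok3 <- lengths(f) >= 3L
    sc <- vapply(f[ok3], `[`, "", 1L)
    po <- suppressWarnings(as.integer(vapply(f[ok3], `[`, "", 2L)))
    de <- vapply(f[ok3], `[`, "", 3L)
    dep <- suppressWarnings(as.integer(de))
    dep[!grepl("^[0-9]+$", de)] <- NA_integer_
    good <- !is.na(po) & !is.na(dep)
    n_skipped <- n_skipped + sum(!ok3) + sum(!good)
    parts[[length(parts) + 1L]] <- data.frame(
      scaffold = sc[good], position = po[good], depth = dep[good],
      stringsAsFactors = FALSE)
  }
  out <- if (length(parts)) do.call(rbind, parts)
         else data.frame(scaffold = character(), position = integer(),
                         depth = integer())
  rownames(out) <- NULL
  if (n_skipped > 0) warning("read_depth_table: skipped ", n_skipped,
                             " malformed line(s)")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read / write a scaffold length index
#'
#' Two-column TSV (scaffold, length); a samtools `.fai` file also parses since
#' only the first two columns are used.
#'
#' @param path file path.
#' @return data.frame(scaffold, length).
#' @export
read_scaffold_index <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  out <- data.frame(scaffold = as.character(x[[1]]),
                    length = as.integer(x[[2]]), stringsAsFactors = FALSE)
  if (any(out$length < 1)) stop("scaffold lengths must be >= 1")
  out
}

#' @rdname read_scaffold_index
#' @param idx data.frame(scaffold, length).
#' @export
write_scaffold_index <- function(idx, path) {
  utils::write.table(idx[, c("scaffold", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a consensus map object
#'
#' @param placements data.frame with columns `chrom`, `scaffold`,
#'   `orientation` (`"+"`, `"-"` or `"?"`) in within-chromosome order, and
#'   optionally `start`/`end` chromosome coordinates.
#' @param unplaced character vector of unanchored scaffold ids.
#' @return object of class `consensus_map`.
#' @export
consensus_map <- function(placements, unplaced = character()) {
  stopifnot(all(c("chrom", "scaffold", "orientation") %in% names(placements)))
  if (!all(placements$orientation %in% c("+", "-", "?"))) {
    stop("orientation must be one of +, -, ?")
  }
  if (anyDuplicated(placements$scaffold)) stop("scaffold anchored twice")
  structure(list(placements = placements,
                 unplaced = as.character(unplaced)),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat("consensus_map: ", length(unique(x$placements$chrom)), " chromosomes, ",
      nrow(x$placements), " anchored scaffolds (",
      sum(x$placements$orientation != "?"), " oriented), ",
      length(x$unplaced), " unplaced\n", sep = "")
  invisible(x)
}

#' Write a consensus map as AGP v2.0
#'
#' Anchored scaffolds become `W` components with their orientation; consecutive
#' scaffolds are separated by `U` gaps of `gap_length` (gap type "map", linkage
#' "no").  Unplaced scaffolds are emitted as single-component objects.
#'
#' @param map a [consensus_map].
#' @param scaffold_index data.frame(scaffold, length) covering every scaffold
#'   in the map.
#' @param path output file.
#' @param gap_length gap size in bp between consecutive anchored scaffolds.
#' @export
write_agp <- function(map, scaffold_index, path, gap_length = 100L) {
  len <- stats::setNames(scaffold_index$length, scaffold_index$scaffold)
  all_sc <- c(map$placements$scaffold, map$unplaced)
  if (!all(all_sc %in% names(len))) {
    stop("scaffold(s) missing from scaffold_index: ",
         paste(utils::head(setdiff(all_sc, names(len))), collapse = ", "))
  }
  rows <- list()
  for (ch in unique(map$placements$chrom)) {
    p <- map$placements[map$placements$chrom == ch, , drop = FALSE]
    pos <- 1L
    part <- 1L
    for (i in seq_len(nrow(p))) {
      L <- len[[p$scaffold[i]]]
      ori <- if (p$orientation[i] == "-") "-" else if (p$orientation[i] == "?") "?" else "+"
      rows[[length(rows) + 1L]] <- data.frame(
        object = ch, object_beg = pos, object_end = pos + L - 1L,
        part_number = part, component_type = "W",
        c1 = p$scaffold[i], c2 = 1L, c3 = L, c4 = ori,
        stringsAsFactors = FALSE)
      pos <- pos + L
      part <- part + 1L
      if (i < nrow(p)) {
        rows[[length(rows) + 1L]] <- data.frame(
          object = ch, object_beg = pos, object_end = pos + gap_length - 1L,
          part_number = part, component_type = "U",
          c1 = gap_length, c2 = "map", c3 = "no", c4 = "na",
          stringsAsFactors = FALSE)
        pos <- pos + gap_length
        part <- part + 1L
      }
    }
  }
  for (sc in map$unplaced) {
    rows[[length(rows) + 1L]] <- data.frame(
      object = sc, object_beg = 1L, object_end = len[[sc]],
      part_number = 1L, component_type = "W",
      c1 = sc, c2 = 1L, c3 = len[[sc]], c4 = "+",
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.0", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an AGP file back into a consensus map
#'
#' Inverse of [write_agp] for the fields this pipeline uses (object, order,
#' component id, orientation).  Single-component objects whose object id
#' equals the component id are interpreted as unplaced scaffolds.
#'
#' @param path AGP file.
#' @return a [consensus_map].
#' @export
read_agp <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE,
                         col.names = paste0("V", 1:9), fill = TRUE)
  w <- x[x$V5 == "W", , drop = FALSE]
  unplaced <- w$V6[w$V1 == w$V6]
  p <- w[w$V1 != w$V6, , drop = FALSE]
  placements <- data.frame(chrom = p$V1, scaffold = p$V6,
                           orientation = p$V9,
                           start = as.integer(p$V2), end = as.integer(p$V3),
                           stringsAsFactors = FALSE)
  consensus_map(placements, unplaced)
}

#' Lift scaffold-local GFF features onto chromosome coordinates
#'
#' Features on anchored scaffolds are translated into the chromosome frame of
#' a consensus map: for a `+` scaffold at chromosome offset `o`, a feature
#' `[s, e]` maps to `[o + s, o + e]`; for a `-` scaffold of length `L` it maps
#' to `[o + L - e + 1, o + L - s + 1]` with the strand flipped.  Scaffolds
#' anchored without orientation (`?`) are treated as `+`.  Features on
#' unplaced scaffolds pass through unchanged with `liftover_status=unplaced`.
#' Feature length is preserved exactly in both orientations.
#'
#' @param gff_path input GFF3 with scaffold-local, 1-based coordinates.
#' @param map a [consensus_map] carrying `start` offsets (as produced by
#'   [merge_maps] or [read_agp]).
#' @param scaffold_index data.frame(scaffold, length).
#' @param out_path optional path; when given the lifted GFF3 is written there.
#' @return a `GRanges` of lifted features (invisible when `out_path` given).
#' @export
liftover_gff <- function(gff_path, map, scaffold_index, out_path = NULL) {
  gr <- rtracklayer::import(gff_path)
  len <- stats::setNames(scaffold_index$length, scaffold_index$scaffold)
  pl <- map$placements
  idx <- match(as.character(GenomicRanges::seqnames(gr)), pl$scaffold)
  anchored <- !is.na(idx)

  sc_len <- len[as.character(GenomicRanges::seqnames(gr))]
  over <- anchored & GenomicRanges::end(gr) > sc_len
  if (any(over)) {
    warning("liftover_gff: skipped ", sum(over),
            " feature(s) extending past their scaffold end")
    gr <- gr[!over]
    idx <- idx[!over]
    anchored <- anchored[!over]
    sc_len <- sc_len[!over]
  }

  status <- ifelse(anchored, "lifted", "unplaced")
  new_chrom <- as.character(GenomicRanges::seqnames(gr))
  s <- GenomicRanges::start(gr)
  e <- GenomicRanges::end(gr)
  str <- as.character(GenomicRanges::strand(gr))
  if (any(anchored)) {
    i <- which(anchored)
    off <- pl$start[idx[i]] - 1L
    ori <- pl$orientation[idx[i]]
    minus <- ori == "-"
    L <- sc_len[i]
    ns <- ifelse(minus, off + L - e[i] + 1L, off + s[i])
    ne <- ifelse(minus, off + L - s[i] + 1L, off + e[i])
    new_chrom[i] <- pl$chrom[idx[i]]
    s[i] <- ns
    e[i] <- ne
    flip <- minus & str[i] %in% c("+", "-")
    str[i][flip] <- ifelse(str[i][flip] == "+", "-", "+")
  }
  out <- GenomicRanges::GRanges(
    seqnames = new_chrom,
    ranges = IRanges::IRanges(start = s, end = e),
    strand = str)
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  S4Vectors::mcols(out)$liftover_status <- status
  if (!is.null(out_path)) {
    rtracklayer::export(out, out_path, format = "gff3")
    return(invisible(out))
  }
  out
}

#' Read a pipeline run configuration from YAML
#'
#' Flat key-value YAML; unknown keys are kept so that stage-specific configs
#' can travel in one file.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
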