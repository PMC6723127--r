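#' Assemble an F1 family allele-depth / genotype container
#'
#' The central data structure of the package: per-locus, per-sample reference
#' and alternate read counts together with the genotype calls for a single
#' outbred F1 family (one mother, one father, one or more offspring).  All
#' filtering, dropout correction and mapping operate on this object.
#'
#' @param loci data.frame with columns `locus_id`, `scaffold`, `position`
#'   (1-based bp), `ref`, `alt` (single nucleotides).
#' @param samples data.frame with columns `sample_id` and `role`; roles must
#'   include exactly one `"mother"`, exactly one `"father"` and at least one
#'   `"offspring"`.
#' @param ref_depth,alt_depth integer matrices (loci x samples) of read counts
#'   supporting the reference / alternate allele.
#' @param gt character matrix (loci x samples) of genotype calls in
#'   `"AA"`, `"AB"`, `"BB"`; `NA` encodes a missing call.
#' @return An object of class `rad_cross`.
#' @export
rad_cross <- function(loci, samples, ref_depth, alt_depth, gt) {
  stopifnot(is.data.frame(loci), is.data.frame(samples))
  req <- c("locus_id", "scaffold", "position", "ref", "alt")
  if (!all(req %in% names(loci))) {
    stop("loci must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(loci$locus_id)) stop("duplicate locus ids")
  if (anyDuplicated(paste(loci$scaffold, loci$position))) {
    stop("duplicate (scaffold, position) pairs among loci")
  }
  if (any(loci$position < 1)) stop("locus positions must be >= 1")
  if (any(loci$ref == loci$alt)) stop("ref and alt allele identical at some locus")
  if (sum(samples$role == "mother") != 1 || sum(samples$role == "father") != 1) {
    stop("samples must contain exactly one mother and one father")
  }
  if (sum(samples$role == "offspring") < 1) stop("at least one offspring required")
  dims <- c(nrow(loci), nrow(samples))
  for (m in list(ref_depth, alt_depth, gt)) {
    if (!identical(dim(m), as.integer(dims))) stop("matrix dimensions do not match loci x samples")
  }
  if (any(ref_depth < 0, na.rm = TRUE) || any(alt_depth < 0, na.rm = TRUE)) {
    stop("negative read depths")
  }
  bad <- !(gt %in% c("AA", "AB", "BB") | is.na(gt))
  if (any(bad)) stop("genotype calls must be AA/AB/BB/NA")
  dimnames(ref_depth) <- dimnames(alt_depth) <- dimnames(gt) <-
    list(loci$locus_id, samples$sample_id)
  structure(
    list(loci = loci, samples = samples,
         ref_depth = ref_depth, alt_depth = alt_depth, gt = gt),
    class = "rad_cross")
}

#' @export
print.rad_cross <- function(x, ...) {
  cat("rad_cross: ", nrow(x$loci), " loci x ", nrow(x$samples), " samples (",
      sum(x$samples$role == "offspring"), " offspring)\n", sep = "")
  cat("  missing genotype calls: ",
      round(100 * mean(is.na(x$gt)), 2), "%\n", sep = "")
  invisible(x)
}

#' @rdname rad_cross
#' @param x a `rad_cross` object.
#' @export
n_offspring <- function(x) sum(x$samples$role == "offspring")

#' @rdname rad_cross
#' @export
offspring_ids <- function(x) x$samples$sample_id[x$samples$role == "offspring"]

#' @rdname rad_cross
#' @export
mother_id <- function(x) x$samples$sample_id[x$samples$role == "mother"]

#' @rdname rad_cross
#' @export
father_id <- function(x) x$samples$sample_id[x$samples$role == "father"]

#' Subset a cross to a set of loci
#'
#' @param x a `rad_cross`.
#' @param keep logical or character vector (locus ids) selecting loci.
#' @return a `rad_cross` restricted to the selected loci, original order kept.
#' @export
subset_loci <- function(x, keep) {
  if (is.character(keep)) keep <- x$loci$locus_id %in% keep
  stopifnot(length(keep) == nrow(x$loci))
  rad_cross(x$loci[keep, , drop = FALSE], x$samples,
            x$ref_depth[keep, , drop = FALSE],
            x$alt_depth[keep, , drop = FALSE],
            x$gt[keep, , drop = FALSE])
}

#' Per-locus offspring genotype counts
#'
#' Counts of AA/AB/BB calls among offspring, the sufficient statistic for
#' cross-type likelihoods.
#'
#' @param x a `rad_cross`, or a genotype matrix with offspring columns.
#' @param offspring optional character vector of offspring column names (only
#'   needed when `x` is a bare matrix).
#' @return data.frame with columns `n_aa`, `n_ab`, `n_bb`, rownames = locus ids.
#' @export
genotype_counts <- function(x, offspring = NULL) {
  gt <- if (inherits(x, "rad_cross")) x$gt[, offspring_ids(x), drop = FALSE]
        else x[, offspring, drop = FALSE]
  out <- data.frame(
    n_aa = rowSums(gt == "AA", na.rm = TRUE),
    n_ab = rowSums(gt == "AB", na.rm = TRUE),
    n_bb = rowSums(gt == "BB", na.rm = TRUE))
  rownames(out) <- rownames(gt)
  out
}
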