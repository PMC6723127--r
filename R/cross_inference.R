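#' Offspring genotype-class probabilities under a cross-type
#'
#' Category probabilities of observing AA / AB / BB in an offspring at a
#' biallelic locus, given the parental cross-type and a global heterozygote
#' dropout rate `e` (the per-direction probability that a true heterozygote
#' is observed as one specific homozygote; total dropout probability `2e`).
#'
#' \describe{
#'   \item{AAxAB}{(0.5 + e/2, 0.5 - e, e/2)}
#'   \item{ABxBB}{(e/2, 0.5 - e, 0.5 + e/2)}
#'   \item{ABxAB}{(0.25 + e/2, 0.5 - e, 0.25 + e/2)}
#'   \item{AAxBB}{(e, 1 - 2e, e)}
#' }
#' Each triple sums to 1 for every `e` in \[0, 0.5\].
#'
#' @param cross_type one of `"AAxAB"`, `"ABxBB"`, `"ABxAB"`, `"AAxBB"`.
#' @param e dropout rate in \[0, 0.5\].
#' @return numeric length-3 vector `c(p_aa, p_ab, p_bb)`.
#' @export
crosstype_probs <- function(cross_type, e) {
  if (e < 0 || e > 0.5) stop("e must lie in [0, 0.5]")
  switch(cross_type,
    AAxAB = c(0.5 + e / 2, 0.5 - e, e / 2),
    ABxBB = c(e / 2, 0.5 - e, 0.5 + e / 2),
    ABxAB = c(0.25 + e / 2, 0.5 - e, 0.25 + e / 2),
    AAxBB = c(e, 1 - 2 * e, e),
    stop("unknown cross_type: ", cross_type))
}

# fixed enumeration order; also the tie-break priority in classification
.cross_types <- c("AAxAB", "ABxBB", "ABxAB", "AAxBB")

#' Multinomial log-likelihood of offspring genotype counts
#'
#' `sum over g of n_g * log(p_g)` with the convention that a category with
#' `n_g = 0` contributes 0 even when `p_g = 0`, and `n_g > 0` with `p_g = 0`
#' gives `-Inf`.
#'
#' @param counts numeric length-3 `c(n_aa, n_ab, n_bb)` or a matrix/data.frame
#'   with those three columns (one row per locus).
#' @param cross_type a cross-type name, see [crosstype_probs].
#' @param e dropout rate in \[0, 0.5\].
#' @return log-likelihood (vector when `counts` has several rows).
#' @export
crosstype_loglik <- function(counts, cross_type, e) {
  p <- crosstype_probs(cross_type, e)
  m <- if (is.null(dim(counts))) matrix(as.numeric(counts), 1) else
    as.matrix(counts)[, 1:3, drop = FALSE]
  lp <- ifelse(p > 0, log(p), -Inf)
  ll <- sweep(m, 2, lp, `*`)
  ll[m == 0] <- 0           # 0 * log(0) := 0
  out <- rowSums(ll)
  if (is.null(dim(counts))) out[[1]] else out
}

# loci x 4 matrix of log-likelihoods at a fixed e
.loglik_matrix <- function(counts, e) {
  n <- nrow(as.matrix(counts))
  ll <- vapply(.cross_types, function(ct) crosstype_loglik(counts, ct, e),
               numeric(n))
  matrix(ll, nrow = n, dimnames = list(NULL, .cross_types))
}

#' Estimate the global heterozygote dropout rate
#'
#' Profile maximum likelihood: for a candidate `e`, each locus contributes the
#' log-likelihood of its best-fitting cross-type; `e` maximising the summed
#' profile over all loci is returned.  A coarse grid (step 0.005 over
#' \[0, 0.5\]) brackets the optimum, which is then refined by golden-section
#' search within the bracketing interval.
#'
#' @param counts matrix/data.frame of offspring genotype counts
#'   (`n_aa`, `n_ab`, `n_bb`), one row per locus; see [genotype_counts].
#' @param grid_step coarse grid resolution.
#' @return list: `e` (the estimate), `loglik` at the optimum, and `profile`
#'   (data.frame of the grid evaluations).
#' @export
estimate_global_e <- function(counts, grid_step = 0.005) {
  m <- as.matrix(counts)[, 1:3, drop = FALSE]
  if (nrow(m) < 1) stop("at least one locus required")
  f <- function(e) sum(apply(.loglik_matrix(m, e), 1, max))
  grid <- seq(0, 0.5, by = grid_step)
  prof <- vapply(grid, f, numeric(1))
  i <- which.max(prof)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-6)
  # the boundary e = 0 is a legal optimum the interior search cannot reach
  best_e <- if (prof[i] >= opt$objective) grid[i] else opt$maximum
  best_ll <- max(prof[i], opt$objective)
  list(e = best_e, loglik = best_ll,
       profile = data.frame(e = grid, loglik = prof))
}

#' Classify each locus to its maximum-likelihood cross-type
#'
#' At a fixed global dropout rate, assigns the cross-type with the highest
#' multinomial log-likelihood.  Ties are broken by the fixed enumeration
#' order AAxAB, ABxBB, ABxAB, AAxBB and flagged.
#'
#' @param counts per-locus offspring genotype counts (see [genotype_counts]).
#' @param e global dropout rate, typically from [estimate_global_e].
#' @return data.frame: `cross_type`, one log-likelihood column per type
#'   (`ll_AAxAB`, ...), and a logical `tie` flag.
#' @export
classify_loci <- function(counts, e) {
  m <- as.matrix(counts)[, 1:3, drop = FALSE]
  ll <- .loglik_matrix(m, e)
  best <- apply(ll, 1, which.max)        # first maximum = enumeration order
  mx <- ll[cbind(seq_len(nrow(ll)), best)]
  tie <- rowSums(abs(ll - mx) < 1e-9) > 1
  out <- data.frame(cross_type = .cross_types[best], tie = tie,
                    stringsAsFactors = FALSE)
  colnames(ll) <- paste0("ll_", .cross_types)
  out <- cbind(out, as.data.frame(ll))
  rownames(out) <- rownames(counts)
  out
}

#' Correct impossible offspring genotypes caused by allelic dropout
#'
#' For single-heterozygote loci the unexpected homozygote class is impossible
#' under Mendelian segregation and is corrected to the heterozygote: at AAxAB
#' loci offspring BB becomes AB; at ABxBB loci AA becomes AB; at AAxBB loci
#' both homozygote classes become AB.  ABxAB loci are left unchanged, since
#' all three genotypes are possible there.  The heterozygote count at a locus
#' can only grow.
#'
#' @param x a [rad_cross].
#' @param cross_types character vector of per-locus ML cross-types (aligned
#'   with `x$loci`), e.g. `classify_loci(...)$cross_type`.
#' @return list: `cross` with corrected calls, `n_corrected`, and `events`
#'   (data.frame locus_id, sample_id, from).
#' @export
correct_dropout_genotypes <- function(x, cross_types) {
  stopifnot(length(cross_types) == nrow(x$loci))
  off <- offspring_ids(x)
  gt <- x$gt[, off, drop = FALSE]
  fix <- matrix(FALSE, nrow(gt), ncol(gt))
  fix[cross_types == "AAxAB", ] <- gt[cross_types == "AAxAB", ] == "BB"
  fix[cross_types == "ABxBB", ] <- gt[cross_types == "ABxBB", ] == "AA"
  fix[cross_types == "AAxBB", ] <- gt[cross_types == "AAxBB", ] %in% c("AA", "BB")
  fix[is.na(fix)] <- FALSE
  ev <- which(fix, arr.ind = TRUE)
  events <- data.frame(locus_id = rownames(gt)[ev[, 1]],
                       sample_id = off[ev[, 2]],
                       from = gt[fix], stringsAsFactors = FALSE)
  gt[fix] <- "AB"
  x$gt[, off] <- gt
  list(cross = x, n_corrected = nrow(events), events = events)
}

#' Segregation-distortion test per locus
#'
#' Single-heterozygote cross-types are tested by the exact two-sided binomial
#' test of the two permitted genotype classes against 1:1 (two-sided p = sum
#' of outcome probabilities not exceeding that of the observed outcome);
#' double heterozygotes (ABxAB) by a chi-square goodness of fit against
#' 1:2:1 (df = 2).  AAxBB segregates no variation, so p = 1 by convention.
#'
#' @param counts per-locus offspring genotype counts.
#' @param cross_types aligned vector of ML cross-types.
#' @param sided `"two"` (default) or `"one"` (smaller tail, no doubling) for
#'   the binomial test.
#' @return numeric vector of p-values; `NA` (with a warning) where the
#'   relevant counts are all zero.
#' @export
test_segregation <- function(counts, cross_types, sided = c("two", "one")) {
  sided <- match.arg(sided)
  m <- if (is.null(dim(counts))) matrix(as.numeric(counts), 1) else
    as.matrix(counts)[, 1:3, drop = FALSE]
  n <- nrow(m)
  stopifnot(length(cross_types) == n)
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ct <- cross_types[i]
    if (ct == "AAxBB") { p[i] <- 1; next }
    if (ct == "ABxAB") {
      tot <- sum(m[i, ])
      if (tot == 0) next
      p[i] <- suppressWarnings(
        stats::chisq.test(m[i, ], p = c(0.25, 0.5, 0.25))$p.value)
      next
    }
    k <- if (ct == "AAxAB") m[i, c(1, 2)] else m[i, c(3, 2)]
    tot <- sum(k)
    if (tot == 0) next
    p[i] <- if (sided == "two") {
      stats::binom.test(k[1], tot, p = 0.5)$p.value
    } else {
      min(stats::pbinom(k[1], tot, 0.5),
          stats::pbinom(k[1] - 1, tot, 0.5, lower.tail = FALSE))
    }
  }
  if (anyNA(p)) warning("test_segregation: ", sum(is.na(p)),
                        " locus/loci with zero testable counts")
  p
}

#' Parent-offspring concordance filter and sex orientation
#'
#' Retains a locus iff the observed parental genotype pair is compatible with
#' the offspring-derived ML cross-type, and determines which parent is the
#' heterozygous (informative) one.  When one parent call is missing, the
#' other parent orients the locus on its own if it is compatible; when both
#' are missing the locus is retained but flagged unoriented.
#'
#' @param x a [rad_cross] (parental calls are read from it).
#' @param cross_types aligned vector of per-locus ML cross-types.
#' @return data.frame: `retained` (logical), `het_parent` in
#'   `"mother"`/`"father"`/`"both"`/`"none"`/`NA`, `unoriented` (logical).
#' @export
concordance_filter <- function(x, cross_types) {
  mg <- x$gt[, mother_id(x)]
  fg <- x$gt[, father_id(x)]
  n <- nrow(x$loci)
  retained <- rep(TRUE, n)
  het_parent <- rep(NA_character_, n)

  check_pair <- function(ct, a, b) {
    # returns c(ok, het) where het describes parent "a"'s status
    switch(ct,
      AAxAB = if (a == "AB") c(TRUE, TRUE) else c(a == "AA", FALSE),
      ABxBB = if (a == "AB") c(TRUE, TRUE) else c(a == "BB", FALSE),
      ABxAB = c(a == "AB", a == "AB"),
      AAxBB = c(a %in% c("AA", "BB"), FALSE))
  }

  for (i in seq_len(n)) {
    ct <- cross_types[i]
    m <- mg[i]; f <- fg[i]
    if (is.na(m) && is.na(f)) { het_parent[i] <- NA; next }
    if (ct == "ABxAB") {
      ok_m <- is.na(m) || m == "AB"
      ok_f <- is.na(f) || f == "AB"
      retained[i] <- ok_m && ok_f
      het_parent[i] <- if (retained[i]) "both" else NA
      next
    }
    if (ct == "AAxBB") {
      ok <- (is.na(m) || m %in% c("AA", "BB")) &&
            (is.na(f) || f %in% c("AA", "BB")) &&
            (is.na(m) || is.na(f) || m != f)
      retained[i] <- ok
      het_parent[i] <- if (ok) "none" else NA
      next
    }
    hom <- if (ct == "AAxAB") "AA" else "BB"
    m_ok <- is.na(m) || m %in% c("AB", hom)
    f_ok <- is.na(f) || f %in% c("AB", hom)
    if (!m_ok || !f_ok) { retained[i] <- FALSE; next }
    if (!is.na(m) && !is.na(f)) {
      if (m == "AB" && f == hom) het_parent[i] <- "mother"
      else if (f == "AB" && m == hom) het_parent[i] <- "father"
      else retained[i] <- FALSE      # AB/AB or hom/hom does not match the type
    } else if (!is.na(m)) {
      het_parent[i] <- if (m == "AB") "mother" else "father"
    } else {
      het_parent[i] <- if (f == "AB") "father" else "mother"
    }
  }
  data.frame(retained = retained, het_parent = het_parent,
             unoriented = retained & is.na(het_parent),
             stringsAsFactors = FALSE, row.names = x$loci$locus_id)
}
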