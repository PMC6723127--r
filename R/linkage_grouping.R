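#' Encode single-heterozygote markers as pseudo-testcross phase classes
#'
#' For a marker heterozygous in one parent and homozygous in the other, each
#' offspring falls in one of two classes: heterozygote (coded 1) or the
#' expected homozygote (coded 0).  Missing calls and (pre-correction)
#' impossible homozygotes code NA.  Recombination in the informative parent
#' is estimated from discordance between these class vectors.
#'
#' @param x a [rad_cross] after dropout correction.
#' @param cross_types aligned per-locus cross-types.
#' @param het_parent aligned `"mother"`/`"father"` orientation from
#'   [concordance_filter]; loci with any other value are skipped.
#' @param parent which parent's informative markers to encode.
#' @return integer matrix (informative loci x offspring) of 0/1/NA, rownames
#'   = locus ids.
#' @export
phase_class_matrix <- function(x, cross_types, het_parent,
                               parent = c("mother", "father")) {
  parent <- match.arg(parent)
  sel <- which(cross_types %in% c("AAxAB", "ABxBB") & !is.na(het_parent) &
                 het_parent == parent)
  gt <- x$gt[sel, offspring_ids(x), drop = FALSE]
  hom <- ifelse(cross_types[sel] == "AAxAB", "AA", "BB")
  out <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = dimnames(gt))
  out[gt == "AB"] <- 1L
  out[gt == hom[row(gt)]] <- 0L
  out
}

#' Two-point recombination fraction between two pseudo-testcross markers
#'
#' Over offspring called at both loci (n), with d the count of discordant
#' phase-class pairs, the estimate is `rf = min(d, n - d) / n`; phase is
#' coupling when `d <= n - d`, repulsion otherwise.  Fewer than `min_n`
#' co-called offspring flags the estimate unreliable.
#'
#' @param x,y integer 0/1/NA phase-class vectors (same offspring order).
#' @param parent_x,parent_y optional parent tags; differing tags are a hard
#'   error since recombination is only defined within one parent's meioses.
#' @param min_n reliability threshold on co-called offspring.
#' @return list: `rf`, `n_informative`, `phase`, `reliable`.
#' @export
pairwise_rf <- function(x, y, parent_x = NULL, parent_y = NULL, min_n = 20) {
  if (!is.null(parent_x) && !is.null(parent_y) && parent_x != parent_y) {
    stop("loci are informative in different parents; stratify by parent")
  }
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n == 0) return(list(rf = NA_real_, n_informative = 0L,
                          phase = NA_character_, reliable = FALSE))
  d <- sum(x[ok] != y[ok])
  list(rf = min(d, n - d) / n, n_informative = n,
       phase = if (d <= n - d) "coupling" else "repulsion",
       reliable = n >= min_n)
}

#' All pairwise recombination fractions among one parent's markers
#'
#' Vectorised two-point estimation for every marker pair of a phase-class
#' matrix.  Identical to looping [pairwise_rf] over all pairs.
#'
#' @param X phase-class matrix from [phase_class_matrix].
#' @param min_n reliability threshold on co-called offspring.
#' @return list of matrices: `rf` (NaN where no co-called offspring),
#'   `n` (co-called counts), `d` (discordant counts), `reliable` (logical).
#' @export
rf_matrix <- function(X, min_n = 20) {
  C <- !is.na(X)
  A <- X == 1L & C
  B <- X == 0L & C
  storage.mode(A) <- storage.mode(B) <- storage.mode(C) <- "double"
  A[is.na(A)] <- 0; B[is.na(B)] <- 0
  D <- A %*% t(B) + B %*% t(A)
  N <- C %*% t(C)
  rf <- pmin(D, N - D) / N
  list(rf = rf, n = N, d = D, reliable = N >= min_n)
}

#' Mean inter-scaffold recombination fraction matrix
#'
#' Entry (s, t) is the mean of all reliable marker-pair estimates spanning
#' scaffolds s and t, pooled over the per-parent recombination matrices
#' supplied; pairs with no reliable estimate are unknown (NA).  The diagonal
#' holds within-scaffold means.
#'
#' @param rf_list list of outputs of [rf_matrix] (one per parent).
#' @param scaffold_list parallel list of scaffold-id vectors, one entry per
#'   marker row of the corresponding matrix.
#' @param scaffolds optional character vector fixing the output scaffold set
#'   and order.
#' @return list: `rf` (square matrix, NA = unknown), `n_pairs`.
#' @export
scaffold_rf_matrix <- function(rf_list, scaffold_list, scaffolds = NULL) {
  if (is.null(scaffolds)) {
    scaffolds <- sort(unique(unlist(scaffold_list)))
  }
  S <- length(scaffolds)
  sum_rf <- matrix(0, S, S, dimnames = list(scaffolds, scaffolds))
  n_pairs <- matrix(0, S, S, dimnames = list(scaffolds, scaffolds))
  for (k in seq_along(rf_list)) {
    rfk <- rf_list[[k]]
    if (is.null(rfk) || nrow(rfk$rf) == 0) next
    use <- rfk$reliable & !is.na(rfk$rf)
    diag(use) <- FALSE                     # no self-pairs
    M <- rfk$rf
    M[!use] <- 0
    f <- factor(scaffold_list[[k]], levels = scaffolds)
    agg <- function(mat) {
      r <- rowsum(mat, f)                  # drops absent levels? no: keeps used
      r <- r[match(scaffolds, rownames(r)), , drop = FALSE]
      r[is.na(r)] <- 0
      r2 <- rowsum(t(r), f)
      r2 <- r2[match(scaffolds, rownames(r2)), , drop = FALSE]
      r2[is.na(r2)] <- 0
      t(r2)
    }
    sum_rf <- sum_rf + agg(M)
    n_pairs <- n_pairs + agg(use * 1)
  }
  rf <- sum_rf / n_pairs
  rf[n_pairs == 0] <- NA
  list(rf = rf, n_pairs = n_pairs)
}

#' Pooled scaffold-level recombination fractions from consensus phase
#'
#' Builds one consensus phase vector per scaffold and parent
#' ([scaffold_consensus_phase]), estimates phase-free discordance per parent,
#' and pools the minimised counts over both parents' meioses:
#' `rf = (sum of min(d, n - d)) / (sum of n)`.  Majority voting inside each
#' scaffold suppresses single-marker errors, so these estimates are far less
#' inflated than marker-pair averages.
#'
#' @param phase list with `mother`/`father` phase-class matrices.
#' @param loci_list per-parent loci data.frames aligned with matrix rows.
#' @param scaffolds optional scaffold set/order for the output.
#' @param min_n entries with fewer pooled co-called meioses are NA.
#' @return list: `rf`, `d` (pooled minimised discordance), `n` (pooled
#'   co-called meioses).
#' @export
pooled_scaffold_rf <- function(phase, loci_list, scaffolds = NULL,
                               min_n = 20) {
  if (is.null(scaffolds)) {
    scaffolds <- sort(unique(unlist(lapply(loci_list, function(d) d$scaffold))))
  }
  S <- length(scaffolds)
  Dp <- Np <- matrix(0, S, S, dimnames = list(scaffolds, scaffolds))
  for (par in names(phase)) {
    li <- loci_list[[par]]
    sel <- li$scaffold %in% scaffolds
    if (!any(sel)) next
    cm <- scaffold_consensus_phase(phase[[par]][sel, , drop = FALSE],
                                   li$scaffold[sel])
    rr <- rf_matrix(cm, min_n = 1)
    dmin <- pmin(rr$d, rr$n - rr$d)
    ii <- match(rownames(cm), scaffolds)
    Dp[ii, ii] <- Dp[ii, ii] + dmin
    Np[ii, ii] <- Np[ii, ii] + rr$n
  }
  rf <- Dp / Np
  rf[Np < min_n] <- NA
  list(rf = rf, d = Dp, n = Np)
}

#' Cluster scaffolds into linkage groups by single-linkage agglomeration
#'
#' Scaffolds join one linkage group whenever a chain of pairwise mean
#' recombination fractions below the threshold connects them — a scaffold is
#' grouped "with any scaffold in the group".  Unknown entries are treated as
#' unlinked.  The result equals the connected components of the graph with
#' edges `rf < threshold`.  Groups are numbered by descending total scaffold
#' length (ties by lexicographic smallest member id).
#'
#' @param scaffold_rf square mean-rf matrix from [scaffold_rf_matrix].
#' @param scaffold_index data.frame(scaffold, length) for group numbering.
#' @param threshold linkage threshold on rf (default 0.07).
#' @return data.frame: `scaffold`, `group` (integer), `group_size`.
#' @export
cluster_scaffolds <- function(scaffold_rf, scaffold_index, threshold = 0.07) {
  stopifnot(threshold > 0, threshold < 0.5)
  sc <- rownames(scaffold_rf)
  n <- length(sc)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  edges <- which(!is.na(scaffold_rf) & scaffold_rf < threshold &
                   upper.tri(scaffold_rf), arr.ind = TRUE)
  for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(n), find, integer(1))
  len <- stats::setNames(scaffold_index$length, scaffold_index$scaffold)[sc]
  len[is.na(len)] <- 0
  tot <- tapply(as.numeric(len), comp, sum)
  first <- tapply(sc, comp, min)
  ord <- order(-tot, first)
  relabel <- stats::setNames(seq_along(ord), names(tot)[ord])
  group <- relabel[as.character(comp)]
  sizes <- table(group)
  data.frame(scaffold = sc, group = as.integer(group),
             group_size = as.integer(sizes[as.character(group)]),
             stringsAsFactors = FALSE)
}

#' Flag scaffolds that look chimeric from within-scaffold linkage
#'
#' Scans each scaffold's markers in physical order for a split into two
#' contiguous blocks (each with at least two markers) that are internally
#' linked (within-block mean rf < `within_max`) yet mutually unlinked
#' (between-block mean rf > `between_min`) — the signature of an assembly
#' join across chromosomes.  Flagged scaffolds are reported, never split.
#' Scaffolds with fewer than four markers in every parent class are
#' untestable.
#'
#' @param rf_list per-parent outputs of [rf_matrix].
#' @param loci_list per-parent data.frames (locus_id, scaffold, position)
#'   aligned with the matrix rows.
#' @param within_max,between_min block linkage thresholds.
#' @return data.frame: `scaffold`, `verdict` in `"ok"`, `"flagged"`,
#'   `"untestable"`.
#' @export
flag_chimeric_scaffolds <- function(rf_list, loci_list,
                                    within_max = 0.07, between_min = 0.3) {
  scaffolds <- sort(unique(unlist(lapply(loci_list, function(d) d$scaffold))))
  verdict <- stats::setNames(rep("untestable", length(scaffolds)), scaffolds)
  for (k in seq_along(rf_list)) {
    loci <- loci_list[[k]]
    rf <- rf_list[[k]]$rf
    for (sc in unique(loci$scaffold)) {
      idx <- which(loci$scaffold == sc)
      if (length(idx) < 4) next
      idx <- idx[order(loci$position[idx])]
      m <- length(idx)
      if (verdict[sc] == "untestable") verdict[sc] <- "ok"
      sub <- rf[idx, idx, drop = FALSE]
      for (kk in 2:(m - 2)) {
        b1 <- seq_len(kk); b2 <- (kk + 1):m
        within1 <- mean(sub[b1, b1][upper.tri(sub[b1, b1])], na.rm = TRUE)
        within2 <- mean(sub[b2, b2][upper.tri(sub[b2, b2])], na.rm = TRUE)
        between <- mean(sub[b1, b2], na.rm = TRUE)
        if (!is.na(within1) && !is.na(within2) && !is.na(between) &&
            within1 < within_max && within2 < within_max &&
            between > between_min) {
          verdict[sc] <- "flagged"
          break
        }
      }
    }
  }
  data.frame(scaffold = scaffolds, verdict = unname(verdict),
             stringsAsFactors = FALSE)
}

#' Exclude loci with linkage to multiple groups
#'
#' Drops any marker whose mean reliable rf is below the threshold toward two
#' or more linkage groups, or whose own group looks unlinked (mean rf at or
#' above threshold) while another group looks linked — the missing-data
#' spurious-linkage failure mode.
#'
#' @param rfm an [rf_matrix] output for one parent's markers.
#' @param loci_scaffold scaffold id per matrix row.
#' @param groups output of [cluster_scaffolds].
#' @param threshold linkage threshold (default 0.07, as for clustering).
#' @return logical keep vector over the matrix rows.
#' @export
exclude_multigroup_loci <- function(rfm, loci_scaffold, groups,
                                    threshold = 0.07) {
  grp <- stats::setNames(groups$group, groups$scaffold)[loci_scaffold]
  n <- length(loci_scaffold)
  use <- rfm$reliable & !is.na(rfm$rf)
  diag(use) <- FALSE
  M <- rfm$rf
  M[!use] <- 0
  f <- factor(grp)
  sums <- t(rowsum(t(M), f))            # n x G sums of rf toward each group
  cnts <- t(rowsum(t(use * 1), f))
  means <- sums / cnts                   # NaN where no reliable pair
  linked <- !is.na(means) & means < threshold
  own <- cbind(seq_len(n), match(grp, levels(f)))
  own_mean <- means[own]
  own_linked <- linked[own]
  other_linked <- rowSums(linked) - own_linked
  keep <- !((own_linked + other_linked >= 2) |
              (!is.na(own_mean) & own_mean >= threshold & other_linked >= 1))
  keep
}

#' Thin markers to the k most complete per scaffold and cross-type class
#'
#' Nearby RAD markers are nearly always co-inherited and add computation, not
#' resolution; per scaffold and per parent-informative class only the `k`
#' markers with the most called offspring are kept (ties broken by position,
#' then locus id, so the result is order-invariant).
#'
#' @param loci data.frame with `locus_id`, `scaffold`, `position`,
#'   `parent_class` (e.g. het parent) and `n_called`.
#' @param k markers to keep per scaffold x class (default 5).
#' @return logical keep vector aligned with `loci` rows.
#' @export
thin_markers <- function(loci, k = 5) {
  keep <- rep(FALSE, nrow(loci))
  key <- paste(loci$scaffold, loci$parent_class)
  for (g in unique(key)) {
    idx <- which(key == g)
    o <- idx[order(-loci$n_called[idx], loci$position[idx],
                   loci$locus_id[idx])]
    keep[utils::head(o, k)] <- TRUE
  }
  keep
}

#' Align linkage phase of markers within each scaffold
#'
#' The 0/1 phase classes of two pseudo-testcross markers are only comparable
#' up to the unknown linkage phase of the heterozygous parent: whether the
#' het call travels with the same parental haplotype at both loci is
#' arbitrary per locus.  Within a scaffold, markers are essentially fully
#' linked, so the phase is resolved by majority concordance against the
#' scaffold's running consensus: a marker whose calls disagree with the
#' consensus in more than half of co-called offspring is flipped.  After
#' alignment, each scaffold's rows indicate a common parental haplotype, and
#' within-scaffold majority votes and flip detection become meaningful.
#' Recombination fractions are unaffected (the estimator is phase-free).
#'
#' @param X phase-class matrix (markers x offspring) for one parent.
#' @param loci data.frame (locus_id, scaffold, position) aligned with rows.
#' @return the phase-aligned matrix.
#' @export
align_scaffold_phase <- function(X, loci) {
  for (sc in unique(loci$scaffold)) {
    idx <- which(loci$scaffold == sc)
    if (length(idx) < 2) next
    idx <- idx[order(loci$position[idx])]
    ref <- X[idx[1], ]
    for (j in idx[-1]) {
      ok <- !is.na(ref) & !is.na(X[j, ])
      if (sum(ok) == 0) { ref <- ifelse(is.na(ref), X[j, ], ref); next }
      if (sum(ref[ok] != X[j, ok]) * 2 > sum(ok)) X[j, ] <- 1L - X[j, ]
      # running consensus: fill individuals the reference lacks
      ref <- ifelse(is.na(ref), X[j, ], ref)
    }
  }
  X
}

#' Blank isolated phase flips within scaffolds (per-genotype cleaning)
#'
#' Recombination within a scaffold is rare, so an individual's phase classes
#' along a scaffold should form at most one step; an interior marker call
#' disagreeing with both physical neighbours while they agree with each other
#' is a double crossover within a few hundred kb — overwhelmingly a
#' genotyping artifact (e.g. allelic dropout toward the permitted homozygote,
#' which no Mendelian rule can catch).  Such calls are set to missing;
#' genuine crossover steps (prefix/suffix patterns) are untouched.  All
#' comparisons use the original matrix, so cleaning is order-independent.
#'
#' @param X phase-class matrix (markers x offspring) for one parent.
#' @param loci data.frame (locus_id, scaffold, position) aligned with rows.
#' @return the cleaned matrix; number of blanked calls in attribute
#'   `n_cleaned`.
#' @export
clean_phase_singletons <- function(X, loci) {
  out <- X
  n_cleaned <- 0L
  for (sc in unique(loci$scaffold)) {
    idx <- which(loci$scaffold == sc)
    if (length(idx) < 3) next
    idx <- idx[order(loci$position[idx])]
    for (j in 2:(length(idx) - 1)) {
      a <- X[idx[j - 1], ]; b <- X[idx[j], ]; cc <- X[idx[j + 1], ]
      hit <- !is.na(a) & !is.na(b) & !is.na(cc) & a == cc & b != a
      out[idx[j], hit] <- NA_integer_
      n_cleaned <- n_cleaned + sum(hit)
    }
  }
  attr(out, "n_cleaned") <- n_cleaned
  out
}

#' Scaffold-consensus phase vectors
#'
#' Per scaffold and individual, the majority phase class over the scaffold's
#' markers (ties and all-missing give NA).  Since co-scaffold markers are
#' essentially always co-inherited, the consensus suppresses residual
#' single-marker errors and yields far less noisy scaffold-level
#' recombination estimates than averaging marker pairs.
#'
#' @param X phase-class matrix (markers x offspring).
#' @param scaffold scaffold id per row.
#' @return 0/1/NA matrix (scaffolds x offspring), rownames = scaffold ids.
#' @export
scaffold_consensus_phase <- function(X, scaffold) {
  f <- factor(scaffold)
  ones <- rowsum((X == 1L) * 1, f, na.rm = TRUE)
  called <- rowsum((!is.na(X)) * 1, f, na.rm = TRUE)
  cons <- matrix(NA_integer_, nlevels(f), ncol(X),
                 dimnames = list(levels(f), colnames(X)))
  cons[ones * 2 > called] <- 1L
  cons[ones * 2 < called & called > 0] <- 0L
  cons
}

#' Remove loci showing apparent short double-crossover events
#'
#' Within a scaffold, a marker whose phase class differs from both physical
#' neighbours in the same individual (all three called) implies two
#' crossovers within a few hundred kb — overwhelmingly a genotyping error.
#' A locus is removed when such singleton flips occur in at least
#' `min_individuals` individuals.
#'
#' @param X phase-class matrix (markers x offspring) for one parent.
#' @param loci data.frame (locus_id, scaffold, position) aligned with rows.
#' @param min_individuals removal threshold (default 1).
#' @return logical keep vector over rows.
#' @export
remove_double_crossover_loci <- function(X, loci, min_individuals = 1) {
  flips <- integer(nrow(X))
  for (sc in unique(loci$scaffold)) {
    idx <- which(loci$scaffold == sc)
    if (length(idx) < 3) next
    idx <- idx[order(loci$position[idx])]
    for (j in 2:(length(idx) - 1)) {
      a <- X[idx[j - 1], ]; b <- X[idx[j], ]; cc <- X[idx[j + 1], ]
      hit <- !is.na(a) & !is.na(b) & !is.na(cc) & a == cc & b != a
      flips[idx[j]] <- flips[idx[j]] + sum(hit)
    }
  }
  flips < min_individuals
}
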