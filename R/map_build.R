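#' Order markers within a linkage group by seriation
#'
#' Minimises the sum of adjacent recombination fractions (SARF): a greedy
#' nearest-neighbour chain is grown from the globally closest marker pair,
#' then improved by 2-opt segment reversals to a local optimum.  Unknown
#' pairwise fractions are treated as 0.5 (unlinked).  The output is
#' deterministic; its overall direction is normalised so that the
#' lexicographically smallest terminal scaffold comes first.
#'
#' @param rf square marker rf matrix (rownames = locus ids); NAs allowed.
#' @param scaffold optional scaffold id per marker, used only for direction
#'   normalisation (locus ids are used when absent).
#' @param max_moves cap on accepted 2-opt moves.
#' @return character vector of locus ids in map order.
#' @export
order_markers <- function(rf, scaffold = NULL, max_moves = 500,
                          n_starts = 12) {
  ids <- rownames(rf)
  n <- length(ids)
  if (n <= 2) return(ids)
  P <- as.matrix(rf)
  P[is.na(P)] <- 0.5
  diag(P) <- Inf
  Pf <- P
  diag(Pf) <- 0

  greedy_from <- function(chain) {
    used <- rep(FALSE, n)
    used[chain] <- TRUE
    while (length(chain) < n) {
      free <- which(!used)
      d_head <- P[chain[1], free]
      d_tail <- P[chain[length(chain)], free]
      if (min(d_head) <= min(d_tail)) {
        nx <- free[which.min(d_head)]
        chain <- c(nx, chain)
      } else {
        nx <- free[which.min(d_tail)]
        chain <- c(chain, nx)
      }
      used[nx] <- TRUE
    }
    chain
  }

  two_opt <- function(chain) {
    moves <- 0
    repeat {
      o <- chain
      Z <- matrix(0, n + 2, n + 2)
      Z[2:(n + 1), 2:(n + 1)] <- Pf[o, o]
      i <- rep(seq_len(n - 1), times = n - 1)
      j <- rep(2:n, each = n - 1)
      v <- j > i
      i <- i[v]; j <- j[v]
      delta <- Z[cbind(i, j + 1)] + Z[cbind(i + 1, j + 2)] -
        Z[cbind(i, i + 1)] - Z[cbind(j + 1, j + 2)]
      k <- which.min(delta)
      if (length(k) == 0 || delta[k] > -1e-12 || moves >= max_moves) break
      chain[i[k]:j[k]] <- rev(chain[i[k]:j[k]])
      moves <- moves + 1
    }
    chain
  }

  chain_cost <- function(o) sum(Pf[cbind(o[-n], o[-1])])

  or_opt <- function(chain) {
    # single-element best reinsertion, repeated to stability
    repeat {
      improved <- FALSE
      for (el in seq_len(n)) {
        pos <- match(el, chain)
        rest <- chain[-pos]
        base <- chain_cost(chain)
        costs <- vapply(0:(n - 1), function(at) {
          chain_cost(append(rest, el, after = at))
        }, numeric(1))
        k <- which.min(costs)
        if (costs[k] < base - 1e-12) {
          chain <- append(rest, el, after = k - 1)
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    chain
  }

  # deterministic multi-start: the globally closest pair plus the nearest-
  # neighbour chain grown from several spread-out anchors
  starts <- list()
  sp <- which(P == min(P), arr.ind = TRUE)
  sp <- sp[order(sp[, 1], sp[, 2]), , drop = FALSE][1, ]
  starts[[1]] <- c(sp[1], sp[2])
  anchors <- unique(round(seq(1, n, length.out = min(n_starts - 1, n))))
  for (a in anchors) starts[[length(starts) + 1L]] <- a

  best <- NULL
  best_cost <- Inf
  for (s in starts) {
    ch <- or_opt(two_opt(greedy_from(s)))
    cst <- chain_cost(ch)
    if (cst < best_cost - 1e-12) {
      best <- ch
      best_cost <- cst
    }
  }
  chain <- best

  key <- if (is.null(scaffold)) ids else scaffold
  if (key[chain[length(chain)]] < key[chain[1]]) chain <- rev(chain)
  ids[chain]
}

#' Order a linkage group's markers by scaffold blocks
#'
#' Treats each scaffold as a rigid block: scaffolds are seriated on their
#' mean inter-scaffold recombination fraction (the same greedy + 2-opt SARF
#' seriation as [order_markers], with far less tie degeneracy because every
#' entry averages many marker pairs), markers inside a block keep their
#' physical order, and each block's direction is chosen by exact dynamic
#' programming minimising the summed junction rf between consecutive blocks.
#' Anchoring whole scaffolds this way is what keeps co-scaffold markers
#' together when individual two-point estimates are tied or noisy.
#'
#' @param rfm an [rf_matrix] output for the group's markers (one parent).
#' @param loci data.frame (locus_id, scaffold, position) aligned with the
#'   matrix rows.
#' @param X the parent's phase-class matrix (aligned with `loci`); scaffold
#'   distances are estimated from its consensus vectors
#'   ([scaffold_consensus_phase]).
#' @param min_n reliability threshold for the scaffold-level estimates.
#' @param X_full,loci_full optional unthinned phase matrix and loci for the
#'   same parent; consensus vectors then use every cleaned marker (thinning
#'   only limits the ordering workload, not the scaffold-level evidence).
#' @return character vector of locus ids in map order.
#' @export
order_scaffold_blocks <- function(rfm, loci, X, min_n = 20,
                                  X_full = NULL, loci_full = NULL) {
  n <- nrow(loci)
  if (n <= 1) return(loci$locus_id)
  scs <- sort(unique(loci$scaffold))
  if (length(scs) == 1) {
    return(loci$locus_id[order(loci$position)])
  }
  if (!is.null(X_full)) {
    sel <- loci_full$scaffold %in% scs
    cons <- scaffold_consensus_phase(X_full[sel, , drop = FALSE],
                                     loci_full$scaffold[sel])
  } else {
    cons <- scaffold_consensus_phase(X, loci$scaffold)
  }
  crf <- rf_matrix(cons, min_n = min_n)
  # shrunken (d + 1/2)/(n + 1): low-support zeros must not beat
  # well-supported adjacencies
  srf <- (pmin(crf$d, crf$n - crf$d) + 0.5) / (crf$n + 1)
  srf[!crf$reliable] <- NA
  dimnames(srf) <- dimnames(crf$rf)
  sc_order <- seriate_scaffolds(srf)
  rf <- rfm$rf
  rownames(rf) <- colnames(rf) <- loci$locus_id
  blocks <- lapply(sc_order, function(s) {
    i <- which(loci$scaffold == s)
    loci$locus_id[i][order(loci$position[i])]
  })
  m <- length(blocks)
  jrf <- function(a, b) {
    v <- rf[a, b]
    if (is.na(v)) 0.5 else v
  }
  # chain DP over block directions (1 = physical order, 2 = reversed)
  ends <- lapply(blocks, function(b) rbind(c(b[1], b[length(b)]),
                                           c(b[length(b)], b[1])))
  cost <- matrix(0, m, 2)
  back <- matrix(1L, m, 2)
  for (i in 2:m) {
    for (d in 1:2) {
      c1 <- cost[i - 1, 1] + jrf(ends[[i - 1]][1, 2], ends[[i]][d, 1])
      c2 <- cost[i - 1, 2] + jrf(ends[[i - 1]][2, 2], ends[[i]][d, 1])
      cost[i, d] <- min(c1, c2)
      back[i, d] <- if (c1 <= c2) 1L else 2L    # prefer physical order on ties
    }
  }
  dir <- integer(m)
  dir[m] <- if (cost[m, 1] <= cost[m, 2]) 1L else 2L
  for (i in m:2) dir[i - 1] <- back[i, dir[i]]
  ord <- unlist(lapply(seq_len(m), function(i) {
    if (dir[i] == 1) blocks[[i]] else rev(blocks[[i]])
  }))
  # deterministic overall direction: smallest terminal scaffold first
  sc_of <- stats::setNames(loci$scaffold, loci$locus_id)
  if (sc_of[[ord[length(ord)]]] < sc_of[[ord[1]]]) ord <- rev(ord)
  ord
}

#' Seriate scaffolds from a recombination-distance matrix
#'
#' Global seriation for noisy, tie-rich scaffold-level distances: the matrix
#' is completed by [complete_rf_paths], converted to Haldane cM, and embedded
#' in one dimension by classical multidimensional scaling; the principal-
#' coordinate order uses every pairwise estimate at once, so scaffolds with
#' weak direct evidence are still placed by their pattern of distances to
#' the rest of the group.  Local inversions left by the embedding are then
#' polished by adjacent-swap sweeps on the sum of adjacent fractions, which
#' cannot disturb the global arrangement.
#'
#' @param m_rf square scaffold rf matrix (NAs for unknown pairs).
#' @param polish run the adjacent-swap polishing sweeps.
#' @return rownames of `m_rf` in seriated order.
#' @export
seriate_scaffolds <- function(m_rf, polish = TRUE) {
  ids <- rownames(m_rf)
  n <- length(ids)
  if (n <= 2) return(ids)
  M <- complete_rf_paths(m_rf)
  Dm <- -50 * log(1 - 2 * pmin(M, 0.45))
  diag(Dm) <- 0
  pc <- tryCatch(stats::cmdscale(Dm, k = 1)[, 1],
                 error = function(e) NULL)
  o <- if (is.null(pc) || length(unique(pc)) < 2) seq_len(n)
       else order(pc, ids)
  P <- M
  diag(P) <- 0
  cost_at <- function(o, k) {
    # adjacent-edge cost touching positions k, k+1
    s <- 0
    if (k > 1) s <- s + P[o[k - 1], o[k]]
    s <- s + P[o[k], o[k + 1]]
    if (k + 1 < n) s <- s + P[o[k + 1], o[k + 2]]
    s
  }
  while (polish) {
    improved <- FALSE
    for (k in seq_len(n - 1)) {
      base <- cost_at(o, k)
      o2 <- o
      o2[c(k, k + 1)] <- o2[c(k + 1, k)]
      if (cost_at(o2, k) < base - 1e-12) {
        o <- o2
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  ids[o]
}

#' Complete unknown recombination entries by shortest-path closure
#'
#' Two scaffolds can lack a direct estimate (e.g. one carries only maternal,
#' the other only paternal markers).  At small fractions recombination
#' distances are nearly additive, so unknown entries are filled with the
#' min-plus shortest path through known entries (capped at 0.5); entries in
#' disconnected components stay at 0.5.
#'
#' @param m square rf matrix with NAs for unknown pairs.
#' @return completed matrix.
#' @export
complete_rf_paths <- function(m) {
  D <- as.matrix(m)
  known <- !is.na(D)
  D[!known] <- Inf
  diag(D) <- 0
  n <- nrow(D)
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D[!known & is.finite(D)] <- pmin(D[!known & is.finite(D)], 0.5)
  D[is.infinite(D)] <- 0.5
  D[known] <- as.matrix(m)[known]
  D
}

#' Sum of adjacent recombination fractions of an order
#'
#' The seriation objective; exposed for tests and diagnostics.
#'
#' @param ids locus ids in order.
#' @param rf marker rf matrix.
#' @export
sarf <- function(ids, rf) {
  P <- as.matrix(rf)
  P[is.na(P)] <- 0.5
  sum(P[cbind(ids[-length(ids)], ids[-1])])
}

#' Convert adjacent recombination fractions to centimorgan positions
#'
#' Haldane (default, no interference): `d = -50 ln(1 - 2r)`; Kosambi:
#' `d = 25 ln((1 + 2r)/(1 - 2r))`.  Fractions at or above 0.5 are clamped to
#' `rf_ceiling` with a warning; unknown adjacent fractions contribute zero
#' distance.  Positions are cumulative from 0 cM.
#'
#' @param ordered_ids locus ids in map order.
#' @param rf marker rf matrix.
#' @param map_function `"haldane"` or `"kosambi"`.
#' @param rf_ceiling clamp value for rf >= 0.5.
#' @return data.frame(locus_id, cM).
#' @export
map_distances <- function(ordered_ids, rf, map_function = c("haldane", "kosambi"),
                          rf_ceiling = 0.49) {
  map_function <- match.arg(map_function)
  n <- length(ordered_ids)
  if (n == 1) return(data.frame(locus_id = ordered_ids, cM = 0))
  r <- as.matrix(rf)[cbind(ordered_ids[-n], ordered_ids[-1])]
  r[is.na(r)] <- 0
  if (any(r >= 0.5)) {
    warning("adjacent rf >= 0.5 clamped to ", rf_ceiling)
    r[r >= 0.5] <- rf_ceiling
  }
  d <- switch(map_function,
              haldane = -50 * log(1 - 2 * r),
              kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)))
  data.frame(locus_id = ordered_ids, cM = cumsum(c(0, d)))
}

#' Estimate the residual phase-error floor by split-half discordance
#'
#' Markers on one scaffold recombine essentially never, so the discordance
#' between consensus vectors built from alternating halves of a scaffold's
#' markers measures the residual per-vector error rate (dropout toward the
#' permitted homozygote and genotype errors that survive cleaning).  This
#' floor inflates every between-scaffold recombination fraction additively
#' and is subtracted before map distances are computed — the standard
#' counter to genotyping-error map expansion.
#'
#' @param X cleaned phase-class matrix for one parent.
#' @param loci data.frame (locus_id, scaffold, position) aligned with rows.
#' @return pooled floor estimate (a fraction), 0 when inestimable.
#' @export
phase_error_floor <- function(X, loci) {
  Dsum <- 0
  Nsum <- 0
  for (sc in unique(loci$scaffold)) {
    mi <- which(loci$scaffold == sc)
    if (length(mi) < 2) next
    mi <- mi[order(loci$position[mi])]
    h1 <- mi[seq(1, length(mi), 2)]
    h2 <- mi[seq(2, length(mi), 2)]
    c1 <- scaffold_consensus_phase(X[h1, , drop = FALSE],
                                   rep(sc, length(h1)))
    c2 <- scaffold_consensus_phase(X[h2, , drop = FALSE],
                                   rep(sc, length(h2)))
    ok <- !is.na(c1[1, ]) & !is.na(c2[1, ])
    d <- sum(c1[1, ok] != c2[1, ok])
    n <- sum(ok)
    Dsum <- Dsum + min(d, n - d)
    Nsum <- Nsum + n
  }
  if (Nsum == 0) 0 else Dsum / Nsum
}

#' Build the two sex-specific maps
#'
#' Markers heterozygous in exactly one parent are informative for
#' recombination in that parent alone; each parent's markers are ordered and
#' distanced independently within every linkage group.  A linkage group with
#' no markers for a parent is recorded empty.
#'
#' @param phase list with `mother` and `father` phase-class matrices
#'   ([phase_class_matrix]).
#' @param loci_list list with per-parent data.frames (locus_id, scaffold,
#'   position) aligned with matrix rows.
#' @param groups scaffold clustering from [cluster_scaffolds].
#' @param lg_ids which group ids to map (default: all groups with >= 2
#'   scaffolds).
#' @param min_n reliability threshold passed to [rf_matrix].
#' @param map_function see [map_distances].
#' @param phase_full,loci_full optional unthinned phase matrices / loci used
#'   for scaffold-level seriation evidence (see [order_scaffold_blocks]).
#' @return named list (`maternal`, `paternal`) of data.frames
#'   (lg, locus_id, scaffold, position, cM).
#' @export
build_sex_maps <- function(phase, loci_list, groups, lg_ids = NULL,
                           min_n = 20, map_function = "haldane",
                           phase_full = NULL, loci_full = NULL) {
  grp <- stats::setNames(groups$group, groups$scaffold)
  if (is.null(lg_ids)) {
    sizes <- table(groups$group)
    lg_ids <- as.integer(names(sizes)[sizes >= 2])
  }
  out <- list()
  for (par in c("mother", "father")) {
    X <- phase[[par]]
    loci <- loci_list[[par]]
    floor_par <- phase_error_floor(
      if (!is.null(phase_full)) phase_full[[par]] else X,
      if (!is.null(loci_full)) loci_full[[par]] else loci)
    rows <- list()
    for (lg in sort(lg_ids)) {
      sel <- which(grp[loci$scaffold] == lg)
      if (length(sel) == 0) next
      if (length(sel) == 1) {
        rows[[length(rows) + 1L]] <- data.frame(
          lg = lg, locus_id = loci$locus_id[sel],
          scaffold = loci$scaffold[sel], position = loci$position[sel],
          cM = 0, stringsAsFactors = FALSE)
        next
      }
      rfm <- rf_matrix(X[sel, , drop = FALSE], min_n = min_n)
      rownames(rfm$rf) <- colnames(rfm$rf) <- loci$locus_id[sel]
      ord <- order_scaffold_blocks(rfm, loci[sel, , drop = FALSE],
                                   X[sel, , drop = FALSE], min_n = min_n,
                                   X_full = phase_full[[par]],
                                   loci_full = loci_full[[par]])
      m <- match(ord, loci$locus_id)
      # cM at scaffold resolution: consensus phase vectors suppress the
      # residual per-marker error floor that would otherwise inflate every
      # marker-to-marker interval (map expansion); markers on one scaffold
      # share its cM position
      sc_seq <- rle(loci$scaffold[m])$values
      Xc <- if (!is.null(phase_full)) phase_full[[par]] else X
      lc <- if (!is.null(loci_full)) loci_full[[par]] else loci
      csel <- lc$scaffold %in% sc_seq
      cons <- scaffold_consensus_phase(Xc[csel, , drop = FALSE],
                                       lc$scaffold[csel])
      r_adj <- vapply(seq_len(max(length(sc_seq) - 1, 0)), function(k) {
        p <- pairwise_rf(cons[sc_seq[k], ], cons[sc_seq[k + 1], ])
        if (is.na(p$rf)) 0 else max(0, min(p$rf, 0.49) - floor_par)
      }, numeric(1))
      d_adj <- switch(map_function,
                      haldane = -50 * log(1 - 2 * r_adj),
                      kosambi = 25 * log((1 + 2 * r_adj) / (1 - 2 * r_adj)))
      sc_cM <- stats::setNames(cumsum(c(0, d_adj)), sc_seq)
      rows[[length(rows) + 1L]] <- data.frame(
        lg = lg, locus_id = ord, scaffold = loci$scaffold[m],
        position = loci$position[m], cM = unname(sc_cM[loci$scaffold[m]]),
        stringsAsFactors = FALSE)
    }
    map <- if (length(rows)) do.call(rbind, rows) else
      data.frame(lg = integer(), locus_id = character(),
                 scaffold = character(), position = integer(), cM = numeric())
    attr(map, "parent") <- if (par == "mother") "maternal" else "paternal"
    out[[if (par == "mother") "maternal" else "paternal"]] <- map
  }
  out
}

# per-LG scaffold summary of a sex map: mean marker cM rescaled to [0,1]
.scaffold_positions <- function(map) {
  if (nrow(map) == 0) return(data.frame(lg = integer(), scaffold = character(),
                                        pos = numeric()))
  agg <- stats::aggregate(cM ~ lg + scaffold, data = map, FUN = mean)
  out <- do.call(rbind, lapply(split(agg, agg$lg), function(d) {
    span <- max(d$cM) - min(d$cM)
    d$pos <- if (span > 0) (d$cM - min(d$cM)) / span else rep(0.5, nrow(d))
    d
  }))
  rownames(out) <- NULL
  out
}

#' Merge the sex-specific maps into a consensus scaffold map
#'
#' Equal-weight consensus across the two parents: (1) linkage groups are
#' paired across maps by maximal Jaccard overlap of scaffold content; (2)
#' when the parental phase data are supplied, each chromosome's scaffold
#' order is computed by the SARF seriation of scaffold consensus phase
#' vectors pooled over both parents' meioses — every meiosis carries equal
#' weight, and recombination breakpoints from both parents jointly resolve
#' the order; without phase data the order falls back to the mean of the
#' per-map rescaled positions (each scaffold's position in a map is the mean
#' cM of its markers, rescaled to \[0, 1\] within the linkage group), which
#' is also the tie-break between scaffolds no meiosis separates; (3) the
#' paternal group is reflected when its shared-scaffold positions
#' anticorrelate with the maternal ones; (4) orientation per scaffold is the
#' sign of the Spearman correlation between marker bp positions and
#' consensus-frame cM pooled over both maps ('?' when undefined, i.e. no
#' recombination was sampled inside the scaffold: anchored but not
#' oriented); (5) chromosome offsets accumulate scaffold lengths plus
#' `gap_length`.  A scaffold whose two maps disagree on the group pairing
#' follows the maternal map and is logged as a conflict.
#'
#' @param maps output of [build_sex_maps].
#' @param scaffold_index data.frame(scaffold, length).
#' @param gap_length inter-scaffold gap for offset bookkeeping (bp).
#' @param phase optional list with `mother`/`father` phase-class matrices
#'   (cleaned, as in the pipeline); enables pooled-meiosis ordering.
#' @param loci_list per-parent loci data.frames aligned with `phase` rows.
#' @return a [consensus_map]; conflicts attached as attribute `conflicts`,
#'   chromosome/LG correspondence as attribute `lg_table`.
#' @export
merge_maps <- function(maps, scaffold_index, gap_length = 100L,
                       phase = NULL, loci_list = NULL) {
  mat <- maps$maternal
  pat <- maps$paternal
  sp_m <- .scaffold_positions(mat)
  sp_p <- .scaffold_positions(pat)

  lgs_m <- unique(sp_m$lg)
  lgs_p <- unique(sp_p$lg)
  jac <- outer(lgs_m, lgs_p, Vectorize(function(a, b) {
    A <- sp_m$scaffold[sp_m$lg == a]
    B <- sp_p$scaffold[sp_p$lg == b]
    length(intersect(A, B)) / length(union(A, B))
  }))
  # greedy maximal-Jaccard pairing
  pair_p <- stats::setNames(rep(NA_integer_, length(lgs_m)), lgs_m)
  if (length(lgs_m) && length(lgs_p)) {
    J <- jac
    repeat {
      k <- which(J == max(J), arr.ind = TRUE)
      if (length(k) == 0 || max(J) <= 0) break
      k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]
      pair_p[as.character(lgs_m[k[1]])] <- lgs_p[k[2]]
      J[k[1], ] <- -1
      J[, k[2]] <- -1
      if (all(J < 0)) break
    }
  }

  conflicts <- character()
  chroms <- list()
  used_p <- integer()
  for (a in lgs_m) {
    b <- pair_p[[as.character(a)]]
    dm <- sp_m[sp_m$lg == a, ]
    dp <- if (!is.na(b)) sp_p[sp_p$lg == b, ] else sp_p[0, ]
    if (!is.na(b)) used_p <- c(used_p, b)
    flip_p <- FALSE
    shared <- intersect(dm$scaffold, dp$scaffold)
    if (length(shared) >= 2) {
      rho <- suppressWarnings(stats::cor(
        dm$pos[match(shared, dm$scaffold)],
        dp$pos[match(shared, dp$scaffold)], method = "spearman"))
      if (!is.na(rho) && rho < 0) flip_p <- TRUE
    }
    if (flip_p) dp$pos <- 1 - dp$pos
    sc <- union(dm$scaffold, dp$scaffold)
    score <- vapply(sc, function(s) {
      mean(c(dm$pos[match(s, dm$scaffold)], dp$pos[match(s, dp$scaffold)]),
           na.rm = TRUE)
    }, numeric(1))
    ordered <- NULL
    if (!is.null(phase) && length(sc) > 2) {
      # pooled-meiosis seriation: one consensus phase vector per scaffold
      # and parent, concatenated so each meiosis counts once
      # per-parent phase-free discordance counts, pooled over meioses
      # (phase signs are arbitrary per scaffold and parent, so the minimised
      # counts are combined rather than the raw vectors)
      psr <- pooled_scaffold_rf(phase, loci_list, scaffolds = sc, min_n = 20)
      # shrunken estimate (d + 1/2)/(n + 1): a zero over few meioses cannot
      # undercut a zero over many, which kills spurious low-support shortcuts
      m_rf <- (psr$d + 0.5) / (psr$n + 1)
      m_rf[psr$n < 20] <- NA
      ordered <- seriate_scaffolds(m_rf)
      # align the seriation direction with the maternal map frame
      rho_dir <- suppressWarnings(stats::cor(match(sc, ordered), score[sc],
                                             method = "spearman"))
      if (!is.na(rho_dir) && rho_dir < 0) ordered <- rev(ordered)
    }
    if (is.null(ordered)) ordered <- sc[order(score, sc)]

    # scaffold orientation by crossover-event reconstruction: align every
    # scaffold's consensus phase to a common chromosome frame, find meioses
    # whose flanking phases differ (a crossover in the neighbourhood), and
    # read the direction of the clean phase step across the scaffold's own
    # markers; non-monotone marker patterns (residual errors) are rejected.
    orient <- NULL
    if (!is.null(phase) && length(ordered) > 1) {
      votes <- stats::setNames(numeric(length(ordered)), ordered)
      has_vote <- stats::setNames(integer(length(ordered)), ordered)
      for (par in c("mother", "father")) {
        li <- loci_list[[par]]
        sel <- li$scaffold %in% ordered
        if (!any(sel)) next
        cm <- scaffold_consensus_phase(phase[[par]][sel, , drop = FALSE],
                                       li$scaffold[sel])
        present <- ordered[ordered %in% rownames(cm)]
        if (length(present) < 2) next
        A <- cm[present, , drop = FALSE]
        # chain-align consensus signs along the chromosome
        flip <- stats::setNames(rep(FALSE, length(present)), present)
        ref <- A[1, ]
        for (r in seq_len(nrow(A))[-1]) {
          ok <- !is.na(ref) & !is.na(A[r, ])
          if (sum(ok) > 0 && sum(ref[ok] != A[r, ok]) * 2 > sum(ok)) {
            A[r, ] <- 1L - A[r, ]
            flip[r] <- TRUE
          }
          ref <- ifelse(is.na(A[r, ]), ref, A[r, ])
        }
        for (i in seq_along(present)) {
          s <- present[i]
          mi <- which(li$scaffold == s)
          if (length(mi) < 2) next
          ord_m <- mi[order(li$position[mi])]
          Xm <- phase[[par]][ord_m, , drop = FALSE]
          if (flip[i]) Xm <- 1L - Xm
          flank <- function(vals) {
            # nearest informative flank phase, but only when the two nearest
            # agree: disagreement marks a crossover or a local ordering
            # error right next to the scaffold, where a vote is unsafe
            vals <- vals[!is.na(vals)]
            if (length(vals) == 0) return(NA_integer_)
            if (length(vals) >= 2 && vals[1] != vals[2]) return(NA_integer_)
            vals[1]
          }
          for (j in seq_len(ncol(A))) {
            lv <- if (i > 1) flank(rev(A[seq_len(i - 1), j])) else NA_integer_
            rv <- if (i < nrow(A)) flank(A[(i + 1):nrow(A), j]) else NA_integer_
            if (is.na(lv) || is.na(rv) || lv == rv) next
            v <- Xm[, j]
            v <- v[!is.na(v)]
            if (length(v) < 2) next
            if (all(v == lv) || all(v == rv)) next     # crossover outside
            up <- diff(v != lv)                        # left->right step: '+'
            dn <- diff(v != rv)                        # right->left step: '-'
            if (all(up >= 0) && sum(up) == 1) {
              votes[s] <- votes[s] + 1
              has_vote[s] <- has_vote[s] + 1L
            } else if (all(dn >= 0) && sum(dn) == 1) {
              votes[s] <- votes[s] - 1
              has_vote[s] <- has_vote[s] + 1L
            }                                          # else: noisy, reject
          }
        }
      }
      # contradictory votes mean the local order or the data are unreliable
      orient <- ifelse(has_vote > 0 & votes == has_vote, "+",
                       ifelse(has_vote > 0 & votes == -has_vote, "-", "?"))
      names(orient) <- names(has_vote) <- ordered
    }
    chroms[[as.character(a)]] <- list(
      scaffolds = ordered, lg_m = a, lg_p = b, flip_p = flip_p,
      orient = orient,
      orient_support = if (is.null(orient)) NULL else has_vote)
  }
  # paternal-only groups become their own chromosomes
  for (b in setdiff(lgs_p, used_p)) {
    dp <- sp_p[sp_p$lg == b, ]
    ord <- order(dp$pos, dp$scaffold)
    chroms[[paste0("p", b)]] <- list(scaffolds = dp$scaffold[ord],
                                     lg_m = NA_integer_, lg_p = b,
                                     flip_p = FALSE)
  }
  # a scaffold claimed by two different chromosomes follows the maternal map
  seen <- character()
  for (nm in names(chroms)) {
    dup <- intersect(chroms[[nm]]$scaffolds, seen)
    if (length(dup)) {
      conflicts <- c(conflicts, dup)
      chroms[[nm]]$scaffolds <- setdiff(chroms[[nm]]$scaffolds, dup)
    }
    seen <- c(seen, chroms[[nm]]$scaffolds)
  }

  # orientation: marker bp vs consensus-frame cM pooled over both maps
  orient_of <- function(sc, lg_m, lg_p, flip_p) {
    pts <- list()
    if (!is.na(lg_m)) {
      d <- mat[mat$lg == lg_m & mat$scaffold == sc, ]
      if (nrow(d)) pts[[1]] <- d[, c("position", "cM")]
    }
    if (!is.na(lg_p)) {
      d <- pat[pat$lg == lg_p & pat$scaffold == sc, ]
      if (nrow(d)) {
        if (flip_p) {
          span <- max(pat$cM[pat$lg == lg_p])
          d$cM <- span - d$cM
        }
        pts[[2]] <- d[, c("position", "cM")]
      }
    }
    pts <- do.call(rbind, pts)
    if (is.null(pts) || length(unique(pts$position)) < 2 ||
        length(unique(pts$cM)) < 2) return("?")
    rho <- suppressWarnings(stats::cor(pts$position, pts$cM,
                                       method = "spearman"))
    if (is.na(rho) || rho == 0) "?" else if (rho > 0) "+" else "-"
  }

  len <- stats::setNames(scaffold_index$length, scaffold_index$scaffold)
  # chromosome labels by descending anchored length
  tot <- vapply(chroms, function(ch) sum(len[ch$scaffolds], na.rm = TRUE),
                numeric(1))
  chroms <- chroms[order(-tot, names(chroms))]
  rows <- list()
  lg_table <- list()
  for (i in seq_along(chroms)) {
    ch <- chroms[[i]]
    lab <- sprintf("LG%02d", i)
    lg_table[[i]] <- data.frame(chrom = lab, maternal_lg = ch$lg_m,
                                paternal_lg = ch$lg_p,
                                paternal_reflected = ch$flip_p)
    pos <- 1L
    for (sc in ch$scaffolds) {
      L <- len[[sc]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = lab, scaffold = sc,
        orientation = if (!is.null(ch$orient)) ch$orient[[sc]] else
          orient_of(sc, ch$lg_m, ch$lg_p, ch$flip_p),
        orientation_support = if (!is.null(ch$orient_support))
          ch$orient_support[[sc]] else NA_integer_,
        start = pos, end = pos + L - 1L, stringsAsFactors = FALSE)
      pos <- pos + L + as.integer(gap_length)
    }
  }
  placements <- do.call(rbind, rows)
  unplaced <- setdiff(scaffold_index$scaffold, placements$scaffold)
  out <- consensus_map(placements, unplaced)
  attr(out, "conflicts") <- conflicts
  attr(out, "lg_table") <- do.call(rbind, lg_table)
  out
}

#' Score a consensus map against simulation truth
#'
#' Matches each consensus chromosome to the truth chromosome contributing
#' most of its scaffolds, then computes the Kendall rank correlation between
#' consensus order and true position (a linkage group's global direction is
#' unidentifiable, so the absolute value is taken and orientations are
#' compared after aligning the direction) and the fraction of oriented
#' scaffolds whose strand matches truth.
#'
#' @param map a [consensus_map].
#' @param truth_agp truth table from [fragment_genome].
#' @return list: `per_chrom` data.frame (chrom, truth_chrom, n_scaffolds,
#'   kendall_tau, orient_correct, orient_total), `mean_tau`,
#'   `orientation_accuracy`, `anchored_fraction`.
#' @export
score_consensus_map <- function(map, truth_agp) {
  pl <- map$placements
  ti <- match(pl$scaffold, truth_agp$scaffold)
  pl$truth_chrom <- truth_agp$chrom[ti]
  pl$truth_start <- truth_agp$start[ti]
  pl$truth_orient <- truth_agp$orientation[ti]
  res <- list()
  for (ch in unique(pl$chrom)) {
    d <- pl[pl$chrom == ch, ]
    tc <- names(sort(table(d$truth_chrom), decreasing = TRUE))[1]
    dd <- d[d$truth_chrom == tc, ]
    tau <- if (nrow(dd) >= 2) {
      suppressWarnings(stats::cor(seq_len(nrow(dd)), dd$truth_start,
                                  method = "kendall"))
    } else NA_real_
    reflect <- !is.na(tau) && tau < 0
    oriented <- dd$orientation != "?"
    pred <- dd$orientation[oriented]
    if (reflect) pred <- ifelse(pred == "+", "-", "+")
    ok <- sum(pred == dd$truth_orient[oriented])
    res[[ch]] <- data.frame(chrom = ch, truth_chrom = tc,
                            n_scaffolds = nrow(d),
                            kendall_tau = if (is.na(tau)) NA else abs(tau),
                            orient_correct = ok,
                            orient_total = sum(oriented),
                            stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, res)
  rownames(per) <- NULL
  list(per_chrom = per,
       mean_tau = mean(per$kendall_tau, na.rm = TRUE),
       orientation_accuracy = sum(per$orient_correct) /
         max(1, sum(per$orient_total)),
       anchored_fraction = nrow(pl) / (nrow(pl) + length(map$unplaced)))
}
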