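#' Merge one-to-one ortholog pairs with gene positions in two species
#'
#' @param pos_a,pos_b data.frames with columns `gene`, `chrom`, `start` and
#'   optionally `scaffold` (for a species whose map derives from anchored
#'   scaffolds).
#' @param pairs two-column data.frame (`gene_a`, `gene_b`) of one-to-one
#'   ortholog pairs; each gene may appear at most once.
#' @return data.frame, one row per pair found in both position tables, with
#'   `_a` / `_b` suffixed columns.
#' @export
ortholog_table <- function(pos_a, pos_b, pairs) {
  if (anyDuplicated(pairs[[1]]) || anyDuplicated(pairs[[2]])) {
    stop("ortholog pairs must be one-to-one")
  }
  ia <- match(pairs[[1]], pos_a$gene)
  ib <- match(pairs[[2]], pos_b$gene)
  ok <- !is.na(ia) & !is.na(ib)
  out <- data.frame(
    gene_a = pairs[[1]][ok], gene_b = pairs[[2]][ok],
    chrom_a = pos_a$chrom[ia[ok]], start_a = pos_a$start[ia[ok]],
    chrom_b = pos_b$chrom[ib[ok]], start_b = pos_b$start[ib[ok]],
    stringsAsFactors = FALSE)
  if (!is.null(pos_a$scaffold)) out$scaffold_a <- pos_a$scaffold[ia[ok]]
  if (!is.null(pos_b$scaffold)) out$scaffold_b <- pos_b$scaffold[ib[ok]]
  out
}

#' Assign homologous chromosomes by ortholog counts
#'
#' For every chromosome of species A, the species-B chromosome carrying the
#' most shared orthologs is its homolog (the oxford-plot majority rule); the
#' full count matrix is returned for plotting.  Ties resolve to the
#' lexicographically smaller B chromosome and are flagged.
#'
#' @param orthos output of [ortholog_table].
#' @return list: `homologs` data.frame (chrom_a, chrom_b, n_orthologs, tie),
#'   `counts` (A x B ortholog count matrix).
#' @export
assign_homologs <- function(orthos) {
  if (nrow(orthos) < 1) stop("no shared orthologs")
  counts <- table(orthos$chrom_a, orthos$chrom_b)
  hom <- lapply(rownames(counts), function(a) {
    v <- counts[a, ]
    best <- names(v)[v == max(v)]
    data.frame(chrom_a = a, chrom_b = sort(best)[1],
               n_orthologs = as.integer(max(v)),
               tie = length(best) > 1, stringsAsFactors = FALSE)
  })
  list(homologs = do.call(rbind, hom),
       counts = unclass(counts))
}

#' Count singleton and block translocations per chromosome
#'
#' A singleton is an ortholog sitting on a non-homologous B chromosome while
#' both its A-neighbours lie on the homolog; runs of two or more co-moved
#' genes count as block translocations instead.  Genes on the homolog are
#' syntenic, so `singletons + block-translocated + syntenic = shared
#' orthologs` on every chromosome.
#'
#' @param orthos output of [ortholog_table].
#' @param homologs homolog table from [assign_homologs].
#' @return data.frame per A chromosome: `n_orthologs`, `n_syntenic`,
#'   `n_singletons`, `n_block_translocated`, `n_blocks`.
#' @export
count_singletons <- function(orthos, homologs) {
  hb <- stats::setNames(homologs$chrom_b, homologs$chrom_a)
  out <- list()
  for (a in unique(orthos$chrom_a)) {
    d <- orthos[orthos$chrom_a == a, ]
    d <- d[order(d$start_a), ]
    off <- d$chrom_b != hb[[a]]
    n <- nrow(d)
    r <- rle(off)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    singles <- 0L
    block_genes <- 0L
    blocks <- 0L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      if (r$lengths[k] == 1) {
        i <- starts[k]
        # neighbours must both sit on the homolog (run structure guarantees
        # it except at the chromosome ends)
        if (i > 1 && i < n) singles <- singles + 1L
        else { blocks <- blocks + 1L; block_genes <- block_genes + 1L }
      } else {
        blocks <- blocks + 1L
        block_genes <- block_genes + r$lengths[k]
      }
    }
    out[[a]] <- data.frame(
      chrom_a = a, n_orthologs = n, n_syntenic = sum(!off),
      n_singletons = singles, n_block_translocated = block_genes,
      n_blocks = blocks, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect micro-inversion blocks on a homologous chromosome pair
#'
#' Orthologs are sorted by A position; maximal runs whose B-position rank
#' strictly decreases, of length at least `min_genes`, are reported.  Blocks
#' of fewer than three genes are indistinguishable from local ordering noise,
#' hence the default.
#'
#' @param orthos ortholog table restricted (internally) to one A chromosome
#'   and its homologous B chromosome.
#' @param chrom_a,chrom_b the chromosome pair.
#' @param min_genes minimum run length (default 3).
#' @return data.frame, one row per block: gene span indices, boundary genes,
#'   boundary scaffolds where known.
#' @export
detect_inversion_blocks <- function(orthos, chrom_a, chrom_b, min_genes = 3) {
  d <- orthos[orthos$chrom_a == chrom_a & orthos$chrom_b == chrom_b, ]
  d <- d[order(d$start_a), ]
  n <- nrow(d)
  if (n < min_genes) {
    return(data.frame(chrom_a = character(), chrom_b = character(),
                      from = integer(), to = integer(),
                      n_genes = integer(), gene_first = character(),
                      gene_last = character()))
  }
  rk <- rank(d$start_b, ties.method = "first")
  dec <- diff(rk) < 0
  blocks <- list()
  i <- 1
  while (i <= n - 1) {
    if (dec[i]) {
      j <- i
      while (j <= n - 1 && dec[j]) j <- j + 1
      if (j - i + 1 >= min_genes) {
        b <- data.frame(chrom_a = chrom_a, chrom_b = chrom_b,
                        from = i, to = j, n_genes = j - i + 1,
                        gene_first = d$gene_a[i], gene_last = d$gene_a[j],
                        stringsAsFactors = FALSE)
        if (!is.null(d$scaffold_a)) {
          b$scaffold_a_first <- d$scaffold_a[i]
          b$scaffold_a_last <- d$scaffold_a[j]
        }
        if (!is.null(d$scaffold_b)) {
          b$scaffold_b_first <- d$scaffold_b[i]
          b$scaffold_b_last <- d$scaffold_b[j]
        }
        blocks[[length(blocks) + 1L]] <- b
      }
      i <- j
    } else i <- i + 1
  }
  if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom_a = character(), chrom_b = character(),
               from = integer(), to = integer(), n_genes = integer(),
               gene_first = character(), gene_last = character())
}

# is the [from, to] gene run delimited by one scaffold's first/last mapped
# genes in the ordered gene list, within tol_genes?
.scaffold_delimited <- function(d, from, to, scaffold_col, tol_genes) {
  sc <- d[[scaffold_col]]
  if (is.null(sc)) return(FALSE)
  block_sc <- unique(sc[from:to])
  if (length(block_sc) != 1) return(FALSE)
  span <- range(which(sc == block_sc))
  abs(span[1] - from) <= tol_genes && abs(span[2] - to) <= tol_genes
}

#' Classify inversion blocks as scaffold misorientations or real inversions
#'
#' A block delimited by a single scaffold's boundary genes in species X
#' (within `tol_genes`), and co-linear in the comparison against a third
#' species, is a likely scaffold misorientation in X.  A block delimited in
#' neither species, or inverted in both comparisons, is a putative real
#' inversion; anything else is ambiguous.  Without a third species, verdicts
#' reduce to scaffold-delimited / not-delimited.
#'
#' @param orthos_ab ortholog table for species A vs B (A = focal, with
#'   `scaffold_a`; `scaffold_b` optional).
#' @param blocks output of [detect_inversion_blocks] on `orthos_ab`.
#' @param chrom_a,chrom_b the chromosome pair the blocks belong to.
#' @param orthos_ac optional ortholog table A vs third species C.
#' @param chrom_c C's homologous chromosome (required with `orthos_ac`).
#' @param tol_genes boundary tolerance in genes (default 1).
#' @param min_genes passed through to the third-species block scan.
#' @return `blocks` with columns `delimited_a`, `delimited_b`,
#'   `inverted_in_third`, `verdict`.
#' @export
classify_misorientation <- function(orthos_ab, blocks, chrom_a, chrom_b,
                                    orthos_ac = NULL, chrom_c = NULL,
                                    tol_genes = 1, min_genes = 3) {
  d <- orthos_ab[orthos_ab$chrom_a == chrom_a & orthos_ab$chrom_b == chrom_b, ]
  d <- d[order(d$start_a), ]
  third_blocks <- NULL
  if (!is.null(orthos_ac)) {
    stopifnot(!is.null(chrom_c))
    third_blocks <- detect_inversion_blocks(orthos_ac, chrom_a, chrom_c,
                                            min_genes = min_genes)
  }
  n <- nrow(blocks)
  del_a <- del_b <- inv3 <- logical(n)
  verdict <- character(n)
  for (i in seq_len(n)) {
    f <- blocks$from[i]; t <- blocks$to[i]
    del_a[i] <- .scaffold_delimited(d, f, t, "scaffold_a", tol_genes)
    del_b[i] <- .scaffold_delimited(d, f, t, "scaffold_b", tol_genes)
    if (!is.null(third_blocks)) {
      genes <- d$gene_a[f:t]
      inv3[i] <- nrow(third_blocks) > 0 && any(vapply(
        seq_len(nrow(third_blocks)), function(k) {
          dc <- orthos_ac[orthos_ac$chrom_a == chrom_a &
                            orthos_ac$chrom_b == chrom_c, ]
          dc <- dc[order(dc$start_a), ]
          g3 <- dc$gene_a[third_blocks$from[k]:third_blocks$to[k]]
          length(intersect(genes, g3)) >= max(2, length(genes) / 2)
        }, logical(1)))
    }
    # triangulation: a flip in A inverts every comparison against A and is
    # delimited by A's scaffold; a flip in B inverts only the A-B comparison
    # and is delimited by B's scaffold; a real inversion respects neither
    # scaffold boundary
    verdict[i] <- if (is.null(third_blocks)) {
      if (del_a[i] || del_b[i]) "scaffold-delimited" else "not-delimited"
    } else if (del_a[i] && !del_b[i] && inv3[i]) {
      "misorientation-in-A"
    } else if (del_b[i] && !del_a[i] && !inv3[i]) {
      "misorientation-in-B"
    } else if (!del_a[i] && !del_b[i]) {
      "putative-real-inversion"
    } else "ambiguous"
  }
  blocks$delimited_a <- del_a
  blocks$delimited_b <- del_b
  if (!is.null(third_blocks)) blocks$inverted_in_third <- inv3
  blocks$verdict <- verdict
  blocks
}
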