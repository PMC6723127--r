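test_that("two-point rf counts discordance with phase minimisation", {
  x <- c(rep(1L, 45), rep(0L, 45))
  expect_equal(pairwise_rf(x, x)$rf, 0)
  expect_equal(pairwise_rf(x, x)$phase, "coupling")
  y <- 1L - x
  expect_equal(pairwise_rf(x, y)$rf, 0)
  expect_equal(pairwise_rf(x, y)$phase, "repulsion")
  z <- x
  z[1:9] <- 1L - z[1:9]
  expect_equal(pairwise_rf(x, z)$rf, 0.1)
  expect_equal(pairwise_rf(x, z)$n_informative, 90)
  # symmetry
  expect_equal(pairwise_rf(x, z)$rf, pairwise_rf(z, x)$rf)
  # few co-called offspring flags unreliable
  w <- c(x[1:10], rep(NA, 80))
  expect_false(pairwise_rf(x, w)$reliable)
  expect_error(pairwise_rf(x, y, parent_x = "mother", parent_y = "father"),
               "stratify")
})

test_that("rf matrix equals looping the two-point estimator", {
  set.seed(4)
  X <- matrix(sample(c(0L, 1L, NA), 8 * 60, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2)), 8, 60)
  rfm <- rf_matrix(X, min_n = 20)
  for (i in 1:8) for (j in 1:8) {
    ref <- pairwise_rf(X[i, ], X[j, ])
    if (ref$n_informative > 0) {
      expect_equal(rfm$rf[i, j], ref$rf, label = paste(i, j))
      expect_equal(rfm$n[i, j], ref$n_informative)
    }
  }
})

test_that("scaffold rf matrix equals the brute-force mean over marker pairs", {
  set.seed(5)
  X <- matrix(sample(c(0L, 1L, NA), 10 * 70, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1)), 10, 70)
  scaf <- rep(c("a", "b", "c", "d", "e"), each = 2)
  rfm <- rf_matrix(X, min_n = 20)
  srf <- scaffold_rf_matrix(list(rfm), list(scaf))
  for (s1 in unique(scaf)) for (s2 in unique(scaf)) {
    if (s1 == s2) next
    vals <- c()
    for (i in which(scaf == s1)) for (j in which(scaf == s2)) {
      p <- pairwise_rf(X[i, ], X[j, ])
      if (p$reliable) vals <- c(vals, p$rf)
    }
    if (length(vals)) {
      expect_equal(srf$rf[s1, s2], mean(vals), label = paste(s1, s2))
    } else {
      expect_true(is.na(srf$rf[s1, s2]))
    }
  }
  # trivial means
  m <- matrix(c(NA, 0, 0.1, 0, NA, 0.05, 0.1, 0.05, NA), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_equal(mean(c(0.0, 0.1)), 0.05)
})

test_that("single-linkage clustering equals graph connected components", {
  sc <- c("A", "B", "C", "D", "E")
  m <- matrix(0.5, 5, 5, dimnames = list(sc, sc))
  m["A", "B"] <- m["B", "A"] <- 0.05
  m["B", "C"] <- m["C", "B"] <- 0.05
  m["A", "C"] <- m["C", "A"] <- 0.4    # chained via B regardless
  m["D", "E"] <- m["E", "D"] <- 0.3    # not linked at 0.07
  idx <- data.frame(scaffold = sc, length = c(5L, 4L, 3L, 2L, 1L))
  g <- cluster_scaffolds(m, idx, threshold = 0.07)
  expect_equal(g$group[g$scaffold %in% c("A", "B", "C")], rep(1L, 3))
  expect_equal(length(unique(g$group)), 3)      # {A,B,C}, {D}, {E}
  # numbering by descending total length: {A,B,C}=12 > {D}=2 > {E}=1
  expect_equal(g$group[g$scaffold == "D"], 2L)

  # random matrices: equality with igraph components
  skip_if_not_installed("igraph")
  set.seed(6)
  for (rep in 1:5) {
    n <- 12
    m <- matrix(runif(n * n, 0, 0.5), n, n)
    m[sample(length(m), 20)] <- NA
    m <- (m + t(m)) / 2
    dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
    idx <- data.frame(scaffold = rownames(m), length = rep(1L, n))
    g <- cluster_scaffolds(m, idx, threshold = 0.07)
    adj <- !is.na(m) & m < 0.07
    diag(adj) <- FALSE
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "max"))$membership
    # same partition (labels may differ)
    expect_equal(length(unique(g$group)), length(unique(comp)))
    cross <- table(g$group[match(names(comp), g$scaffold)], comp)
    expect_true(all(rowSums(cross > 0) == 1))
  }
})

test_that("chimeric scaffolds are flagged, short scaffolds untestable", {
  # two blocks of markers from different chromosomes glued into one scaffold
  set.seed(7)
  blockA <- matrix(rep(sample(0:1, 60, TRUE), 3), 3, 60, byrow = TRUE)
  blockB <- matrix(rep(sample(0:1, 60, TRUE), 3), 3, 60, byrow = TRUE)
  X <- rbind(blockA, blockB)
  loci <- data.frame(locus_id = paste0("m", 1:6), scaffold = "chimera",
                     position = 1:6 * 100L)
  rfm <- rf_matrix(X, min_n = 20)
  flags <- flag_chimeric_scaffolds(list(rfm), list(loci))
  expect_equal(flags$verdict[flags$scaffold == "chimera"], "flagged")
  # co-linear scaffold is ok
  X2 <- matrix(rep(sample(0:1, 60, TRUE), 4), 4, 60, byrow = TRUE)
  loci2 <- data.frame(locus_id = paste0("k", 1:4), scaffold = "clean",
                      position = 1:4 * 100L)
  flags2 <- flag_chimeric_scaffolds(list(rf_matrix(X2, 20)), list(loci2))
  expect_equal(flags2$verdict, "ok")
  # three markers cannot be evaluated
  loci3 <- loci2[1:3, ]
  flags3 <- flag_chimeric_scaffolds(list(rf_matrix(X2[1:3, ], 20)),
                                    list(loci3))
  expect_equal(flags3$verdict, "untestable")
})

test_that("loci linking to multiple groups are excluded", {
  set.seed(8)
  g1 <- sample(0:1, 80, TRUE)
  g2 <- sample(0:1, 80, TRUE)
  X <- rbind(g1, g1, g2, g2, g1)        # locus 5 sits on a group-2 scaffold
  rownames(X) <- paste0("m", 1:5)
  scaf <- c("a", "a", "b", "b", "b")
  groups <- data.frame(scaffold = c("a", "b"), group = c(1L, 2L),
                       group_size = c(1L, 1L))
  keep <- exclude_multigroup_loci(rf_matrix(X, 20), scaf, groups,
                                  threshold = 0.07)
  # locus 5: unlinked to its own group (random vs g2) but linked to group 1
  expect_false(keep[5])
  expect_true(all(keep[1:4]))
})

test_that("thinning keeps the k most complete markers per scaffold class", {
  loci <- data.frame(
    locus_id = sprintf("m%02d", 1:12), scaffold = "s",
    position = 1:12 * 10L, parent_class = "mother",
    n_called = c(90, 80, 85, 70, 88, 60, 89, 50, 87, 86, 40, 30))
  keep <- thin_markers(loci, k = 5)
  expect_equal(sum(keep), 5)
  expect_setequal(loci$locus_id[keep], c("m01", "m07", "m05", "m09", "m10"))
  # fewer than k survive untouched
  keep3 <- thin_markers(loci[1:3, ], k = 5)
  expect_equal(sum(keep3), 3)
  # order invariance
  perm <- sample.int(12)
  keep_p <- thin_markers(loci[perm, ], k = 5)
  expect_setequal(loci$locus_id[perm][keep_p], loci$locus_id[keep])
})

test_that("double-crossover loci are detected and removed", {
  base <- rep(0L, 30)
  X <- rbind(base, base, base)
  X[2, 7] <- 1L                     # singleton flip at the middle locus
  loci <- data.frame(locus_id = c("a", "b", "c"), scaffold = "s",
                     position = c(10L, 20L, 30L))
  keep <- remove_double_crossover_loci(X, loci, min_individuals = 1)
  expect_equal(unname(keep), c(TRUE, FALSE, TRUE))
  # all-concordant scaffold: nothing removed
  X2 <- rbind(base, base, base)
  expect_true(all(remove_double_crossover_loci(X2, loci)))
})

test_that("phase alignment and singleton cleaning recover scaffold coherence", {
  set.seed(9)
  hap <- sample(0:1, 50, TRUE)
  # three markers of one scaffold with random per-locus phase signs
  X <- rbind(hap, 1L - hap, hap)
  rownames(X) <- c("a", "b", "c")
  loci <- data.frame(locus_id = c("a", "b", "c"), scaffold = "s",
                     position = c(1L, 2L, 3L))
  A <- align_scaffold_phase(X, loci)
  expect_equal(unname(A[2, ]), unname(A[1, ]))
  expect_equal(unname(A[3, ]), unname(A[1, ]))
  # an isolated flip is blanked, a genuine step is preserved
  B <- rbind(hap, hap, hap)
  B[2, 5] <- 1L - B[2, 5]
  cleaned <- clean_phase_singletons(B, loci)
  expect_true(is.na(cleaned[2, 5]))
  expect_equal(attr(cleaned, "n_cleaned"), 1L)
  step <- rbind(rep(0L, 10), c(rep(0L, 5), rep(1L, 5)), rep(1L, 10))
  expect_equal(sum(is.na(clean_phase_singletons(step, loci))), 0)
})

test_that("scaffold consensus phase takes the majority and NAs ties", {
  X <- rbind(c(1L, 0L, 1L, NA), c(1L, 0L, 0L, NA), c(1L, 0L, 1L, 1L))
  cons <- scaffold_consensus_phase(X, rep("s", 3))
  expect_equal(unname(cons["s", ]), c(1L, 0L, 1L, 1L))
  X2 <- rbind(c(1L, NA), c(0L, NA))
  cons2 <- scaffold_consensus_phase(X2, rep("t", 2))
  expect_true(all(is.na(cons2)))
})
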