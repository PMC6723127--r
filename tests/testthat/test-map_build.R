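# noise-free rf matrix for markers at known cM positions (Haldane)
rf_from_positions <- function(pos_cM) {
  n <- length(pos_cM)
  m <- outer(pos_cM, pos_cM, function(a, b) (1 - exp(-2 * abs(a - b) / 100)) / 2)
  dimnames(m) <- list(paste0("m", seq_len(n)), paste0("m", seq_len(n)))
  m
}

test_that("seriation recovers a noise-free linear order (brute force oracle)", {
  pos <- c(0, 7, 15, 30)
  rf <- rf_from_positions(pos)
  perm <- c(3, 1, 4, 2)
  rf_p <- rf[perm, perm]
  found <- order_markers(rf_p)
  # brute force over all 4! orders: the true order (or reversal) minimises
  # the sum of adjacent fractions
  perms <- rbind(
    expand.grid(1:4, 1:4, 1:4, 1:4))
  best <- Inf
  ids <- rownames(rf_p)
  for (r in seq_len(nrow(perms))) {
    o <- as.integer(perms[r, ])
    if (length(unique(o)) < 4) next
    s <- sarf(ids[o], rf_p)
    if (s < best) best <- s
  }
  expect_equal(sarf(found, rf_p), best, tolerance = 1e-12)
  expect_true(identical(found, paste0("m", 1:4)) ||
                identical(found, paste0("m", 4:1)))
  # two markers: unique order
  expect_equal(length(order_markers(rf[1:2, 1:2])), 2)
  # 2-opt never worsens the seriation objective relative to the input order
  expect_lte(sarf(found, rf_p), sarf(ids, rf_p))
})

test_that("map distances follow the chosen map function", {
  rf <- matrix(0, 3, 3, dimnames = list(paste0("m", 1:3), paste0("m", 1:3)))
  rf["m1", "m2"] <- rf["m2", "m1"] <- 0.2
  rf["m2", "m3"] <- rf["m3", "m2"] <- 0.01
  d <- map_distances(c("m1", "m2", "m3"), rf)
  expect_equal(d$cM[1], 0)
  expect_equal(d$cM[2], -50 * log(0.6))            # 25.54
  expect_equal(d$cM[2], 25.54, tolerance = 1e-3)
  expect_equal(d$cM[3] - d$cM[2], -50 * log(0.98)) # ~1.01: near-linear
  expect_equal(d$cM[3] - d$cM[2], 1.01, tolerance = 1e-2)
  dk <- map_distances(c("m1", "m2"), rf, map_function = "kosambi")
  expect_equal(dk$cM[2], 25 * log(1.4 / 0.6))
  # r = 0 contributes 0 cM; r >= 0.5 is clamped with a warning
  rf["m1", "m2"] <- rf["m2", "m1"] <- 0.5
  expect_warning(map_distances(c("m1", "m2"), rf), "clamped")
})

test_that("path completion fills unknown entries additively", {
  m <- matrix(NA_real_, 3, 3, dimnames = list(c("a", "b", "c"),
                                              c("a", "b", "c")))
  diag(m) <- 0
  m["a", "b"] <- m["b", "a"] <- 0.1
  m["b", "c"] <- m["c", "b"] <- 0.15
  out <- complete_rf_paths(m)
  expect_equal(out["a", "c"], 0.25)
  expect_equal(out["a", "b"], 0.1)     # known entries untouched
})

test_that("scaffold-block ordering keeps blocks intact and in order", {
  # two scaffolds, three markers each, one crossover individual between them
  set.seed(10)
  hapL <- sample(0:1, 60, TRUE)
  hapR <- hapL
  flips <- sample(60, 12)
  hapR[flips] <- 1L - hapR[flips]
  X <- rbind(matrix(rep(hapL, 3), 3, byrow = TRUE),
             matrix(rep(hapR, 3), 3, byrow = TRUE))
  loci <- data.frame(locus_id = paste0("m", 1:6),
                     scaffold = rep(c("a", "b"), each = 3),
                     position = rep(c(10L, 20L, 30L), 2))
  rfm <- rf_matrix(X, min_n = 20)
  rownames(rfm$rf) <- colnames(rfm$rf) <- loci$locus_id
  ord <- order_scaffold_blocks(rfm, loci, X, min_n = 20)
  sc_seq <- loci$scaffold[match(ord, loci$locus_id)]
  expect_equal(rle(sc_seq)$lengths, c(3L, 3L))   # blocks stay contiguous
})

test_that("sex maps are built per parent and LG with cumulative cM", {
  sim <- small_sim()
  res <- run_pipeline(sim$cross, sim$scaffold_index, sim$depth_table,
                      verbose = FALSE)
  for (m in res$sex_maps) {
    expect_true(all(c("lg", "locus_id", "scaffold", "cM") %in% names(m)))
    for (lg in unique(m$lg)) {
      cM <- m$cM[m$lg == lg]
      expect_equal(cM[1], 0)
      expect_true(all(diff(cM) >= 0))
    }
  }
  # a locus heterozygous in both parents is in neither map
  expect_false(any(res$classification$cross_type[
    match(res$sex_maps$maternal$locus_id, rownames(res$classification))] ==
      "ABxAB"))
})

test_that("merging a map with itself reproduces its scaffold order", {
  map <- data.frame(
    lg = rep(1L, 6), locus_id = paste0("m", 1:6),
    scaffold = rep(c("s1", "s2", "s3"), each = 2),
    position = rep(c(10L, 90L), 3),
    cM = c(0, 1, 5, 6, 11, 12))
  idx <- data.frame(scaffold = c("s1", "s2", "s3"),
                    length = c(100L, 100L, 100L))
  cm <- merge_maps(list(maternal = map, paternal = map), idx)
  expect_equal(cm$placements$scaffold, c("s1", "s2", "s3"))
  # bp and cM increasing together means '+'
  expect_equal(cm$placements$orientation, rep("+", 3))
  # offsets accumulate lengths plus gaps
  expect_equal(cm$placements$start, c(1L, 201L, 401L))
})

test_that("anchored plus unplaced lengths conserve the assembly", {
  sim <- small_sim()
  res <- run_pipeline(sim$cross, sim$scaffold_index, sim$depth_table,
                      verbose = FALSE)
  len <- setNames(sim$scaffold_index$length, sim$scaffold_index$scaffold)
  tot <- sum(len[res$consensus$placements$scaffold]) +
    sum(len[res$consensus$unplaced])
  expect_equal(tot, sum(sim$scaffold_index$length))
  s <- map_summary(res, sim$scaffold_index)
  expect_equal(s$value[s$statistic == "bases_anchored"] +
                 s$value[s$statistic == "bases_unplaced"],
               sum(sim$scaffold_index$length))
})

test_that("scaffold present in only one map is still anchored", {
  mat <- data.frame(lg = 1L, locus_id = c("a1", "b1"),
                    scaffold = c("s1", "s2"), position = c(10L, 10L),
                    cM = c(0, 4))
  pat <- data.frame(lg = 1L, locus_id = c("a2", "c1"),
                    scaffold = c("s1", "s3"), position = c(20L, 10L),
                    cM = c(0, 6))
  idx <- data.frame(scaffold = c("s1", "s2", "s3"), length = rep(50L, 3))
  cm <- merge_maps(list(maternal = mat, paternal = pat), idx)
  expect_setequal(cm$placements$scaffold, c("s1", "s2", "s3"))
  expect_equal(length(cm$unplaced), 0)
})

test_that("sex-map lengths are on the simulated genetic-map scale", {
  sim <- small_sim()
  res <- run_pipeline(sim$cross, sim$scaffold_index, sim$depth_table,
                      verbose = FALSE)
  true_lg_cM <- sim$config$chromosome_length_bp / 1e6 * sim$config$cM_per_Mb
  lens <- c(tapply(res$sex_maps$maternal$cM, res$sex_maps$maternal$lg, max),
            tapply(res$sex_maps$paternal$cM, res$sex_maps$paternal$lg, max))
  # error-floor correction keeps lengths near truth, not inflated many-fold
  expect_lt(mean(lens), 3 * true_lg_cM)
  expect_gt(mean(lens), true_lg_cM / 4)
})
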