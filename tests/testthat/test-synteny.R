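# toy two-species gene sets: n chromosomes, genes evenly spaced
toy_positions <- function(chroms, genes_per = 10, species = "A",
                          scaffold_every = NULL) {
  out <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(gene = sprintf("%s_%s_g%02d", species, ch, 1:genes_per),
               chrom = ch, start = (1:genes_per) * 1000L,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(scaffold_every)) {
    out$scaffold <- paste0(out$chrom, "_sc",
                           (seq_len(nrow(out)) - 1) %/% scaffold_every + 1)
  }
  out
}

identity_pairs <- function(pos_a, pos_b) {
  data.frame(gene_a = pos_a$gene, gene_b = pos_b$gene,
             stringsAsFactors = FALSE)
}

test_that("homolog assignment follows the majority ortholog count", {
  a <- toy_positions(c("A1", "A2"))
  b <- toy_positions(c("B1", "B2"), species = "B")
  ortho <- ortholog_table(a, b, identity_pairs(a, b))
  res <- assign_homologs(ortho)
  expect_equal(res$homologs$chrom_b, c("B1", "B2"))
  expect_false(any(res$homologs$tie))
  # 60/40 split: majority wins, both counts visible in the matrix
  b2 <- b
  b2$chrom[1:4] <- "B2"                 # move 4 of A1's partners to B2
  ortho2 <- ortholog_table(a, b2, identity_pairs(a, b2))
  res2 <- assign_homologs(ortho2)
  expect_equal(res2$homologs$chrom_b[res2$homologs$chrom_a == "A1"], "B1")
  expect_equal(unname(res2$counts["A1", c("B1", "B2")]), c(6L, 4L))
  expect_error(ortholog_table(a, b, rbind(identity_pairs(a, b),
                                          identity_pairs(a, b))),
               "one-to-one")
})

test_that("singleton and block translocations partition the orthologs", {
  a <- toy_positions("A1", genes_per = 12)
  b <- toy_positions("B1", genes_per = 12, species = "B")
  pairs <- identity_pairs(a, b)
  hom <- data.frame(chrom_a = "A1", chrom_b = "B1")
  # fully syntenic: nothing translocated
  s0 <- count_singletons(ortholog_table(a, b, pairs), hom)
  expect_equal(s0$n_singletons, 0)
  expect_equal(s0$n_syntenic, 12)
  # one interior gene moved: a singleton
  b1 <- b
  b1$chrom[5] <- "B9"
  s1 <- count_singletons(ortholog_table(a, b1, pairs), hom)
  expect_equal(s1$n_singletons, 1)
  expect_equal(s1$n_block_translocated, 0)
  # three consecutive genes moved: one block, no singletons
  b3 <- b
  b3$chrom[5:7] <- "B9"
  s3 <- count_singletons(ortholog_table(a, b3, pairs), hom)
  expect_equal(s3$n_singletons, 0)
  expect_equal(s3$n_block_translocated, 3)
  expect_equal(s3$n_blocks, 1)
  # partition: singletons + block-translocated + syntenic = total
  for (s in list(s0, s1, s3)) {
    expect_equal(s$n_singletons + s$n_block_translocated + s$n_syntenic,
                 s$n_orthologs)
  }
})

test_that("inversion blocks are maximal decreasing runs of rank", {
  a <- toy_positions("A1", genes_per = 6)
  b <- toy_positions("B1", genes_per = 6, species = "B")
  # B order 1,2,5,4,3,6: one inverted block of 3
  b$start <- c(1000L, 2000L, 5000L, 4000L, 3000L, 6000L)
  ortho <- ortholog_table(a, b, identity_pairs(a, b))
  blocks <- detect_inversion_blocks(ortho, "A1", "B1", min_genes = 3)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$from, 3)
  expect_equal(blocks$to, 5)
  # co-linear: no blocks; full reversal: one block spanning all genes
  b_lin <- toy_positions("B1", genes_per = 6, species = "B")
  expect_equal(nrow(detect_inversion_blocks(
    ortholog_table(a, b_lin, identity_pairs(a, b_lin)), "A1", "B1")), 0)
  b_rev <- b_lin
  b_rev$start <- rev(b_rev$start)
  brev <- detect_inversion_blocks(
    ortholog_table(a, b_rev, identity_pairs(a, b_rev)), "A1", "B1")
  expect_equal(nrow(brev), 1)
  expect_equal(brev$n_genes, 6)
})

test_that("reversing the comparator genome mirrors the block set", {
  set.seed(12)
  a <- toy_positions("A1", genes_per = 15)
  b <- toy_positions("B1", genes_per = 15, species = "B")
  b$start[6:9] <- rev(b$start[6:9])
  ortho <- ortholog_table(a, b, identity_pairs(a, b))
  fwd <- detect_inversion_blocks(ortho, "A1", "B1")
  b_flip <- b
  b_flip$start <- max(b$start) + 1000L - b$start
  ortho_f <- ortholog_table(a, b_flip, identity_pairs(a, b_flip))
  rev_blocks <- detect_inversion_blocks(ortho_f, "A1", "B1")
  # the inverted segment becomes co-linear and vice versa: the whole
  # chromosome minus the original block is now decreasing
  expect_equal(nrow(fwd), 1)
  expect_gte(nrow(rev_blocks), 1)
  expect_gt(sum(rev_blocks$n_genes), 15 - fwd$n_genes - 2)
})

# a misorientation fixture: A carries scaffolds; flipping one scaffold's
# gene order in A inverts that block in every comparison against A
misorientation_fixture <- function(flip_in = c("A", "B")) {
  flip_in <- match.arg(flip_in)
  # scaffold grids are staggered so a flip is delimited in one species only
  a <- toy_positions("A1", genes_per = 12,
                     scaffold_every = if (flip_in == "A") 4 else 5)
  b <- toy_positions("B1", genes_per = 12, species = "B",
                     scaffold_every = if (flip_in == "B") 4 else 5)
  c3 <- toy_positions("C1", genes_per = 12, species = "C")
  if (flip_in == "A") {
    a$start[5:8] <- rev(a$start[5:8])    # scaffold A1_sc2 misoriented
  } else {
    b$start[5:8] <- rev(b$start[5:8])    # scaffold B1_sc2 misoriented
  }
  list(a = a, b = b, c = c3,
       ab = ortholog_table(a, b, identity_pairs(a, b)),
       ac = ortholog_table(a, c3, identity_pairs(a, c3)))
}

test_that("triangulation attributes misorientations to the right species", {
  fx <- misorientation_fixture("A")
  blocks <- detect_inversion_blocks(fx$ab, "A1", "B1")
  expect_equal(nrow(blocks), 1)
  cls <- classify_misorientation(fx$ab, blocks, "A1", "B1",
                                 orthos_ac = fx$ac, chrom_c = "C1")
  expect_equal(cls$verdict, "misorientation-in-A")
  fx_b <- misorientation_fixture("B")
  blocks_b <- detect_inversion_blocks(fx_b$ab, "A1", "B1")
  cls_b <- classify_misorientation(fx_b$ab, blocks_b, "A1", "B1",
                                   orthos_ac = fx_b$ac, chrom_c = "C1")
  expect_equal(cls_b$verdict, "misorientation-in-B")
  # without a third species, verdicts reduce to delimitation
  cls_nc <- classify_misorientation(fx$ab, blocks, "A1", "B1")
  expect_equal(cls_nc$verdict, "scaffold-delimited")
})

test_that("blocks respecting no scaffold boundary are putative inversions", {
  a <- toy_positions("A1", genes_per = 12, scaffold_every = 4)
  b <- toy_positions("B1", genes_per = 12, species = "B", scaffold_every = 4)
  c3 <- toy_positions("C1", genes_per = 12, species = "C")
  # inversion spanning half of scaffold 1 and half of scaffold 2 in A
  a$start[3:6] <- rev(a$start[3:6])
  c3$start[3:6] <- rev(c3$start[3:6])    # C agrees with A: inversion is real
  ab <- ortholog_table(a, b, identity_pairs(a, b))
  ac <- ortholog_table(a, c3, identity_pairs(a, c3))
  blocks <- detect_inversion_blocks(ab, "A1", "B1")
  cls <- classify_misorientation(ab, blocks, "A1", "B1",
                                 orthos_ac = ac, chrom_c = "C1")
  expect_equal(cls$verdict, "putative-real-inversion")
})
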