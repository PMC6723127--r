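test_that("rad_cross validates its invariants", {
  x <- tiny_cross()
  expect_s3_class(x, "rad_cross")
  expect_equal(n_offspring(x), 4)
  expect_equal(mother_id(x), "mom")
  bad <- x$loci
  bad$ref <- bad$alt
  expect_error(rad_cross(bad, x$samples, x$ref_depth, x$alt_depth, x$gt),
               "identical")
  two_moms <- x$samples
  two_moms$role[2] <- "mother"
  expect_error(rad_cross(x$loci, two_moms, x$ref_depth, x$alt_depth, x$gt),
               "mother")
})

test_that("VCF reader keeps biallelic SNPs, applies missing-data conventions", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "mom", "dad", "o1"), collapse = "\t"),
    "s1\t10\t.\tA\tC\t.\t.\t.\tGT:AD\t0/0:9,0\t0/1:5,6\t1/1:0,7",
    "s1\t20\t.\tA\tC,G\t.\t.\t.\tGT:AD\t0/0:9,0\t0/0:8,0\t0/0:7,0",
    "s1\t30\t.\tAT\tA\t.\t.\t.\tGT:AD\t0/0:9,0\t0/0:8,0\t0/0:7,0",
    "s1\t40\t.\tA\tG\t.\t.\t.\tGT:AD\t./.\t0/1:4,4\t0/0:6,0"),
    vcf)
  x <- suppressMessages(read_vcf_biallelic(vcf, mother = "mom", father = "dad"))
  expect_equal(nrow(x$loci), 2)          # triallelic + indel skipped
  expect_equal(attr(x, "n_skipped"), 2)
  expect_equal(unname(x$gt[1, ]), c("AA", "AB", "BB"))
  # "./." without AD -> MISSING with zero depths
  expect_true(is.na(x$gt[2, "mom"]))
  expect_equal(unname(x$ref_depth[2, "mom"]), 0L)
  expect_error(read_vcf_biallelic(vcf, mother = "nope", father = "dad"),
               "not in VCF header")
})

test_that("simulator VCF round-trips exactly", {
  sim <- small_sim()
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$cross, path, seed = 42)
  x <- read_vcf_biallelic(path, mother = "mother", father = "father")
  expect_identical(x$ref_depth, sim$cross$ref_depth)
  expect_identical(x$alt_depth, sim$cross$alt_depth)
  expect_identical(x$gt, sim$cross$gt)
  expect_identical(x$loci$scaffold, sim$cross$loci$scaffold)
})

test_that("depth table reader streams chunks and skips malformed lines", {
  path <- tempfile()
  lines <- sprintf("s%d\t%d\t%d", rep(1:4, each = 25), 1:100, 100 + 1:100)
  lines[13] <- "s1 10 NA"
  lines[57] <- "brokenline"
  writeLines(lines, path)
  expect_warning(read_depth_table(path, chunk_size = 7L), "2 malformed")
  dt <- suppressWarnings(read_depth_table(path, chunk_size = 7L))
  expect_equal(nrow(dt), 98)
  expect_equal(attr(dt, "n_skipped"), 2)
  expect_equal(dt$depth[1], 101L)
  # chunk size must not change the result
  dt2 <- suppressWarnings(read_depth_table(path, chunk_size = 100000L))
  expect_equal(dt$depth, dt2$depth)
})

test_that("AGP writer tiles objects and round-trips order and orientation", {
  cm <- consensus_map(
    data.frame(chrom = "chr1", scaffold = c("A", "B"),
               orientation = c("+", "-"), stringsAsFactors = FALSE),
    unplaced = "C")
  idx <- data.frame(scaffold = c("A", "B", "C"), length = c(100L, 50L, 30L))
  path <- tempfile(fileext = ".agp")
  write_agp(cm, idx, path, gap_length = 100L)
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  # A(100) + gap(100) + B(50) -> object length 250, 3 parts
  chr1 <- tab[tab$V1 == "chr1", ]
  expect_equal(nrow(chr1), 3)
  expect_equal(max(chr1$V3), 250)
  expect_equal(chr1$V5, c("W", "U", "W"))
  expect_equal(chr1$V9[1], "+")
  expect_equal(chr1$V9[3], "-")
  # single-scaffold object for the unplaced scaffold, no gaps
  expect_equal(sum(tab$V1 == "C"), 1)
  back <- read_agp(path)
  expect_equal(back$placements$scaffold, cm$placements$scaffold)
  expect_equal(back$placements$orientation, cm$placements$orientation)
  expect_equal(back$unplaced, "C")
})

test_that("single-scaffold chromosome gives one W record and no gap", {
  cm <- consensus_map(data.frame(chrom = "chr1", scaffold = "A",
                                 orientation = "+", stringsAsFactors = FALSE))
  idx <- data.frame(scaffold = "A", length = 70L)
  path <- tempfile()
  write_agp(cm, idx, path)
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$V5, "W")
})

test_that("GFF liftover reflects minus scaffolds and preserves length", {
  cm <- consensus_map(
    data.frame(chrom = "chr1", scaffold = c("plus", "minus"),
               orientation = c("+", "-"),
               start = c(1L, 201L), end = c(100L, 300L),
               stringsAsFactors = FALSE),
    unplaced = "loose")
  idx <- data.frame(scaffold = c("plus", "minus", "loose"),
                    length = c(100L, 100L, 50L))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "minus\tt\tgene\t10\t20\t.\t+\t.\tID=g1",
               "plus\tt\tgene\t10\t20\t.\t+\t.\tID=g2",
               "loose\tt\tgene\t5\t15\t.\t-\t.\tID=g3",
               "plus\tt\tgene\t90\t120\t.\t+\t.\tID=too_long"), gff)
  expect_warning(liftover_gff(gff, cm, idx), "skipped 1")
  out <- suppressWarnings(liftover_gff(gff, cm, idx))
  d <- as.data.frame(out)
  g1 <- d[d$ID == "g1", ]
  # reflection on a 100 bp '-' scaffold at offset 200: [10,20] -> [281,291]
  expect_equal(g1$start, 281)
  expect_equal(g1$end, 291)
  expect_equal(as.character(g1$strand), "-")
  g2 <- d[d$ID == "g2", ]
  expect_equal(c(g2$start, g2$end), c(10, 20))    # identity placement
  g3 <- d[d$ID == "g3", ]
  expect_equal(g3$liftover_status, "unplaced")
  expect_equal(c(g3$start, g3$end), c(5, 15))
  # feature lengths preserved for both orientations
  expect_equal(g1$end - g1$start, 10)
  expect_equal(g2$end - g2$start, 10)
})
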