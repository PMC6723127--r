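#' Configuration for the synthetic F1 RAD-seq cross
#'
#' Defines the study conditions the simulator emulates: a 90-offspring outbred
#' F1 family genotyped by RAD-seq on a 24-chromosome genome fragmented into
#' scaffolds, with pooled tag depth centred near 1000 reads, coverage
#' inflation in repetitive regions, and heterozygote allelic dropout at rate
#' `2 * dropout_e`.
#'
#' Chromosome length defaults to 5 Mb — a deliberate scale-down of the ~35 Mb
#' killifish chromosome so that a full simulated genome remains small — while
#' the genome-wide recombination rate keeps its empirical value of
#' 2.34 cM/Mb.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length_bp length of each chromosome (bp).
#' @param n_scaffolds_per_chromosome scaffolds each chromosome is fragmented into.
#' @param n_offspring offspring in the F1 family.
#' @param rad_sites_per_scaffold integer range `c(min, max)`; the number of
#'   RAD marker sites per scaffold is drawn uniformly from it.
#' @param cM_per_Mb genome-wide recombination rate.
#' @param dropout_e per-direction heterozygote dropout probability; a true
#'   heterozygote is observed homozygous with total probability `2 * dropout_e`.
#' @param mean_tag_depth mean pooled read depth per RAD locus.
#' @param depth_cv coefficient of variation of the per-locus tag efficiency
#'   (log-normal across loci).
#' @param depth_dispersion negative-binomial size of per-genotype depth.
#' @param parent_depth_mult relative sequencing effort per parent (the mapping
#'   family design runs each parent on multiple barcodes).
#' @param repeat_fraction fraction of loci falling in repetitive regions.
#' @param repeat_depth_mult pooled-depth multiplier for repeat loci.
#' @param genotype_error_rate probability that a called genotype is replaced
#'   by a uniformly chosen different call.
#' @param p_single_het probability a locus is heterozygous in exactly one
#'   parent (split evenly between mother and father).
#' @param p_double_het probability a locus is heterozygous in both parents.
#' @param p_aabb probability of an aa x bb locus (remainder of the three).
#' @param p_hom_ref among single-het loci, probability the homozygous parent
#'   is reference-homozygous (reference bias: alt alleles tend to be rarer).
#' @param seed RNG seed governing all randomness of a simulation run.
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 24,
                       chromosome_length_bp = 5e6,
                       n_scaffolds_per_chromosome = 20,
                       n_offspring = 90,
                       rad_sites_per_scaffold = c(5, 10),
                       cM_per_Mb = 2.34,
                       dropout_e = 0.05,
                       mean_tag_depth = 1000,
                       depth_cv = 0.25,
                       depth_dispersion = 8,
                       parent_depth_mult = 3,
                       repeat_fraction = 0.02,
                       repeat_depth_mult = 30,
                       genotype_error_rate = 0.002,
                       p_single_het = 0.6,
                       p_double_het = 0.3,
                       p_aabb = 0.1,
                       p_hom_ref = 0.75,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$dropout_e >= 0, cfg$dropout_e <= 0.5,
            cfg$cM_per_Mb > 0,
            cfg$n_chromosomes >= 1, cfg$n_scaffolds_per_chromosome >= 1,
            cfg$n_offspring >= 1, length(cfg$rad_sites_per_scaffold) == 2,
            abs(cfg$p_single_het + cfg$p_double_het + cfg$p_aabb - 1) < 1e-9)
  class(cfg) <- "sim_config"
  cfg
}

#' Fragment a chromosome-level genome into shuffled scaffolds
#'
#' Partitions each chromosome into contiguous scaffolds with Dirichlet-random
#' lengths, then shuffles scaffold identity across the genome and flips each
#' scaffold with probability 0.5, defining the "assembly" coordinate frame an
#' unmapped draft assembly would present.  The truth AGP records the inverse
#' mapping.
#'
#' @param cfg a [sim_config]. Uses the current RNG state; seed once per run.
#' @return list with `scaffold_index` (data.frame scaffold, length) and
#'   `truth_agp` (data.frame chrom, start, end, scaffold, orientation, length).
#' @export
fragment_genome <- function(cfg) {
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  rows <- list()
  for (ch in chroms) {
    k <- cfg$n_scaffolds_per_chromosome
    w <- stats::rgamma(k, shape = 5, rate = 1)      # Dirichlet(5,...,5)
    lens <- floor(w / sum(w) * cfg$chromosome_length_bp)
    lens[1] <- lens[1] + cfg$chromosome_length_bp - sum(lens)
    lens <- pmax(lens, 1L)
    start <- cumsum(c(1, utils::head(lens, -1)))
    rows[[ch]] <- data.frame(chrom = ch, start = as.integer(start),
                             end = as.integer(start + lens - 1),
                             length = as.integer(lens),
                             stringsAsFactors = FALSE)
  }
  agp <- do.call(rbind, rows)
  n <- nrow(agp)
  # assembly identity: shuffled names, random orientation
  agp$scaffold <- sprintf("scaf%04d", sample.int(n))
  agp$orientation <- sample(c("+", "-"), n, replace = TRUE)
  rownames(agp) <- NULL
  idx <- agp[order(agp$scaffold), c("scaffold", "length")]
  rownames(idx) <- NULL
  list(scaffold_index = idx,
       truth_agp = agp[, c("chrom", "start", "end", "scaffold",
                           "orientation", "length")])
}

#' Map scaffold-local positions to true chromosome coordinates
#'
#' Applies the truth AGP of [fragment_genome]: the inverse of the assembly
#' fragmentation.  For a `-` scaffold the local coordinate is reflected.
#'
#' @param scaffold,position parallel vectors of scaffold ids and 1-based
#'   scaffold-local positions.
#' @param truth_agp truth table from [fragment_genome].
#' @return data.frame(chrom, chrom_pos).
#' @export
scaffold_to_chrom <- function(scaffold, position, truth_agp) {
  i <- match(scaffold, truth_agp$scaffold)
  if (anyNA(i)) stop("unknown scaffold in truth AGP lookup")
  minus <- truth_agp$orientation[i] == "-"
  pos <- ifelse(minus,
                truth_agp$end[i] - position + 1L,
                truth_agp$start[i] + position - 1L)
  data.frame(chrom = truth_agp$chrom[i], chrom_pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

# draw per-locus parental cross-types and phased parent genotypes
.draw_parents <- function(n, cfg) {
  cat3 <- sample(c("single", "double", "aabb"), n, replace = TRUE,
                 prob = c(cfg$p_single_het, cfg$p_double_het, cfg$p_aabb))
  het_parent <- ifelse(cat3 == "single",
                       sample(c("mother", "father"), n, replace = TRUE),
                       ifelse(cat3 == "double", "both", "none"))
  hom_allele <- ifelse(stats::runif(n) < cfg$p_hom_ref, 0L, 1L)  # 0 = ref (a)
  # haplotypes: columns h1,h2 per parent; 0 = a (ref), 1 = b (alt)
  m1 <- m2 <- f1 <- f2 <- integer(n)
  het_phase_m <- sample(0:1, n, replace = TRUE)
  het_phase_f <- sample(0:1, n, replace = TRUE)
  is_m_het <- het_parent %in% c("mother", "both")
  is_f_het <- het_parent %in% c("father", "both")
  m1[is_m_het] <- het_phase_m[is_m_het]
  m2[is_m_het] <- 1L - het_phase_m[is_m_het]
  f1[is_f_het] <- het_phase_f[is_f_het]
  f2[is_f_het] <- 1L - het_phase_f[is_f_het]
  hom_m <- !is_m_het
  hom_f <- !is_f_het
  m1[hom_m] <- m2[hom_m] <- hom_allele[hom_m]
  f1[hom_f] <- f2[hom_f] <- hom_allele[hom_f]
  # aa x bb: parents fixed for opposite alleles
  ab <- cat3 == "aabb"
  m1[ab] <- m2[ab] <- 0L
  f1[ab] <- f2[ab] <- 1L
  data.frame(het_parent = het_parent, m1 = m1, m2 = m2, f1 = f1, f2 = f2)
}

#' Simulate pedigree genotypes for an F1 family with known truth
#'
#' RAD marker sites are placed along each scaffold; parental genotypes are
#' drawn so that all informative cross-types (aa x ab, ab x aa, ab x ab,
#' aa x bb) occur; gametes are generated by a Poisson crossover process (no
#' interference, rate `cM_per_Mb / 100` Morgans per Mb) along the true
#' chromosome coordinate, matching the Haldane map function used by the
#' estimator.
#'
#' @param cfg a [sim_config].
#' @param genome output of [fragment_genome].
#' @return list: `truth` (loci table with parental phase, cross-type, repeat
#'   flags; crossover positions per meiosis; truth AGP) and `gt_true`, the
#'   error-free genotype matrix (loci x samples, parents first).
#' @export
simulate_pedigree_genotypes <- function(cfg, genome) {
  agp <- genome$truth_agp
  site_range <- seq(cfg$rad_sites_per_scaffold[1],
                    cfg$rad_sites_per_scaffold[2])
  loci <- do.call(rbind, lapply(seq_len(nrow(agp)), function(i) {
    k <- if (length(site_range) == 1) site_range else sample(site_range, 1)
    k <- min(k, agp$length[i])
    pos <- sort(sample.int(agp$length[i], k))
    data.frame(scaffold = agp$scaffold[i], position = pos,
               stringsAsFactors = FALSE)
  }))
  cc <- scaffold_to_chrom(loci$scaffold, loci$position, agp)
  loci$chrom <- cc$chrom
  loci$chrom_pos <- cc$chrom_pos
  loci$locus_id <- sprintf("%s_%07d", loci$scaffold, loci$position)
  loci <- loci[order(loci$chrom, loci$chrom_pos), ]
  rownames(loci) <- NULL
  n <- nrow(loci)
  loci <- cbind(loci, .draw_parents(n, cfg))
  loci$repeat_region <- stats::runif(n) < cfg$repeat_fraction

  rate_bp <- cfg$cM_per_Mb / 1e8       # Morgans per bp
  n_off <- cfg$n_offspring
  hap_m <- hap_f <- matrix(0L, n, n_off)  # which parental haplotype (0/1) transmitted
  xo <- list()
  for (ch in unique(loci$chrom)) {
    li <- which(loci$chrom == ch)
    pos <- loci$chrom_pos[li]
    L <- max(agp$end[agp$chrom == ch])
    for (par in c("m", "f")) {
      for (j in seq_len(n_off)) {
        k <- stats::rpois(1, L * rate_bp)
        cuts <- if (k > 0) sort(stats::runif(k, 0, L)) else numeric()
        start <- sample(0:1, 1)
        hap <- (start + findInterval(pos, cuts)) %% 2L
        if (par == "m") hap_m[li, j] <- hap else hap_f[li, j] <- hap
        if (k > 0) xo[[length(xo) + 1L]] <-
          data.frame(chrom = ch, parent = ifelse(par == "m", "mother", "father"),
                     offspring = j, position = cuts, stringsAsFactors = FALSE)
      }
    }
  }
  allele_m <- ifelse(hap_m == 0L, loci$m1, loci$m2)
  allele_f <- ifelse(hap_f == 0L, loci$f1, loci$f2)
  nb <- allele_m + allele_f
  gt_off <- matrix(c("AA", "AB", "BB")[nb + 1L], n, n_off)
  gt_code <- function(h1, h2) c("AA", "AB", "BB")[h1 + h2 + 1L]
  gt_true <- cbind(gt_code(loci$m1, loci$m2), gt_code(loci$f1, loci$f2), gt_off)
  samples <- c("mother", "father", sprintf("off%02d", seq_len(n_off)))
  dimnames(gt_true) <- list(loci$locus_id, samples)
  crossovers <- if (length(xo)) do.call(rbind, xo)
                else data.frame(chrom = character(), parent = character(),
                                offspring = integer(), position = numeric())
  list(truth = list(loci = loci, crossovers = crossovers, truth_agp = agp,
                    hap_m = hap_m, hap_f = hap_f),
       gt_true = gt_true)
}

#' Simulate read depths and observed genotype calls
#'
#' Per-genotype total depth is negative-binomial around a per-locus log-normal
#' tag efficiency.  With probability `2 * dropout_e` a true heterozygote
#' suffers allelic dropout: one allele (uniformly chosen) contributes no
#' reads, so the genotype is sequenced like a homozygote and observed as
#' one; other heterozygotes sample both alleles (truncated binomial split),
#' making `2 * dropout_e` exactly the total het-to-homozygote rate — the
#' quantity the downstream multinomial model estimates.  Repeat-region loci have
#' their depth inflated by `repeat_depth_mult`.  Observed call: AB if both
#' alleles have >= 1 read, otherwise the homozygote of the seen allele;
#' zero depth is missing.  `genotype_error_rate` finally flips calls uniformly.
#' Dropout is applied to offspring genotypes; each parent is sequenced at
#' `parent_depth_mult` times the per-offspring effort (multi-barcode parents),
#' where dropout is negligible.
#'
#' @param ped output of [simulate_pedigree_genotypes].
#' @param cfg a [sim_config].
#' @return list: `cross` (a [rad_cross] of observed data), `depth_table`
#'   (pooled per-site depth), `dropout_events`, `error_events`.
#' @export
simulate_read_depths <- function(ped, cfg) {
  loci <- ped$truth$loci
  gt_true <- ped$gt_true
  n <- nrow(gt_true)
  n_off <- cfg$n_offspring
  n_s <- n_off + 2L
  w <- c(rep(cfg$parent_depth_mult, 2), rep(1, n_off))
  w <- w / sum(w)
  sdlog <- sqrt(log(1 + cfg$depth_cv^2))
  lam <- stats::rlnorm(n, log(cfg$mean_tag_depth) - sdlog^2 / 2, sdlog)
  lam[loci$repeat_region] <- lam[loci$repeat_region] * cfg$repeat_depth_mult
  mu <- outer(lam, w)
  d <- matrix(as.integer(stats::rnbinom(n * n_s, mu = mu,
                                        size = cfg$depth_dispersion)),
              n, n_s)

  het <- gt_true == "AB"
  # allelic dropout: offspring hets only; direction uniform
  drop <- matrix(FALSE, n, n_s)
  drop[, 3:n_s] <- het[, 3:n_s] &
    matrix(stats::runif(n * n_off) < 2 * cfg$dropout_e, n, n_off)
  drop_dir <- matrix(sample(c("ref", "alt"), n * n_s, replace = TRUE), n, n_s)

  ref_d <- matrix(0L, n, n_s)
  # non-dropout hets sample both alleles: truncated binomial split, so the
  # dropout parameter e is exactly the total het-to-homozygote rate (the
  # model the estimator fits); a het with < 2 reads cannot show both
  # alleles and is recorded as a sampling dropout
  hh <- het & !drop
  hh2 <- hh & d >= 2
  dd <- d[hh2]
  u <- stats::runif(sum(hh2), stats::pbinom(0, dd, 0.5),
                    stats::pbinom(dd - 1, dd, 0.5))
  ref_d[hh2] <- as.integer(stats::qbinom(u, dd, 0.5))
  low <- hh & d < 2
  drop[low] <- TRUE
  ref_d[gt_true == "AA"] <- d[gt_true == "AA"]
  ref_d[drop & drop_dir == "ref"] <- d[drop & drop_dir == "ref"]
  alt_d <- d - ref_d

  obs <- matrix(NA_character_, n, n_s)
  obs[ref_d > 0 & alt_d > 0] <- "AB"
  obs[ref_d > 0 & alt_d == 0] <- "AA"
  obs[ref_d == 0 & alt_d > 0] <- "BB"

  # uniform genotype-call errors on called cells
  called <- which(!is.na(obs))
  err <- called[stats::runif(length(called)) < cfg$genotype_error_rate]
  if (length(err)) {
    cur <- obs[err]
    obs[err] <- vapply(cur, function(g) sample(setdiff(c("AA", "AB", "BB"), g), 1), "")
  }

  samples <- data.frame(
    sample_id = colnames(gt_true),
    role = c("mother", "father", rep("offspring", n_off)),
    stringsAsFactors = FALSE)
  loci_df <- data.frame(locus_id = loci$locus_id, scaffold = loci$scaffold,
                        position = loci$position, ref = "A", alt = "C",
                        stringsAsFactors = FALSE)
  cross <- rad_cross(loci_df, samples, ref_d, alt_d, obs)

  ev <- which(drop & !is.na(obs) & obs != "AB", arr.ind = TRUE)
  dropout_events <- data.frame(
    locus_id = loci$locus_id[ev[, 1]],
    sample_id = colnames(gt_true)[ev[, 2]],
    direction = drop_dir[ev], stringsAsFactors = FALSE)
  err_idx <- arrayInd(err, dim(obs))
  error_events <- data.frame(
    locus_id = loci$locus_id[err_idx[, 1]],
    sample_id = colnames(gt_true)[err_idx[, 2]], stringsAsFactors = FALSE)
  depth_table <- data.frame(scaffold = loci$scaffold, position = loci$position,
                            depth = as.integer(rowSums(d)),
                            stringsAsFactors = FALSE)
  list(cross = cross, depth_table = depth_table,
       dropout_events = dropout_events, error_events = error_events)
}

#' Simulate a complete F1 RAD-seq dataset with ground truth
#'
#' Master generator: seeds the RNG once from `cfg$seed`, then fragments the
#' genome, simulates the pedigree and the read data.
#'
#' @param cfg a [sim_config].
#' @return list: `cross`, `depth_table`, `scaffold_index`, `truth` (loci with
#'   phases and cross-types, crossovers, truth AGP, true genotypes, dropout
#'   and error events), `config`.
#' @export
simulate_f1_cross <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  genome <- fragment_genome(cfg)
  ped <- simulate_pedigree_genotypes(cfg, genome)
  reads <- simulate_read_depths(ped, cfg)
  truth <- ped$truth
  truth$gt_true <- ped$gt_true
  truth$dropout_events <- reads$dropout_events
  truth$error_events <- reads$error_events
  list(cross = reads$cross, depth_table = reads$depth_table,
       scaffold_index = genome$scaffold_index, truth = truth, config = cfg)
}

#' Write a simulated dataset to disk in the pipeline's file formats
#'
#' Emits the VCF, depth table, scaffold index, truth AGP and truth locus
#' table; every file records the generating seed in a header comment.
#'
#' @param sim output of [simulate_f1_cross].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- sim$config$seed
  paths <- c(vcf = file.path(dir, "family.vcf"),
             depth = file.path(dir, "depth.tsv"),
             scaffolds = file.path(dir, "scaffolds.tsv"),
             truth_agp = file.path(dir, "truth.agp"),
             truth_loci = file.path(dir, "truth_loci.tsv"))
  write_vcf(sim$cross, paths["vcf"], seed = seed)
  hdr <- function(path) writeLines(paste0("# radmapr seed=", seed), path)
  hdr(paths["depth"])
  utils::write.table(sim$depth_table, paths["depth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  write_scaffold_index(sim$scaffold_index, paths["scaffolds"])
  tm <- consensus_map(
    data.frame(chrom = sim$truth$truth_agp$chrom,
               scaffold = sim$truth$truth_agp$scaffold,
               orientation = sim$truth$truth_agp$orientation,
               stringsAsFactors = FALSE))
  write_agp(tm, sim$scaffold_index, paths["truth_agp"], gap_length = 100L)
  hdr(paths["truth_loci"])
  suppressWarnings(utils::write.table(sim$truth$loci, paths["truth_loci"],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     append = TRUE))
  invisible(paths)
}
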