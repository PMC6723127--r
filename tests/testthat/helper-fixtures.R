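# Hand-built miniature F1 cross: 4 loci x (2 parents + 4 offspring).
# Depths chosen so that individual filter rules can be probed exactly.
tiny_cross <- function() {
  loci <- data.frame(
    locus_id = paste0("L", 1:4),
    scaffold = c("s1", "s1", "s2", "s2"),
    position = c(10L, 50L, 5L, 40L),
    ref = "A", alt = "C", stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = c("mom", "dad", paste0("o", 1:4)),
    role = c("mother", "father", rep("offspring", 4)),
    stringsAsFactors = FALSE)
  ref <- matrix(10L, 4, 6)
  alt <- matrix(10L, 4, 6)
  gt <- matrix("AB", 4, 6)
  rad_cross(loci, samples, ref, alt, gt)
}

# deterministic small simulated dataset, shared across test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_f1_cross(sim_config(n_chromosomes = 2, seed = 42))
    }
    cache
  }
})

# brute-force two-sided exact binomial p-value: sum of outcome probabilities
# not exceeding that of the observed outcome
binom_two_sided_brute <- function(x, n, p = 0.5) {
  probs <- stats::dbinom(0:n, n, p)
  sum(probs[probs <= probs[x + 1] + 1e-12])
}
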