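# Small deterministic fixtures shared across test files.

tiny_map <- function(n = 4L, chrom = 1L, spacing = 1000L,
                     panel = rep("BOTH", n)) {
  marker_map(sprintf("m%02d", seq_len(n)), rep(chrom, n),
             spacing * seq_len(n), panel)
}

tiny_genotypes <- function() {
  calls <- rbind(
    c(0L, 1L, 2L, NA),
    c(1L, 1L, 0L, 2L),
    c(2L, 0L, 1L, 1L)
  )
  genotype_matrix(calls, animal_ids = c("a1", "a2", "a3"),
                  marker_ids = sprintf("m%02d", 1:4))
}

# three-generation family: two founders, their two offspring, one grandchild
family_pedigree <- function() {
  pedigree(
    animal_id = c("s", "d", "o1", "o2", "g"),
    sire_id = c(NA, NA, "s", "s", "o1"),
    dam_id = c(NA, NA, "d", "d", "o2"),
    sex = c("M", "F", "M", "F", "M"),
    birth_year = c(0L, 0L, 1L, 1L, 2L)
  )
}

small_sim_config <- function(...) {
  defaults <- list(
    n_founders = 30L, n_generations = 3L, progeny_per_sire_mean = 2.5,
    n_chromosomes = 1L, markers_per_chromosome_hd = 200L,
    fraction_shared_50k = 0.1, chromosome_length_bp = 7e5,
    missing_rate = 0, genotype_error_rate = 0, n_mismapped = 0L,
    seed = 7L
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

fast_icfg <- function(...) {
  defaults <- list(n_phasing_iterations = 8L, seed = 5L)
  do.call(imputation_config, utils::modifyList(defaults, list(...)))
}

# brute-force r-squared from explicit haplotype counting (independent oracle)
r2_oracle <- function(a, b) {
  n <- length(a)
  pa <- sum(a == 1) / n
  pb <- sum(b == 1) / n
  pab <- sum(a == 1 & b == 1) / n
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}
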