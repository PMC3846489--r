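test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_founders = 0), "n_founders")
  expect_error(sim_config(markers_per_chromosome_hd = 0), "markers_per")
  expect_error(sim_config(markers_per_chromosome_hd = 10,
                          fraction_shared_50k = 0.1), ">= 2")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
})

test_that("two founders and one marker give a 4 x 1 binary panel", {
  cfg <- sim_config(n_founders = 2L, n_generations = 1L, n_chromosomes = 1L,
                    markers_per_chromosome_hd = 1L, fraction_shared_50k = 1,
                    seed = 1L)
  h <- simulate_founder_haplotypes(cfg)
  expect_identical(dim(unclass(h)), c(4L, 1L))
  expect_true(all(unclass(h) %in% 0:1))
})

test_that("ld_strength = 0 gives independent sites at the 1/(2n-1) floor", {
  cfg <- sim_config(n_founders = 50L, n_generations = 1L, n_chromosomes = 1L,
                    markers_per_chromosome_hd = 400L, fraction_shared_50k = 0.1,
                    ld_strength = 0, seed = 2L)
  h <- simulate_founder_haplotypes(cfg)
  a <- unclass(h)
  p <- colMeans(a)
  ok <- pmin(p, 1 - p) >= 0.1
  cols <- which(ok)
  # brute-force oracle: r2 of independently permuted columns has the same
  # null expectation as the generator's non-adjacent pairs
  set.seed(3)
  null_r2 <- replicate(2000, {
    i <- sample(cols, 2)
    r2_oracle(sample(a[, i[1]]), a[, i[2]])
  })
  pairs <- replicate(2000, {
    i <- sort(sample(cols, 2))
    if (i[2] - i[1] < 5) return(NA_real_) # keep clearly non-adjacent pairs
    r2_oracle(a[, i[1]], a[, i[2]])
  })
  expect_equal(mean(pairs, na.rm = TRUE), mean(null_r2),
               tolerance = 0.25) # Monte-Carlo slack around 1/(2n-1) ~ 0.0101
  expect_equal(mean(pairs, na.rm = TRUE), 1 / (2 * 50 - 1), tolerance = 0.25)
})

test_that("LD decays with distance and hits the dairy 70-kb window", {
  cfg <- sim_config(n_chromosomes = 1L, seed = 4L)
  h <- simulate_founder_haplotypes(cfg)
  map <- make_marker_map(cfg)
  curve <- ld_decay(h, map, max_dist_bp = 2e5)
  dense <- curve[curve$n_pairs >= 1000, ]
  expect_true(all(diff(dense$mean_r2) <= 0))
  ld70 <- ld_at(curve)
  expect_gte(ld70, 0.16)
  expect_lte(ld70, 0.26)
})

test_that("pedigree structure matches the configured family sizes", {
  cfg <- sim_config(n_founders = 300L, n_generations = 2L,
                    progeny_per_sire_mean = 2.30, n_chromosomes = 1L,
                    markers_per_chromosome_hd = 10L, fraction_shared_50k = 0.2,
                    seed = 5L)
  ped <- generate_pedigree(cfg)
  founders <- ped[ped$birth_year == 0L, ]
  expect_identical(nrow(founders), 300L)
  expect_true(all(is.na(founders$sire_id)))
  kids <- ped[ped$birth_year == 1L, ]
  sires <- founders$animal_id[founders$sex == "M"] # 150 sires
  per_sire <- as.vector(table(factor(kids$sire_id, levels = sires)))
  expect_gte(mean(per_sire), 2.30 * 0.8)
  expect_lte(mean(per_sire), 2.30 * 1.2)
  # parents born strictly before offspring
  i <- match(kids$sire_id, ped$animal_id)
  expect_true(all(ped$birth_year[i] < kids$birth_year))
  # single-generation configuration: founders only
  ped1 <- generate_pedigree(sim_config(n_founders = 10L, n_generations = 1L))
  expect_identical(nrow(ped1), 10L)
  expect_true(all(is.na(ped1$sire_id) & is.na(ped1$dam_id)))
})

test_that("gene drop is Mendelian-consistent at every marker", {
  sim <- simulate_breed(small_sim_config())
  g <- unclass(sim$genotypes)
  ped <- sim$pedigree
  for (side in c("sire_id", "dam_id")) {
    links <- ped[!is.na(ped[[side]]), ]
    gp <- g[links[[side]], , drop = FALSE]
    go <- g[links$animal_id, , drop = FALSE]
    conflicts <- (gp == 0L & go == 2L) | (gp == 2L & go == 0L)
    expect_identical(sum(conflicts), 0L)
  }
})

test_that("offspring copy whole parental haplotypes when the map is short", {
  # a 1000-bp chromosome has ~1e-5 Morgan: crossovers essentially impossible
  cfg <- sim_config(n_founders = 6L, n_generations = 2L, n_chromosomes = 1L,
                    markers_per_chromosome_hd = 50L, fraction_shared_50k = 0.1,
                    chromosome_length_bp = 1000L, missing_rate = 0,
                    genotype_error_rate = 0, seed = 6L)
  founders <- simulate_founder_haplotypes(cfg)
  ped <- generate_pedigree(cfg)
  sim <- gene_drop(founders, ped, cfg)
  h <- unclass(sim$truth_haplotypes)
  kids <- ped$animal_id[!is.na(ped$sire_id)]
  for (kid in kids) {
    prow <- ped[ped$animal_id == kid, ]
    paternal <- h[paste0(kid, "_1"), ]
    parental <- h[paste0(prow$sire_id, c("_1", "_2")), , drop = FALSE]
    expect_true(any(apply(parental, 1, identical, y = paternal)))
  }
})

test_that("allele-frequency drift matches binomial sampling variance", {
  # one generation of random mating from 250 founders: the change in allele
  # frequency has variance ~ p(1-p)/(2N); Monte-Carlo oracle over 60 runs
  n_founders <- 250L
  deltas <- list()
  for (seed in 1:60) {
    cfg <- sim_config(n_founders = n_founders, n_generations = 2L,
                      progeny_per_sire_mean = 2, n_chromosomes = 1L,
                      markers_per_chromosome_hd = 25L, fraction_shared_50k = 0.2,
                      ld_strength = 0, missing_rate = 0,
                      genotype_error_rate = 0, seed = seed)
    founders <- simulate_founder_haplotypes(cfg)
    ped <- generate_pedigree(cfg)
    sim <- gene_drop(founders, ped, cfg)
    kids <- ped$animal_id[ped$birth_year == 1L]
    g <- unclass(sim$genotypes)
    p0 <- colMeans(g[ped$animal_id[ped$birth_year == 0L], ]) / 2
    p1 <- colMeans(g[kids, ]) / 2
    n_kids <- length(kids)
    # standardise so every marker/run is comparable: var(std) ~ 1
    deltas[[seed]] <- (p1 - p0) / sqrt(p0 * (1 - p0) / (2 * n_kids))
  }
  z <- unlist(deltas)
  expect_equal(mean(z), 0, tolerance = 0.15)
  expect_equal(stats::var(z), 1, tolerance = 0.35)
})

test_that("artifact injection hits its configured rates and bookkeeping", {
  cfg <- small_sim_config()
  sim0 <- simulate_breed(cfg)
  expect_identical(unclass(sim0$genotypes)[, ],
                   unclass(panel_to_genotypes(sim0$truth_haplotypes))[, ])
  big <- sim_config(n_founders = 300L, n_generations = 2L, n_chromosomes = 1L,
                    markers_per_chromosome_hd = 200L, fraction_shared_50k = 0.1,
                    missing_rate = 0.1, genotype_error_rate = 0, seed = 8L)
  sim <- simulate_breed(big)
  n_calls <- length(unclass(sim$genotypes))
  expect_gt(n_calls, 1e5)
  miss <- mean(is.na(unclass(sim$genotypes)))
  expect_gte(miss, 0.094) # binomial 99% interval around 0.1
  expect_lte(miss, 0.106)
})

test_that("mismapping swaps positions without touching genotype values", {
  cfg <- sim_config(n_founders = 20L, n_generations = 2L, n_chromosomes = 2L,
                    markers_per_chromosome_hd = 300L, fraction_shared_50k = 0.1,
                    chromosome_length_bp = 3e7, missing_rate = 0,
                    genotype_error_rate = 0, n_mismapped = 50L, seed = 9L)
  founders <- simulate_founder_haplotypes(cfg)
  ped <- generate_pedigree(cfg)
  clean <- gene_drop(founders, ped, cfg)
  sim <- inject_artifacts(clean, cfg)
  expect_identical(length(sim$mismapped_ids), 50L)
  expect_true(all(sim$mismapped_ids %in% sim$map$marker_id))
  # positions permuted for exactly the recorded markers
  pos_clean <- stats::setNames(clean$map$position_bp, clean$map$marker_id)
  pos_new <- stats::setNames(sim$map$position_bp, sim$map$marker_id)
  chr_clean <- stats::setNames(clean$map$chromosome, clean$map$marker_id)
  chr_new <- stats::setNames(sim$map$chromosome, sim$map$marker_id)
  moved <- names(pos_new)[pos_clean[names(pos_new)] != pos_new |
                            chr_clean[names(pos_new)] != chr_new]
  expect_setequal(moved, sim$mismapped_ids)
  # genotype content untouched, column order aside
  mk <- colnames(clean$genotypes)
  expect_identical(unclass(subset_genotypes(sim$genotypes, markers = mk))[, ],
                   unclass(clean$genotypes)[, ])
})

test_that("panel extraction returns a nested 50K subset", {
  cfg <- sim_config(n_founders = 10L, n_generations = 1L, n_chromosomes = 1L,
                    markers_per_chromosome_hd = 1000L,
                    fraction_shared_50k = 0.05, seed = 10L)
  sim <- simulate_breed(cfg)
  panels <- extract_panels(sim)
  expect_identical(ncol(panels$k50), 50L)
  expect_true(all(colnames(panels$k50) %in% colnames(panels$hd)))
  shared <- colnames(panels$k50)
  expect_identical(unclass(panels$hd)[, shared], unclass(panels$k50)[, ])
  # full sharing: the two panels coincide
  cfg1 <- sim_config(n_founders = 5L, n_generations = 1L, n_chromosomes = 1L,
                     markers_per_chromosome_hd = 20L, fraction_shared_50k = 1,
                     seed = 11L)
  p1 <- extract_panels(simulate_breed(cfg1))
  expect_identical(unclass(p1$hd)[, ], unclass(p1$k50)[, ])
})

test_that("identical configurations reproduce bit-identical datasets", {
  cfg <- small_sim_config(missing_rate = 0.01, genotype_error_rate = 0.01,
                          n_mismapped = 4L)
  a <- simulate_breed(cfg)
  b <- simulate_breed(cfg)
  expect_identical(unclass(a$genotypes)[, ], unclass(b$genotypes)[, ])
  expect_identical(unclass(a$truth_haplotypes)[, ],
                   unclass(b$truth_haplotypes)[, ])
  expect_identical(as.data.frame(a$map), as.data.frame(b$map))
  expect_identical(a$mismapped_ids, b$mismapped_ids)
})
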