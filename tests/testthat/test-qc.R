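# independent enumeration oracle for the exact Hardy-Weinberg test:
# normalised products of binomial coefficients over all heterozygote counts
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n1 <- 2 * n_bb + n_ab
  n1 <- min(n1, 2 * n - n1)
  if (n1 == 0) return(1)
  hets <- seq(n1 %% 2, n1, by = 2)
  w <- vapply(hets, function(h) {
    hom_min <- (n1 - h) / 2
    exp(lchoose(n, hom_min) + lchoose(n - hom_min, h) + h * log(2))
  }, numeric(1))
  p <- w / sum(w)
  obs <- p[hets == n_ab]
  sum(p[p <= obs * (1 + 1e-12)])
}

test_that("exact Hardy-Weinberg test matches enumeration oracle", {
  expect_equal(hwe_exact_test(25, 50, 25), 1.0, tolerance = 1e-12)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-3)
  expect_equal(hwe_exact_test(17, 0, 0), 1.0)
  expect_equal(hwe_exact_test(0, 0, 9), 1.0)
  set.seed(1)
  for (i in 1:25) {
    counts <- as.vector(stats::rmultinom(1, size = sample(5:80, 1),
                                         prob = c(0.3, 0.4, 0.3)))
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                 hwe_oracle(counts[1], counts[2], counts[3]),
                 tolerance = 1e-10)
  }
})

test_that("animal call-rate filter removes strictly below threshold", {
  calls <- matrix(0L, nrow = 3, ncol = 100)
  calls[1, 1:4] <- NA # 0.96
  calls[2, 1:6] <- NA # 0.94
  calls[3, ] <- NA # all missing
  g <- genotype_matrix(calls, c("keep", "drop94", "dropall"),
                       sprintf("m%03d", 1:100))
  res <- filter_animals_by_call_rate(g, qc_config())
  expect_identical(rownames(res$genotypes), "keep")
  expect_setequal(res$report$removed_animals$id, c("drop94", "dropall"))
  expect_true(all(res$report$removed_animals$reason == "call_rate"))
})

test_that("marker filter applies missingness and HWE on the same input", {
  set.seed(2)
  n <- 100
  hwe_ok <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  calls <- cbind(
    hwe_ok,
    c(rep(NA, 11), sample(0:2, n - 11, replace = TRUE)), # 11% missing
    c(rep(0L, 50), rep(2L, 50)), # extreme het deficit
    c(rep(NA, 10), sample(0:2, n - 10, replace = TRUE)) # exactly 10%: kept
  )
  g <- genotype_matrix(calls, sprintf("a%03d", 1:n),
                       c("ok", "gap", "nohet", "edge"))
  res <- filter_markers(g, qc_config())
  removed <- res$report$removed_markers
  expect_setequal(removed$id, c("gap", "nohet"))
  expect_identical(removed$reason[removed$id == "gap"], "missingness")
  expect_identical(removed$reason[removed$id == "nohet"], "hwe")
  expect_setequal(colnames(res$genotypes), c("ok", "edge"))
})

test_that("cross-chip concordance uses a strict 'more than' rule", {
  set.seed(3)
  n <- 100
  hd <- genotype_matrix(matrix(sample(0:2, n * 3, TRUE), n, 3),
                        sprintf("a%03d", 1:n), c("m1", "m2", "m3"))
  k50 <- hd
  k <- unclass(k50)
  k[1:2, 2] <- (k[1:2, 2] + 1L) %% 3L # 2% discordant
  k[1, 3] <- (k[1, 3] + 1L) %% 3L # exactly 1%: retained
  k50 <- genotype_matrix(k, rownames(hd), colnames(hd))
  rep <- cross_chip_concordance(hd, k50, qc_config())
  expect_identical(rep$removed_markers$id, "m2")
  g1 <- subset_genotypes(hd, animals = "a001")
  expect_error(cross_chip_concordance(
    subset_genotypes(hd, animals = "a001"),
    subset_genotypes(k50, animals = "a002")
  ), "both chips")
})

test_that("identical chips yield zero concordance exclusions", {
  g <- tiny_genotypes()
  expect_identical(nrow(cross_chip_concordance(g, g)$removed_markers), 0L)
})

test_that("unrelated pairs accumulate opposing homozygotes as expected", {
  # at MAF 0.5 an unrelated pair is opposing-homozygous with prob 2 p^2 q^2
  set.seed(4)
  m <- 500
  freq <- rep(0.5, m)
  draw <- function() rbinom(m, 2, freq)
  g <- genotype_matrix(rbind(draw(), draw()), c("par", "off"),
                       sprintf("m%03d", 1:m))
  ped <- pedigree(c("par", "off"), c(NA, "par"), c(NA, NA), c("M", "M"),
                  c(0L, 1L))
  res <- parentage_test(g, ped, qc_config())
  n_inc <- res$pairs$n_incompatibilities[1]
  # expectation 500 * 2 * 0.25 * 0.25 = 62.5; binomial 99.9% interval
  expect_gt(n_inc, 30)
  expect_lt(n_inc, 100)
  expect_true(res$pairs$flagged[1])
  expect_identical(res$report$removed_animals$id, "off")
})

test_that("a sire incompatible with two progeny is removed instead of them", {
  set.seed(5)
  m <- 600
  sire <- rbinom(m, 2, 0.5)
  mk_child <- function(parent) {
    # true child of `parent` and a random mate
    gam_p <- ifelse(parent == 1, rbinom(m, 1, 0.5), parent / 2)
    gam_m <- rbinom(m, 1, 0.5)
    as.integer(gam_p + gam_m)
  }
  unrelated <- function() rbinom(m, 2, 0.5)
  g <- genotype_matrix(
    rbind(sire, mk_child(sire), unrelated(), unrelated()),
    c("sire", "kid_ok", "kid_bad1", "kid_bad2"), sprintf("m%03d", 1:m)
  )
  ped <- pedigree(
    c("sire", "kid_ok", "kid_bad1", "kid_bad2"),
    c(NA, "sire", "sire", "sire"), rep(NA_character_, 4),
    c("M", "M", "M", "F"), c(0L, 1L, 1L, 1L)
  )
  res <- parentage_test(g, ped, qc_config())
  expect_identical(res$report$removed_animals$id, "sire")
  expect_identical(res$report$removed_animals$reason, "parentage_parent")
})

test_that("true gene-drop families show zero incompatibilities", {
  sim <- simulate_breed(small_sim_config())
  res <- parentage_test(sim$genotypes, sim$pedigree,
                        qc_config(n_parentage_markers = 100L))
  expect_true(all(res$pairs$n_incompatibilities == 0L))
})

test_that("mendelian repair deletes the right call", {
  # sire 0-coded; 3/10 progeny 2-coded at marker 1 (30% > 20%): sire deleted
  # at marker 2 a single conflicting progeny call is deleted instead
  n_kids <- 10
  calls <- matrix(0L, nrow = n_kids + 1, ncol = 2)
  calls[2:4, 1] <- 2L
  calls[2, 2] <- 2L
  g <- genotype_matrix(calls, c("sire", paste0("k", 1:n_kids)), c("mA", "mB"))
  ped <- pedigree(
    c("sire", paste0("k", 1:n_kids)),
    c(NA, rep("sire", n_kids)), rep(NA_character_, n_kids + 1),
    c("M", rep("F", n_kids)), c(0L, rep(1L, n_kids))
  )
  res <- mendelian_repair(g, ped, qc_config())
  out <- unclass(res$genotypes)
  expect_true(is.na(out["sire", "mA"]))
  expect_false(anyNA(out[paste0("k", 1:n_kids), "mA"]))
  expect_true(is.na(out["k1", "mB"]))
  expect_false(is.na(out["sire", "mB"]))
  # no conflicts -> identity
  clean <- mendelian_repair(res$genotypes, ped, qc_config())
  expect_identical(unclass(clean$genotypes)[, ], unclass(res$genotypes)[, ])
  expect_identical(nrow(clean$report$genotype_edits), 0L)
})

test_that("replaying a QC report reproduces the edited dataset exactly", {
  cfg <- small_sim_config(missing_rate = 0.02, genotype_error_rate = 0.02)
  sim <- simulate_breed(cfg)
  res <- suppressWarnings(run_qc(sim$genotypes, sim$pedigree,
                                 qc_config(n_parentage_markers = 100L)))
  replayed <- apply_qc_report(sim$genotypes, res$report)
  expect_identical(unclass(replayed)[, ], unclass(res$genotypes)[, ])
})

test_that("mendelian edit count grows with the injected error rate", {
  edits <- vapply(c(0, 0.01, 0.05), function(e) {
    sim <- simulate_breed(small_sim_config(genotype_error_rate = e))
    res <- mendelian_repair(sim$genotypes, sim$pedigree, qc_config())
    nrow(res$report$genotype_edits)
  }, numeric(1))
  expect_identical(edits[1], 0)
  expect_true(all(diff(edits) > 0))
})

test_that("HWE removals on clean gene-drop data are rare", {
  # the exact test is conservative under the null: expected removal
  # fraction at alpha = 0.001 stays below 0.005
  removed <- 0L
  total <- 0L
  for (seed in 1:10) {
    sim <- simulate_breed(small_sim_config(seed = seed))
    res <- filter_markers(sim$genotypes, qc_config())
    removed <- removed + sum(res$report$removed_markers$reason == "hwe")
    total <- total + ncol(sim$genotypes)
  }
  expect_lt(removed / total, 0.005)
})
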