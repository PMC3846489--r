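test_that("age split takes the youngest fraction with id tie-breaks", {
  n <- 100L
  ids <- sprintf("a%03d", seq_len(n))
  ped <- pedigree(ids, NA_character_, NA_character_, rep("M", n),
                  rep(c(0L, 1L, 2L, 3L, 4L), each = 20L))
  sp <- split_by_age(ped, ids, 0.2)
  expect_identical(length(sp$training), 80L)
  expect_identical(length(sp$validation), 20L)
  expect_true(all(ped$birth_year[match(sp$validation, ids)] == 4L))
  expect_length(intersect(sp$training, sp$validation), 0L)
  # all same birth year: split is determined by the id tie-break
  ped_tie <- pedigree(ids, NA_character_, NA_character_, rep("M", n),
                      rep(1L, n))
  sp_tie <- split_by_age(ped_tie, ids, 0.2)
  expect_identical(sp_tie$validation, sort(ids)[1:20])
  # floor rule
  sp7 <- split_by_age(ped, ids[1:7], 0.2)
  expect_identical(length(sp7$validation), 1L)
})

test_that("masking hits exactly the HD-only markers", {
  map <- tiny_map(10, panel = c(rep("HD_ONLY", 9), "BOTH"))
  calls <- matrix(1L, nrow = 3, ncol = 10,
                  dimnames = list(paste0("a", 1:3), map$marker_id))
  g <- genotype_matrix(calls)
  masked <- mask_hd_only(g, map)
  expect_identical(sum(is.na(unclass(masked))), 27L)
  expect_false(anyNA(unclass(masked)[, "m10"]))
  all_both <- tiny_map(10)
  expect_identical(unclass(mask_hd_only(g, all_both))[, ], unclass(g)[, ])
})

test_that("allelic error counts wrong alleles, not wrong genotypes", {
  truth <- genotype_matrix(matrix(c(0L, 1L, 2L), 1, 3), "a",
                           c("m1", "m2", "m3"))
  imput <- genotype_matrix(matrix(c(0L, 2L, 2L), 1, 3), "a",
                           c("m1", "m2", "m3"))
  rep <- allelic_error_rate(imput, truth, c("m1", "m2", "m3"))
  expect_equal(rep$overall_error, 1 / 6, tolerance = 1e-12)
  expect_identical(rep$n_alleles_compared, 6L)
  # identity
  expect_equal(allelic_error_rate(truth, truth,
                                  c("m1", "m2", "m3"))$overall_error, 0)
  # complement: heterozygotes are their own complement, homozygotes flip
  het <- genotype_matrix(matrix(1L, 2, 4), c("a", "b"), paste0("m", 1:4))
  expect_equal(allelic_error_rate(het, het, paste0("m", 1:4))$overall_error, 0)
  hom <- genotype_matrix(matrix(c(0L, 2L), 2, 4), c("a", "b"),
                         paste0("m", 1:4))
  flip <- genotype_matrix(2L - unclass(hom), rownames(hom), colnames(hom))
  expect_equal(allelic_error_rate(flip, hom, paste0("m", 1:4))$overall_error,
               1)
  # restriction to masked markers: untouched markers contribute no errors
  rep2 <- allelic_error_rate(imput, truth, c("m1", "m3"))
  expect_identical(rep2$n_alleles_compared, 4L)
  expect_equal(rep2$overall_error, 0)
})

test_that("error times allele count is integral and per-snp table aggregates", {
  set.seed(41)
  n <- 20
  m <- 30
  truth <- genotype_matrix(matrix(sample(0:2, n * m, TRUE), n, m),
                           sprintf("a%02d", 1:n), sprintf("s%02d", 1:m))
  imput <- unclass(truth)
  flip <- matrix(runif(n * m) < 0.1, n, m)
  imput[flip] <- (imput[flip] + 1L) %% 3L
  imput <- genotype_matrix(imput, rownames(truth), colnames(truth))
  rep <- allelic_error_rate(imput, truth, colnames(truth))
  total <- rep$overall_error * rep$n_alleles_compared
  expect_equal(total, round(total), tolerance = 1e-9)
  expect_equal(sum(rep$per_snp$error * rep$per_snp$n_alleles), total)
  expect_equal(sum(rep$per_animal$error * rep$per_animal$n_alleles), total)
})

test_that("high-error SNP detection flags constructed outliers only", {
  set.seed(42)
  mk <- sprintf("s%04d", 1:1000)
  mk_report <- function() {
    err <- pmax(rnorm(1000, 0.01, 0.005), 0)
    err[1000] <- 0.5
    r <- list(per_snp = tibble::tibble(marker_id = mk, error = err,
                                       n_alleles = 200L))
    class(r) <- "error_report"
    r
  }
  reports <- list(b1 = mk_report(), b2 = mk_report(), b3 = mk_report())
  tab <- detect_high_error_snps(reports, min_breeds = 3L)
  expect_identical(tab$marker_id[1], "s1000")
  expect_identical(tab$n_breeds_flagged[1], 3L)
  expect_lte(nrow(tab), 3) # no wide net around the bulk
  # all-equal errors: sd = 0, strictly-greater rule flags nothing
  flat <- list(per_snp = tibble::tibble(marker_id = mk[1:10],
                                        error = rep(0.02, 10),
                                        n_alleles = 20L))
  class(flat) <- "error_report"
  tab0 <- detect_high_error_snps(list(a = flat, b = flat), min_breeds = 2L)
  expect_identical(nrow(tab0), 0L)
})

test_that("high-error table writes the ';'-separated layout", {
  tab <- tibble::tibble(chromosome = 1L, marker_id = "x",
                        n_breeds_flagged = 3L, mean_error = 0.4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_high_error_snps(tab, path)
  lines <- readLines(path)
  expect_identical(lines[1], "chromosome;marker_id;n_breeds_flagged;mean_error")
})

test_that("maf profile splits groups and degenerates gracefully", {
  set.seed(43)
  n <- 40
  m <- 200
  truth <- genotype_matrix(matrix(rbinom(n * m, 2, runif(m, 0.1, 0.9)), n, m,
                                  byrow = TRUE),
                           sprintf("a%02d", 1:n), sprintf("s%03d", 1:m))
  rep <- list(per_snp = tibble::tibble(
    marker_id = colnames(truth),
    error = c(rep(0, m / 2), runif(m / 2, 0.2, 0.5)),
    n_alleles = 2L * n
  ))
  class(rep) <- "error_report"
  prof <- maf_error_profile(rep, truth)
  expect_setequal(unique(prof$group), c("low_error", "high_error"))
  low <- prof[prof$group == "low_error", ]
  expect_true(all(low$mean_error == 0))
  # all-zero errors: single group plus a warning about the empty one
  rep0 <- list(per_snp = tibble::tibble(marker_id = colnames(truth),
                                        error = rep(0, m),
                                        n_alleles = 2L * n))
  class(rep0) <- "error_report"
  expect_warning(prof0 <- maf_error_profile(rep0, truth), "high_error")
  expect_true(all(prof0$group == "low_error"))
  expect_true(all(prof0$mean_error == 0))
})

test_that("randomly imputed SNPs err more at high MAF", {
  # closed-form intuition: imputing by an independent draw from the genotype
  # distribution errs with probability increasing in heterozygosity; check
  # the Spearman trend over MAF deciles by simulation
  set.seed(44)
  n <- 300
  m <- 400
  freq <- runif(m, 0.05, 0.95)
  truth <- genotype_matrix(matrix(rbinom(n * m, 2, rep(freq, each = n)), n, m),
                           sprintf("a%03d", 1:n), sprintf("s%03d", 1:m))
  random_imp <- genotype_matrix(
    matrix(rbinom(n * m, 2, rep(freq, each = n)), n, m),
    rownames(truth), colnames(truth)
  )
  rep <- allelic_error_rate(random_imp, truth, colnames(truth))
  prof <- maf_error_profile(rep, truth, split_at = 0.1)
  hi <- prof[prof$group == "high_error", ]
  expect_gt(nrow(hi), 5)
  expect_gt(stats::cor(hi$maf_bin, hi$mean_error, method = "spearman"), 0)
})

test_that("a group made of one breed twice reproduces the single-breed error", {
  sim <- simulate_breed(small_sim_config())
  res <- multibreed_evaluate(list(B = sim), list(c("B", "B")), fast_icfg())
  expect_equal(res$single_error[1], res$multi_error[1], tolerance = 1e-12)
})

test_that("pooling unrelated breeds does not improve imputation", {
  # breeds with disjoint founder haplotype pools: the pooled reference adds
  # templates the target never copies from usefully, so accuracy does not
  # improve (and may degrade slightly)
  mk <- function(seed, breed) {
    small_sim_config(n_founders = 40L, markers_per_chromosome_hd = 400L,
                     chromosome_length_bp = 1.4e6, seed = seed, breed = breed)
  }
  datasets <- list(A = simulate_breed(mk(61, "A")),
                   B = simulate_breed(mk(62, "B")))
  res <- multibreed_evaluate(datasets, list(c("A", "B")),
                             fast_icfg(seed = 9))
  expect_identical(nrow(res), 2L)
  expect_true(all(res$multi_error >= res$single_error - 0.005))
  expect_true(all(res$multi_error <= res$single_error + 0.03))
})
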