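#' Split genotyped animals into training (oldest) and validation (youngest)
#'
#' The validation set holds the `floor(validation_fraction * N)` youngest
#' animals (largest birth years, ties broken by animal id); the rest train.
#'
#' @param ped A `pedigree`.
#' @param genotyped Character vector of genotyped animal ids.
#' @param validation_fraction Fraction of animals used for validation
#'   (default 0.20).
#' @return A list with `training` and `validation` id vectors (disjoint and
#'   exhaustive over `genotyped`).
#' @export
split_by_age <- function(ped, genotyped, validation_fraction = 0.20) {
  stopifnot(validation_fraction > 0, validation_fraction < 1)
  i <- match(genotyped, ped$animal_id)
  if (anyNA(i)) {
    stop("genotyped animals absent from pedigree: ",
         paste(utils::head(genotyped[is.na(i)], 5L), collapse = ", "),
         call. = FALSE)
  }
  by <- ped$birth_year[i]
  if (anyNA(by)) stop("missing birth year", call. = FALSE)
  ord <- order(-by, genotyped)
  n_val <- floor(validation_fraction * length(genotyped))
  if (n_val < 1L) stop("validation set would be empty", call. = FALSE)
  validation <- genotyped[ord[seq_len(n_val)]]
  training <- setdiff(genotyped, validation)
  list(training = training, validation = validation)
}

#' Mask markers present only on the high-density panel
#'
#' Sets every `HD_ONLY` marker to missing (mimicking animals genotyped on the
#' 50K-like chip); shared (`BOTH`) markers are untouched.
#'
#' @param g A `genotype_matrix`.
#' @param map A `marker_map` with panel membership.
#' @return A `genotype_matrix` of the same shape.
#' @export
mask_hd_only <- function(g, map) {
  hd_only <- map$marker_id[map$panel == "HD_ONLY"]
  gm <- unclass(g)
  cols <- intersect(colnames(g), hd_only)
  gm[, cols] <- NA_integer_
  genotype_matrix(gm, rownames(g), colnames(g))
}

#' Allelic imputation error rate
#'
#' The number of falsely imputed alleles over the total number of imputed
#' alleles, restricted to the masked markers and to entries where the truth
#' is non-missing. Per entry, the number of wrong alleles is
#' `|imputed - truth|` on the dosage codes (heterozygote vs homozygote = 1
#' allele, opposite homozygotes = 2 alleles); each compared entry contributes
#' two alleles to the denominator. The overall rate is total mismatches over
#' total alleles (not the mean of per-animal rates).
#'
#' @param imputed An `imputed_genotypes` object or a `genotype_matrix` of
#'   hard calls.
#' @param truth A `genotype_matrix` of true genotypes.
#' @param masked_markers Character vector of marker ids that were masked
#'   (i.e. actually imputed).
#' @return An object of class `error_report`: list with `overall_error`,
#'   `per_animal` (tibble: animal_id, error, n_alleles), `per_snp` (tibble:
#'   marker_id, error, n_alleles) and `n_alleles_compared`.
#' @export
allelic_error_rate <- function(imputed, truth, masked_markers) {
  hard <- if (inherits(imputed, "imputed_genotypes")) {
    imputed$hard_calls
  } else {
    imputed
  }
  markers <- intersect(masked_markers, intersect(colnames(hard),
                                                 colnames(truth)))
  animals <- intersect(rownames(hard), rownames(truth))
  if (!length(markers) || !length(animals)) {
    stop("no comparable entries", call. = FALSE)
  }
  im <- unclass(hard)[animals, markers, drop = FALSE]
  tr <- unclass(truth)[animals, markers, drop = FALSE]
  ok <- !is.na(tr) & !is.na(im)
  if (!any(ok)) stop("no comparable entries", call. = FALSE)
  wrong <- abs(im - tr)
  wrong[!ok] <- NA_integer_
  n_entry_a <- rowSums(ok)
  n_entry_s <- colSums(ok)
  per_animal <- tibble::tibble(
    animal_id = animals,
    error = rowSums(wrong, na.rm = TRUE) / (2 * pmax(n_entry_a, 1L)),
    n_alleles = 2L * n_entry_a
  )
  per_snp <- tibble::tibble(
    marker_id = markers,
    error = colSums(wrong, na.rm = TRUE) / (2 * pmax(n_entry_s, 1L)),
    n_alleles = 2L * n_entry_s
  )
  out <- list(
    overall_error = sum(wrong, na.rm = TRUE) / (2 * sum(ok)),
    per_animal = per_animal,
    per_snp = per_snp[per_snp$n_alleles > 0L, ],
    n_alleles_compared = 2L * sum(ok)
  )
  class(out) <- "error_report"
  out
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> overall allelic error %.4f%% over %d alleles\n",
              100 * x$overall_error, x$n_alleles_compared))
  invisible(x)
}

#' Detect SNPs with recurrently high imputation error across breeds
#'
#' Within each breed a SNP is flagged when its per-SNP error rate strictly
#' exceeds that breed's mean per-SNP error plus three standard deviations.
#' SNPs flagged in at least `min_breeds` breeds are returned, with the
#' chromosome, the number of breeds flagging the SNP and its average error
#' rate across breeds.
#'
#' @param reports Named list (breed -> `error_report`).
#' @param min_breeds Minimum number of flagging breeds (default 3).
#' @param map Optional `marker_map` used to attach chromosome numbers.
#' @return A tibble (`chromosome`, `marker_id`, `n_breeds_flagged`,
#'   `mean_error`) sorted by decreasing `n_breeds_flagged` and error.
#' @export
detect_high_error_snps <- function(reports, min_breeds = 3L, map = NULL) {
  if (length(reports) < min_breeds) {
    stop("fewer breed reports than min_breeds", call. = FALSE)
  }
  flags <- lapply(names(reports), function(br) {
    ps <- reports[[br]]$per_snp
    if (nrow(ps) < 2L) {
      stop("breed ", br, " has fewer than 2 evaluated SNPs (SD undefined)",
           call. = FALSE)
    }
    thr <- mean(ps$error) + 3 * stats::sd(ps$error)
    tibble::tibble(breed = br, marker_id = ps$marker_id, error = ps$error,
                   flagged = ps$error > thr)
  })
  all_flags <- dplyr::bind_rows(flags)
  out <- all_flags |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(
      n_breeds_flagged = sum(.data$flagged),
      mean_error = mean(.data$error),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_breeds_flagged >= min_breeds) |>
    dplyr::arrange(dplyr::desc(.data$n_breeds_flagged),
                   dplyr::desc(.data$mean_error))
  chromosome <- if (!is.null(map)) {
    map$chromosome[match(out$marker_id, map$marker_id)]
  } else {
    NA_integer_
  }
  dplyr::bind_cols(tibble::tibble(chromosome = chromosome), out)
}

#' Write a high-error SNP table as semicolon-separated text
#'
#' @param table Output of [detect_high_error_snps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_high_error_snps <- function(table, path) {
  utils::write.table(table, path, sep = ";", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Imputation error versus minor allele frequency
#'
#' SNPs are split into a low- and a high-error group at `split_at`; minor
#' allele frequencies are computed from the truth genotypes; the mean error
#' per MAF decile (deciles of the MAF distribution over evaluated SNPs) is
#' returned per group. A SNP imputed at random errs more often the more
#' heterozygous it is, so high-error (e.g. mismapped) SNPs show error rising
#' with MAF while well-imputed SNPs show no trend.
#'
#' @param report An `error_report`.
#' @param truth `genotype_matrix` of true genotypes (typically the validation
#'   animals).
#' @param split_at Error-rate threshold separating the groups (default 0.1).
#' @return A tibble (`maf_bin`, `group`, `mean_maf`, `mean_error`, `n_snps`).
#' @export
maf_error_profile <- function(report, truth, split_at = 0.1) {
  ps <- report$per_snp
  markers <- intersect(ps$marker_id, colnames(truth))
  ps <- ps[ps$marker_id %in% markers, ]
  freq <- colMeans(unclass(truth)[, ps$marker_id, drop = FALSE],
                   na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  d <- tibble::tibble(
    marker_id = ps$marker_id,
    error = ps$error,
    maf = unname(maf),
    group = ifelse(ps$error >= split_at, "high_error", "low_error"),
    maf_bin = dplyr::ntile(unname(maf), 10L)
  )
  present <- unique(d$group)
  for (g in setdiff(c("low_error", "high_error"), present)) {
    warning("empty group omitted: ", g, call. = FALSE)
  }
  d |>
    dplyr::group_by(.data$maf_bin, .data$group) |>
    dplyr::summarise(
      mean_maf = mean(.data$maf),
      mean_error = mean(.data$error),
      n_snps = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group, .data$maf_bin)
}

#' Run the full within-breed imputation evaluation on a simulated dataset
#'
#' Convenience pipeline: age split, reference phasing, masking of HD-only
#' markers in the validation animals, imputation, and allelic error rate
#' against the (pre-artifact) truth genotypes.
#'
#' @param data A `sim_dataset`.
#' @param icfg An `imputation_config`.
#' @param validation_fraction Fraction of youngest animals held out.
#' @param reference_ids Optional explicit training set (overrides the age
#'   split's training ids; validation stays the youngest fraction).
#' @return A list with `report` (`error_report`), `split`, `imputed`,
#'   `masked_markers` and `reference` (the phased panel).
#' @export
evaluate_imputation <- function(data, icfg = imputation_config(),
                                validation_fraction = 0.20,
                                reference_ids = NULL) {
  split <- split_by_age(data$pedigree, rownames(data$genotypes),
                        validation_fraction)
  training <- if (is.null(reference_ids)) split$training else reference_ids
  ref_g <- subset_genotypes(data$genotypes, animals = training)
  ref <- phase_reference(ref_g, data$map, icfg)
  val_g <- subset_genotypes(data$genotypes, animals = split$validation)
  masked <- mask_hd_only(val_g, data$map)
  imputed <- impute_target(ref, masked, data$map, icfg)
  truth <- panel_to_genotypes(data$truth_haplotypes)
  truth_val <- subset_genotypes(truth, animals = split$validation)
  masked_markers <- data$map$marker_id[data$map$panel == "HD_ONLY"]
  report <- allelic_error_rate(imputed, truth_val, masked_markers)
  list(report = report, split = split, imputed = imputed,
       masked_markers = masked_markers, reference = ref)
}

#' Single- versus multi-breed imputation evaluation
#'
#' For each group of breeds, the phased training panels of all member breeds
#' are pooled into one multi-breed reference, every member breed's validation
#' animals are imputed against it, and the allelic error is averaged per
#' animal within breed. The single-breed baseline uses identical splits and
#' phased panels. Duplicate animals (a breed listed twice) are pooled once.
#'
#' @param datasets Named list (breed -> `sim_dataset`); all datasets must
#'   share one marker map.
#' @param groups List of character vectors of breed names; a breed may appear
#'   in at most one group.
#' @param icfg An `imputation_config`.
#' @param validation_fraction Fraction of youngest animals held out.
#' @return A tibble (`breed`, `group`, `single_error`, `multi_error`), where
#'   errors are per-animal error rates averaged within breed.
#' @export
multibreed_evaluate <- function(datasets, groups,
                                icfg = imputation_config(),
                                validation_fraction = 0.20) {
  if (anyDuplicated(unlist(lapply(groups, unique)))) {
    stop("a breed appears in more than one group", call. = FALSE)
  }
  all_breeds <- unique(unlist(groups))
  missing <- setdiff(all_breeds, names(datasets))
  if (length(missing)) {
    stop("datasets missing for breed(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ref_map <- datasets[[all_breeds[1L]]]$map
  for (br in all_breeds) {
    if (!identical(datasets[[br]]$map$marker_id, ref_map$marker_id)) {
      stop("breeds must share one marker map", call. = FALSE)
    }
  }
  single <- lapply(all_breeds, function(br) {
    evaluate_imputation(datasets[[br]], icfg, validation_fraction)
  })
  names(single) <- all_breeds
  rows <- list()
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]] # duplicates allowed: animals are pooled once
    panels <- lapply(grp, function(br) single[[br]]$reference)
    pooled_ids <- unique(unlist(lapply(panels, panel_animal_ids)))
    pooled <- do.call(rbind, lapply(panels, unclass))
    rows_keep <- as.vector(rbind(paste0(pooled_ids, "_1"),
                                 paste0(pooled_ids, "_2")))
    pooled <- pooled[match(rows_keep, rownames(pooled)), , drop = FALSE]
    pooled_panel <- haplotype_panel(pooled, rows_keep, colnames(panels[[1L]]))
    for (br in grp) {
      data <- datasets[[br]]
      split <- single[[br]]$split
      val_g <- subset_genotypes(data$genotypes, animals = split$validation)
      masked <- mask_hd_only(val_g, data$map)
      imputed <- impute_target(pooled_panel, masked, data$map, icfg)
      truth <- subset_genotypes(panel_to_genotypes(data$truth_haplotypes),
                                animals = split$validation)
      rep_multi <- allelic_error_rate(imputed, truth,
                                      single[[br]]$masked_markers)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        breed = br,
        group = gi,
        single_error = mean(single[[br]]$report$per_animal$error),
        multi_error = mean(rep_multi$per_animal$error)
      )
    }
  }
  dplyr::bind_rows(rows)
}
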