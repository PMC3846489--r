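#' Quality-control configuration
#'
#' Thresholds of the data-editing cascade. All comparisons are strict in the
#' direction stated: animals with call rate *lower than* the minimum are
#' removed, markers with *more than* the allowed missingness or discordance
#' are removed, pairs with *more than* the allowed incompatibilities are
#' flagged, and a sire's call is deleted when *more than* the allowed
#' fraction of its progeny contradict it.
#'
#' @param min_animal_call_rate Minimum per-animal call rate (default 0.95).
#' @param hwe_p_threshold Exact Hardy-Weinberg p-value below which a marker
#'   is removed (default 0.001).
#' @param max_snp_missing Maximum per-marker missing fraction (default 0.10).
#' @param max_discordance Maximum cross-chip discordance fraction
#'   (default 0.01).
#' @param n_parentage_markers Number of informative markers used for
#'   parentage testing (default 500).
#' @param max_incompatibilities Opposing-homozygote count above which a
#'   parent-offspring pair is declared incompatible (default 10).
#' @param max_progeny_contradiction Fraction of contradicting progeny above
#'   which the parent's call (not the progeny's) is deleted (default 0.20).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_animal_call_rate = 0.95,
                      hwe_p_threshold = 0.001,
                      max_snp_missing = 0.10,
                      max_discordance = 0.01,
                      n_parentage_markers = 500L,
                      max_incompatibilities = 10L,
                      max_progeny_contradiction = 0.20) {
  cfg <- list(
    min_animal_call_rate = min_animal_call_rate,
    hwe_p_threshold = hwe_p_threshold,
    max_snp_missing = max_snp_missing,
    max_discordance = max_discordance,
    n_parentage_markers = as.integer(n_parentage_markers),
    max_incompatibilities = as.integer(max_incompatibilities),
    max_progeny_contradiction = max_progeny_contradiction
  )
  stopifnot(
    cfg$min_animal_call_rate >= 0, cfg$min_animal_call_rate <= 1,
    cfg$hwe_p_threshold >= 0, cfg$hwe_p_threshold <= 1,
    cfg$max_snp_missing >= 0, cfg$max_snp_missing <= 1,
    cfg$max_discordance >= 0, cfg$max_discordance <= 1,
    cfg$n_parentage_markers >= 1L, cfg$max_incompatibilities >= 0L,
    cfg$max_progeny_contradiction >= 0, cfg$max_progeny_contradiction <= 1
  )
  class(cfg) <- "qc_config"
  cfg
}

new_qc_report <- function(removed_animals = NULL, removed_markers = NULL,
                          genotype_edits = NULL) {
  empty_rm <- tibble::tibble(id = character(0), reason = character(0),
                             value = numeric(0))
  empty_ed <- tibble::tibble(animal_id = character(0),
                             marker_id = character(0),
                             action = character(0))
  out <- list(
    removed_animals = if (is.null(removed_animals)) empty_rm else removed_animals,
    removed_markers = if (is.null(removed_markers)) empty_rm else removed_markers,
    genotype_edits = if (is.null(genotype_edits)) empty_ed else genotype_edits
  )
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d animal(s) removed, %d marker(s) removed, %d genotype edit(s)\n",
    nrow(x$removed_animals), nrow(x$removed_markers), nrow(x$genotype_edits)
  ))
  invisible(x)
}

#' Combine QC reports in cascade order
#'
#' @param ... `qc_report` objects.
#' @return A single `qc_report` with the rows of all inputs.
#' @export
combine_qc_reports <- function(...) {
  reps <- list(...)
  new_qc_report(
    dplyr::bind_rows(lapply(reps, `[[`, "removed_animals")),
    dplyr::bind_rows(lapply(reps, `[[`, "removed_markers")),
    dplyr::bind_rows(lapply(reps, `[[`, "genotype_edits"))
  )
}

#' Remove animals with low call rate
#'
#' @param g A `genotype_matrix`.
#' @param cfg A `qc_config`.
#' @return List with the filtered `genotypes` and a `qc_report`.
#' @export
filter_animals_by_call_rate <- function(g, cfg = qc_config()) {
  cr <- rowMeans(!is.na(unclass(g)))
  drop <- cr < cfg$min_animal_call_rate
  report <- new_qc_report(removed_animals = tibble::tibble(
    id = rownames(g)[drop], reason = "call_rate", value = unname(cr[drop])
  ))
  keep <- rownames(g)[!drop]
  if (!length(keep)) {
    stop("call-rate filter removed every animal", call. = FALSE)
  }
  list(genotypes = subset_genotypes(g, animals = keep), report = report)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on genotype counts: all heterozygote counts
#' consistent with the observed allele counts are enumerated and the
#' probabilities of configurations no more probable than the observed one
#' are summed. Monomorphic markers return p = 1 (no test possible).
#'
#' @param n_aa Count of homozygous-reference genotypes.
#' @param n_ab Count of heterozygous genotypes.
#' @param n_bb Count of homozygous-alternate genotypes.
#' @return Exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("need at least one genotype", call. = FALSE)
  n1 <- 2L * n_bb + n_ab # alternate allele count
  if (n1 > n) n1 <- 2L * n - n1 # work with the minor allele
  if (n1 == 0L) return(1.0)
  hets <- seq.int(n1 %% 2L, n1, by = 2L)
  # log P(n_het = h | allele counts) up to a constant:
  # multinomial genotype count x 2^h over the allele-permutation constant
  log_p <- h_log_prob(hets, n, n1)
  log_p <- log_p - max(log_p)
  p <- exp(log_p)
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

h_log_prob <- function(h, n, n1) {
  hom_minor <- (n1 - h) / 2
  hom_major <- n - h - hom_minor
  lgamma(n + 1) - lgamma(hom_minor + 1) - lgamma(h + 1) -
    lgamma(hom_major + 1) + h * log(2)
}

#' Remove markers failing Hardy-Weinberg or missingness criteria
#'
#' Both criteria are evaluated on the same input state (a marker failing both
#' is reported with missingness as the primary reason).
#'
#' @param g A `genotype_matrix`.
#' @param cfg A `qc_config`.
#' @return List with the filtered `genotypes` and a `qc_report`.
#' @export
filter_markers <- function(g, cfg = qc_config()) {
  gm <- unclass(g)
  miss <- colMeans(is.na(gm))
  n_aa <- colSums(gm == 0L, na.rm = TRUE)
  n_ab <- colSums(gm == 1L, na.rm = TRUE)
  n_bb <- colSums(gm == 2L, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(gm)), function(j) {
    if (n_aa[j] + n_ab[j] + n_bb[j] == 0L) return(1.0)
    hwe_exact_test(n_aa[j], n_ab[j], n_bb[j])
  }, numeric(1))
  drop_miss <- miss > cfg$max_snp_missing
  drop_hwe <- !drop_miss & hwe_p < cfg$hwe_p_threshold
  report <- new_qc_report(removed_markers = dplyr::bind_rows(
    tibble::tibble(id = colnames(g)[drop_miss], reason = "missingness",
                   value = unname(miss[drop_miss])),
    tibble::tibble(id = colnames(g)[drop_hwe], reason = "hwe",
                   value = unname(hwe_p[drop_hwe]))
  ))
  keep <- colnames(g)[!(drop_miss | drop_hwe)]
  if (!length(keep)) stop("marker filter removed every marker", call. = FALSE)
  list(genotypes = subset_genotypes(g, markers = keep), report = report)
}

#' Cross-chip genotype concordance check
#'
#' For every marker shared between the two panels, discordance is the
#' fraction of dual-genotyped animals (both calls non-missing) whose codes
#' disagree; markers with discordance strictly above `max_discordance` are
#' flagged for exclusion.
#'
#' @param hd High-density `genotype_matrix`.
#' @param k50 Medium-density `genotype_matrix`.
#' @param cfg A `qc_config`.
#' @return A `qc_report` whose `removed_markers` lists the flagged markers.
#' @export
cross_chip_concordance <- function(hd, k50, cfg = qc_config()) {
  shared <- intersect(colnames(hd), colnames(k50))
  dual <- intersect(rownames(hd), rownames(k50))
  if (!length(dual)) stop("no animals genotyped on both chips", call. = FALSE)
  if (!length(shared)) stop("no shared markers between chips", call. = FALSE)
  a <- unclass(subset_genotypes(hd, animals = dual, markers = shared))
  b <- unclass(subset_genotypes(k50, animals = dual, markers = shared))
  both <- !is.na(a) & !is.na(b)
  n_both <- colSums(both)
  n_disc <- colSums(both & (a != b), na.rm = TRUE)
  disc <- ifelse(n_both > 0L, n_disc / n_both, 0)
  flag <- disc > cfg$max_discordance
  new_qc_report(removed_markers = tibble::tibble(
    id = shared[flag], reason = "cross_chip_discordance",
    value = unname(disc[flag])
  ))
}

# opposing-homozygote counts for a set of (parent, offspring) id pairs
opposing_homozygote_counts <- function(g, parents, offspring, markers) {
  gp <- unclass(g)[parents, markers, drop = FALSE]
  go <- unclass(g)[offspring, markers, drop = FALSE]
  conflict <- (gp == 0L & go == 2L) | (gp == 2L & go == 0L)
  rowSums(conflict, na.rm = TRUE)
}

#' Opposing-homozygote parentage test
#'
#' Tests every genotyped parent-offspring pair on a fixed set of informative
#' markers: the `n_parentage_markers` markers with the highest minor allele
#' frequency among those without any missing call in the tested animals
#' (ties broken by map/column order). An incompatibility is an
#' opposing-homozygote pair (codes 0 vs 2). Pairs with more than
#' `max_incompatibilities` conflicts are flagged; the flagged offspring is
#' removed, except that a parent found incompatible with at least two of its
#' progeny is removed instead (its flagged progeny are then retained).
#'
#' @param g A `genotype_matrix`.
#' @param ped A `pedigree`.
#' @param cfg A `qc_config`.
#' @return A list with `report` (a `qc_report`) and `pairs` (a tibble of all
#'   tested pairs with their incompatibility counts and flags).
#' @export
parentage_test <- function(g, ped, cfg = qc_config()) {
  geno_ids <- rownames(g)
  pairs <- dplyr::bind_rows(
    tibble::tibble(parent = ped$sire_id, offspring = ped$animal_id),
    tibble::tibble(parent = ped$dam_id, offspring = ped$animal_id)
  )
  pairs <- pairs[!is.na(pairs$parent) &
                   pairs$parent %in% geno_ids &
                   pairs$offspring %in% geno_ids, ]
  if (!nrow(pairs)) {
    stop("no genotyped parent-offspring pairs to test", call. = FALSE)
  }
  tested_animals <- unique(c(pairs$parent, pairs$offspring))
  sub <- unclass(g)[tested_animals, , drop = FALSE]
  complete <- colSums(is.na(sub)) == 0L
  freq <- colMeans(sub, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  candidates <- which(complete)
  if (length(candidates) < cfg$n_parentage_markers) {
    warning(sprintf(
      "only %d informative markers available (%d requested); using all",
      length(candidates), cfg$n_parentage_markers
    ), call. = FALSE)
  }
  ord <- candidates[order(-maf[candidates], candidates)]
  informative <- colnames(g)[utils::head(ord, cfg$n_parentage_markers)]
  counts <- opposing_homozygote_counts(g, pairs$parent, pairs$offspring,
                                       informative)
  pairs$n_incompatibilities <- counts
  pairs$flagged <- counts > cfg$max_incompatibilities
  flagged <- pairs[pairs$flagged, ]
  parent_tab <- table(flagged$parent)
  bad_parents <- names(parent_tab)[parent_tab >= 2L]
  remove_offspring <- setdiff(flagged$offspring,
                              flagged$offspring[flagged$parent %in% bad_parents])
  report <- new_qc_report(removed_animals = dplyr::bind_rows(
    tibble::tibble(id = bad_parents, reason = "parentage_parent",
                   value = as.numeric(parent_tab[bad_parents])),
    tibble::tibble(id = unique(remove_offspring), reason = "parentage_offspring",
                   value = NA_real_)
  ))
  list(report = report, pairs = tibble::as_tibble(pairs),
       informative_markers = informative)
}

#' Repair Mendelian inconsistencies between compatible parents and offspring
#'
#' Applied after [parentage_test()] (only compatible pairs should remain).
#' Per marker and per genotyped parent: if the fraction of the parent's
#' genotyped progeny showing an opposing-homozygote conflict exceeds
#' `max_progeny_contradiction`, the parent's call at that marker is set to
#' missing; otherwise each conflicting progeny call is set to missing.
#'
#' @param g A `genotype_matrix`.
#' @param ped A `pedigree`.
#' @param cfg A `qc_config`.
#' @return List with the repaired `genotypes` and a `qc_report` logging every
#'   edit.
#' @export
mendelian_repair <- function(g, ped, cfg = qc_config()) {
  gm <- unclass(g)
  geno_ids <- rownames(g)
  edits <- list()
  for (side in c("sire_id", "dam_id")) {
    links <- tibble::tibble(parent = ped[[side]], offspring = ped$animal_id)
    links <- links[!is.na(links$parent) &
                     links$parent %in% geno_ids &
                     links$offspring %in% geno_ids, ]
    if (!nrow(links)) next
    for (p in unique(links$parent)) {
      kids <- links$offspring[links$parent == p]
      gp <- gm[p, ]
      gk <- gm[kids, , drop = FALSE]
      conflict <- sweep(gk == 2L, 2L, gp == 0L, `&`) |
        sweep(gk == 0L, 2L, gp == 2L, `&`)
      conflict[is.na(conflict)] <- FALSE
      n_conf <- colSums(conflict)
      n_typed <- colSums(!is.na(gk))
      frac <- ifelse(n_typed > 0L, n_conf / n_typed, 0)
      del_parent <- n_conf > 0L & frac > cfg$max_progeny_contradiction
      if (any(del_parent)) {
        gm[p, del_parent] <- NA_integer_
        edits[[length(edits) + 1L]] <- tibble::tibble(
          animal_id = p, marker_id = colnames(g)[del_parent],
          action = "set_missing_parent"
        )
      }
      fix_kids <- which(conflict & !matrix(del_parent, nrow(gk), ncol(gk),
                                           byrow = TRUE), arr.ind = TRUE)
      if (nrow(fix_kids)) {
        gm[cbind(match(kids[fix_kids[, 1L]], geno_ids), fix_kids[, 2L])] <- NA_integer_
        edits[[length(edits) + 1L]] <- tibble::tibble(
          animal_id = kids[fix_kids[, 1L]],
          marker_id = colnames(g)[fix_kids[, 2L]],
          action = "set_missing_offspring"
        )
      }
    }
  }
  report <- new_qc_report(genotype_edits = if (length(edits)) {
    dplyr::bind_rows(edits)
  } else {
    NULL
  })
  list(genotypes = genotype_matrix(gm, rownames(g), colnames(g)),
       report = report)
}

#' Run the full quality-control cascade
#'
#' Deterministic, order-fixed cascade: animal call rate, marker filters
#' (Hardy-Weinberg and missingness), optional cross-chip concordance,
#' parentage testing, Mendelian repair.
#'
#' @param g High-density `genotype_matrix`.
#' @param ped A `pedigree`.
#' @param cfg A `qc_config`.
#' @param k50 Optional medium-density `genotype_matrix` for the concordance
#'   step (skipped when `NULL`).
#' @return List with the edited `genotypes` and the combined `qc_report`.
#' @export
run_qc <- function(g, ped, cfg = qc_config(), k50 = NULL) {
  s1 <- filter_animals_by_call_rate(g, cfg)
  s2 <- filter_markers(s1$genotypes, cfg)
  g2 <- s2$genotypes
  conc_report <- new_qc_report()
  if (!is.null(k50)) {
    conc_report <- cross_chip_concordance(g2, k50, cfg)
    keep <- setdiff(colnames(g2), conc_report$removed_markers$id)
    g2 <- subset_genotypes(g2, markers = keep)
  }
  pt <- tryCatch(parentage_test(g2, ped, cfg),
                 error = function(e) NULL)
  if (!is.null(pt)) {
    keep <- setdiff(rownames(g2), pt$report$removed_animals$id)
    g2 <- subset_genotypes(g2, animals = keep)
    pt_report <- pt$report
  } else {
    pt_report <- new_qc_report()
  }
  mr <- mendelian_repair(g2, ped, cfg)
  list(
    genotypes = mr$genotypes,
    report = combine_qc_reports(s1$report, s2$report, conc_report,
                                pt_report, mr$report)
  )
}

#' Replay a QC report on the raw input
#'
#' Applies the removals and genotype edits recorded in a `qc_report` to the
#' raw genotype matrix, reproducing the edited dataset exactly.
#'
#' @param g The raw `genotype_matrix` the report was derived from.
#' @param report A `qc_report`.
#' @return A `genotype_matrix`.
#' @export
apply_qc_report <- function(g, report) {
  keep_a <- setdiff(rownames(g), report$removed_animals$id)
  keep_m <- setdiff(colnames(g), report$removed_markers$id)
  out <- unclass(subset_genotypes(g, animals = keep_a, markers = keep_m))
  ed <- report$genotype_edits
  if (nrow(ed)) {
    out[cbind(match(ed$animal_id, rownames(out)),
              match(ed$marker_id, colnames(out)))] <- NA_integer_
  }
  genotype_matrix(out, rownames(out), colnames(out))
}
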