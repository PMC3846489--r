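#' Construct a genotype matrix
#'
#' A `genotype_matrix` stores allele-dosage codes for a set of animals at a
#' set of biallelic markers. Codes count copies of the alternate allele:
#' 0 (homozygous reference), 1 (heterozygous), 2 (homozygous alternate),
#' `NA` (missing call).
#'
#' @param calls Integer matrix (animals in rows, markers in columns) with
#'   values in `{0, 1, 2, NA}`.
#' @param animal_ids Character vector of row identifiers; defaults to
#'   `rownames(calls)`.
#' @param marker_ids Character vector of column identifiers; defaults to
#'   `colnames(calls)`.
#' @return An object of class `genotype_matrix` (an integer matrix with
#'   dimnames).
#' @export
genotype_matrix <- function(calls,
                            animal_ids = rownames(calls),
                            marker_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(animal_ids) || is.null(marker_ids)) {
    stop("genotype_matrix() needs animal and marker identifiers", call. = FALSE)
  }
  animal_ids <- as.character(animal_ids)
  marker_ids <- as.character(marker_ids)
  if (length(animal_ids) != nrow(calls) || length(marker_ids) != ncol(calls)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(animal_ids)) stop("duplicated animal ids", call. = FALSE)
  if (anyDuplicated(marker_ids)) stop("duplicated marker ids", call. = FALSE)
  storage.mode(calls) <- "integer"
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  dimnames(calls) <- list(animal_ids, marker_ids)
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d animals x %d markers (%.2f%% missing)\n",
    nrow(x), ncol(x), 100 * mean(is.na(x))
  ))
  invisible(x)
}

#' Construct a haplotype panel
#'
#' A `haplotype_panel` stores phased binary haplotypes, two consecutive rows
#' per animal (named `<animal>_1` and `<animal>_2`). Summing the two rows of
#' an animal yields its genotype codes.
#'
#' @param alleles Integer matrix of 0/1 alleles, haplotypes in rows.
#' @param haplotype_ids Character row identifiers (two per animal, adjacent).
#' @param marker_ids Character column identifiers.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles,
                            haplotype_ids = rownames(alleles),
                            marker_ids = colnames(alleles)) {
  alleles <- as.matrix(alleles)
  if (nrow(alleles) %% 2L != 0L) {
    stop("a haplotype panel needs an even number of haplotypes", call. = FALSE)
  }
  storage.mode(alleles) <- "integer"
  vals <- alleles[!is.na(alleles)]
  if (anyNA(alleles) || (length(vals) && (min(vals) < 0L || max(vals) > 1L))) {
    stop("haplotype alleles must be 0 or 1", call. = FALSE)
  }
  dimnames(alleles) <- list(as.character(haplotype_ids), as.character(marker_ids))
  class(alleles) <- c("haplotype_panel", class(alleles))
  alleles
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "<haplotype_panel> %d haplotypes (%d animals) x %d markers\n",
    nrow(x), nrow(x) %/% 2L, ncol(x)
  ))
  invisible(x)
}

#' Animal identifiers of a haplotype panel
#'
#' @param h A `haplotype_panel`.
#' @return Character vector, one id per haplotype pair.
#' @export
panel_animal_ids <- function(h) {
  ids <- sub("_[12]$", "", rownames(h))
  unique(ids)
}

#' Collapse a haplotype panel into genotype codes
#'
#' @param h A `haplotype_panel`.
#' @return A `genotype_matrix` with one row per animal.
#' @export
panel_to_genotypes <- function(h) {
  n <- nrow(h) %/% 2L
  g <- unclass(h)[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    unclass(h)[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  genotype_matrix(g, animal_ids = panel_animal_ids(h), marker_ids = colnames(h))
}

#' Subset a genotype matrix by animal and/or marker identifiers
#'
#' Order of the requested identifiers is preserved and calls are never
#' altered. Unknown identifiers are an error.
#'
#' @param g A `genotype_matrix`.
#' @param animals Character vector of animal ids to keep (`NULL` keeps all).
#' @param markers Character vector of marker ids to keep (`NULL` keeps all).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, animals = NULL, markers = NULL) {
  if (is.null(animals)) animals <- rownames(g)
  if (is.null(markers)) markers <- colnames(g)
  animals <- as.character(animals)
  markers <- as.character(markers)
  if (length(animals) == 0L) stop("empty animal selection", call. = FALSE)
  if (length(markers) == 0L) stop("empty marker selection", call. = FALSE)
  miss_a <- setdiff(animals, rownames(g))
  if (length(miss_a)) {
    stop("unknown animal id(s): ", paste(miss_a, collapse = ", "), call. = FALSE)
  }
  miss_m <- setdiff(markers, colnames(g))
  if (length(miss_m)) {
    stop("unknown marker id(s): ", paste(miss_m, collapse = ", "), call. = FALSE)
  }
  genotype_matrix(unclass(g)[animals, markers, drop = FALSE], animals, markers)
}

#' Subset a haplotype panel
#'
#' @param h A `haplotype_panel`.
#' @param animals Animal ids to keep (`NULL` keeps all).
#' @param markers Marker ids to keep (`NULL` keeps all).
#' @return A `haplotype_panel`.
#' @export
subset_panel <- function(h, animals = NULL, markers = NULL) {
  if (is.null(animals)) animals <- panel_animal_ids(h)
  if (is.null(markers)) markers <- colnames(h)
  rows <- as.vector(rbind(paste0(animals, "_1"), paste0(animals, "_2")))
  missing_rows <- setdiff(rows, rownames(h))
  if (length(missing_rows)) {
    stop("unknown animal id(s) in panel: ",
         paste(sub("_[12]$", "", missing_rows), collapse = ", "), call. = FALSE)
  }
  miss_m <- setdiff(markers, colnames(h))
  if (length(miss_m)) {
    stop("unknown marker id(s): ", paste(miss_m, collapse = ", "), call. = FALSE)
  }
  haplotype_panel(unclass(h)[rows, markers, drop = FALSE], rows, markers)
}

#' Construct a marker map
#'
#' @param marker_id Character marker identifiers (unique).
#' @param chromosome Integer chromosome numbers.
#' @param position_bp Non-negative integer base-pair positions (1-based).
#' @param panel Panel membership, `"HD_ONLY"` or `"BOTH"` (present on both
#'   the high-density and the 50K-like chip).
#' @return A tibble sorted by (chromosome, position_bp) with class
#'   `marker_map` prepended.
#' @export
marker_map <- function(marker_id, chromosome, position_bp, panel) {
  stopifnot(!anyDuplicated(marker_id))
  if (!all(panel %in% c("HD_ONLY", "BOTH"))) {
    stop("panel must be 'HD_ONLY' or 'BOTH'", call. = FALSE)
  }
  if (any(position_bp < 0)) stop("negative position_bp", call. = FALSE)
  out <- tibble::tibble(
    marker_id = as.character(marker_id),
    chromosome = as.integer(chromosome),
    position_bp = as.integer(position_bp),
    panel = as.character(panel)
  )
  out <- dplyr::arrange(out, .data$chromosome, .data$position_bp, .data$marker_id)
  class(out) <- c("marker_map", class(out))
  out
}

#' Construct a pedigree
#'
#' @param animal_id Character animal identifiers (unique).
#' @param sire_id,dam_id Parent identifiers or `NA` when unknown.
#' @param sex `"M"` or `"F"`.
#' @param birth_year Integer birth years.
#' @param breed Breed label.
#' @return A tibble with class `pedigree` prepended. Referenced parents must
#'   be present in `animal_id` or `NA`; the parent graph must be acyclic.
#' @export
pedigree <- function(animal_id, sire_id, dam_id, sex, birth_year,
                     breed = "unknown") {
  out <- tibble::tibble(
    animal_id = as.character(animal_id),
    sire_id = as.character(sire_id),
    dam_id = as.character(dam_id),
    sex = as.character(sex),
    birth_year = as.integer(birth_year),
    breed = as.character(breed)
  )
  if (anyDuplicated(out$animal_id)) stop("duplicated animal ids", call. = FALSE)
  if (!all(out$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'", call. = FALSE)
  parents <- c(out$sire_id, out$dam_id)
  parents <- parents[!is.na(parents)]
  unknown <- setdiff(parents, out$animal_id)
  if (length(unknown)) {
    stop("parents absent from pedigree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pedigree_order(out) # errors on cycles
  class(out) <- c("pedigree", class(out))
  out
}

#' Topological (parents-before-offspring) order of a pedigree
#'
#' @param ped A pedigree tibble.
#' @return Character vector of animal ids such that every parent precedes all
#'   of its offspring. Errors if the parent graph contains a cycle.
#' @export
pedigree_order <- function(ped) {
  ids <- ped$animal_id
  idx <- stats::setNames(seq_along(ids), ids)
  sire <- ifelse(is.na(ped$sire_id), 0L, idx[ped$sire_id])
  dam <- ifelse(is.na(ped$dam_id), 0L, idx[ped$dam_id])
  n <- length(ids)
  depth <- rep(NA_integer_, n)
  pending <- rep(FALSE, n)
  calc <- function(i) {
    if (!is.na(depth[i])) return(depth[i])
    if (pending[i]) stop("pedigree contains a cycle", call. = FALSE)
    pending[i] <<- TRUE
    ds <- if (sire[i] > 0L) calc(sire[i]) else -1L
    dd <- if (dam[i] > 0L) calc(dam[i]) else -1L
    pending[i] <<- FALSE
    depth[i] <<- max(ds, dd) + 1L
    depth[i]
  }
  for (i in seq_len(n)) calc(i)
  ids[order(depth, seq_len(n))]
}
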