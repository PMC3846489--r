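#' Write genotypes (or phased haplotypes) to a plain-text VCF 4.2 file
#'
#' Biallelic SNPs only. Synthetic alleles `A` (reference) / `B` (alternate)
#' are written when the map carries no allele information; genotype codes
#' count copies of the alternate allele. Unphased genotypes use `/`
#' separators; a haplotype panel is written phased with `|`.
#'
#' @param x A `genotype_matrix` or a `haplotype_panel`.
#' @param map A `marker_map` covering all markers of `x`.
#' @param path Output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, map, path) {
  phased <- inherits(x, "haplotype_panel")
  markers <- colnames(x)
  map_use <- map[match(markers, map$marker_id), ]
  if (anyNA(map_use$marker_id)) {
    stop("map does not cover all markers", call. = FALSE)
  }
  if (phased) {
    n <- nrow(x) %/% 2L
    a1 <- unclass(x)[seq(1L, 2L * n, 2L), , drop = FALSE]
    a2 <- unclass(x)[seq(2L, 2L * n, 2L), , drop = FALSE]
    gt <- matrix(paste0(a1, "|", a2), nrow = n)
    samples <- panel_animal_ids(x)
  } else {
    codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow = nrow(x), ncol = ncol(x))
    ok <- !is.na(unclass(x))
    gt[ok] <- codes[as.character(unclass(x)[ok])]
    samples <- rownames(x)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hdimpute",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- cbind(
    map_use$chromosome, map_use$position_bp, markers, "A", "B", ".", ".", ".",
    "GT", t(gt)
  )
  lines <- c(header, apply(body, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a biallelic-SNP VCF file
#'
#' Parsing is delegated to \pkg{vcfR}. Genotype codes count copies of the
#' alternate allele. If every genotype is phased (`|` separators), a
#' `haplotype_panel` is returned as well.
#'
#' @param path VCF file path.
#' @return A list with elements `genotypes` (`genotype_matrix`), `map`
#'   (`marker_map`, with panel membership set to `"BOTH"` as VCF carries no
#'   panel annotation) and `haplotypes` (`haplotype_panel` or `NULL`).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt))) {
    stop("multiallelic records are not supported", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  gt_chr <- substr(gt, 1L, 3L)
  bad <- !is.na(gt_chr) & !gt_chr %in% c("0/0", "0/1", "1/0", "1/1", "0|0",
                                         "0|1", "1|0", "1|1", "./.", ".|.")
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("unsupported genotype '%s' at record %d (mixed ploidy or non-diploid call)",
                 gt[bad][1L], ij[1L]), call. = FALSE)
  }
  a1 <- suppressWarnings(as.integer(substr(gt, 1L, 1L)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3L, 3L)))
  calls <- a1 + a2
  calls <- matrix(calls, nrow = nrow(gt),
                  dimnames = list(fix[, "ID"], colnames(gt)))
  g <- genotype_matrix(t(calls), animal_ids = colnames(gt),
                       marker_ids = fix[, "ID"])
  map <- marker_map(fix[, "ID"], as.integer(fix[, "CHROM"]),
                    as.integer(fix[, "POS"]), rep("BOTH", nrow(fix)))
  haps <- NULL
  if (all(grepl("|", gt, fixed = TRUE)) && !anyNA(calls)) {
    animals <- colnames(gt)
    alleles <- matrix(0L, nrow = 2L * length(animals), ncol = nrow(gt))
    alleles[seq(1L, nrow(alleles), 2L), ] <- t(matrix(a1, nrow = nrow(gt)))
    alleles[seq(2L, nrow(alleles), 2L), ] <- t(matrix(a2, nrow = nrow(gt)))
    haps <- haplotype_panel(
      alleles,
      haplotype_ids = as.vector(rbind(paste0(animals, "_1"), paste0(animals, "_2"))),
      marker_ids = fix[, "ID"]
    )
  }
  list(genotypes = g, map = map, haplotypes = haps)
}

#' Read genotypes in VCF or PLINK-text format
#'
#' @param path File path. For `format = "PLINK_TEXT"` give the `.ped` file;
#'   the matching `.map` file must sit alongside it.
#' @param format `"VCF"` or `"PLINK_TEXT"`.
#' @return A list with `genotypes`, `map` and (VCF only, when fully phased)
#'   `haplotypes`.
#' @export
read_genotypes <- function(path, format = c("VCF", "PLINK_TEXT")) {
  format <- match.arg(format)
  if (format == "VCF") read_vcf(path) else read_plink(path)
}

#' Write genotypes as PLINK-text (.ped/.map) files
#'
#' Allele letters `A` (reference) and `B` (alternate) are used; missing calls
#' are written `0 0`.
#'
#' @param g A `genotype_matrix`.
#' @param map A `marker_map` covering all markers of `g`.
#' @param basename Output path without extension; `<basename>.ped` and
#'   `<basename>.map` are written.
#' @return `basename`, invisibly.
#' @export
write_plink <- function(g, map, basename) {
  markers <- colnames(g)
  map_use <- map[match(markers, map$marker_id), ]
  if (anyNA(map_use$marker_id)) stop("map does not cover all markers", call. = FALSE)
  pairs <- c(`0` = "A A", `1` = "A B", `2` = "B B")
  m <- matrix("0 0", nrow = nrow(g), ncol = ncol(g))
  ok <- !is.na(unclass(g))
  m[ok] <- pairs[as.character(unclass(g)[ok])]
  lines <- paste(rownames(g), rownames(g), 0, 0, 0, -9,
                 apply(m, 1L, paste, collapse = " "))
  writeLines(lines, paste0(basename, ".ped"))
  writeLines(paste(map_use$chromosome, markers, 0, map_use$position_bp,
                   sep = "\t"),
             paste0(basename, ".map"))
  invisible(basename)
}

#' Read PLINK-text (.ped/.map) genotypes
#'
#' Biallelic markers only. The alternate allele of each marker is designated
#' at first sight: when the observed alleles are exactly `{A, B}` the `B`
#' allele is the alternate (matching [write_plink()]); otherwise the first
#' non-missing allele encountered in file order becomes the alternate, so
#' that codes are assigned consistently within a file.
#'
#' @param path Path to the `.ped` file (with `<path minus .ped>.map` alongside)
#'   or the basename without extension.
#' @return A list with `genotypes` and `map` (panel set to `"BOTH"`).
#' @export
read_plink <- function(path) {
  base <- sub("\\.ped$", "", path)
  ped_file <- paste0(base, ".ped")
  map_file <- paste0(base, ".map")
  map_df <- utils::read.table(map_file, header = FALSE,
                              colClasses = c("integer", "character",
                                             "integer", "integer"))
  names(map_df) <- c("chromosome", "marker_id", "cm", "position_bp")
  fields <- strsplit(trimws(readLines(ped_file)), "[ \t]+")
  n_mark <- nrow(map_df)
  calls <- matrix(NA_integer_, nrow = length(fields), ncol = n_mark)
  animals <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 6L + 2L * n_mark) {
      stop(sprintf("malformed .ped record at line %d: %d fields, expected %d",
                   i, length(f), 6L + 2L * n_mark), call. = FALSE)
    }
    animals[i] <- f[2L]
  }
  allele1 <- do.call(rbind, lapply(fields, function(f) f[seq(7L, length(f), 2L)]))
  allele2 <- do.call(rbind, lapply(fields, function(f) f[seq(8L, length(f), 2L)]))
  for (j in seq_len(n_mark)) {
    a <- c(rbind(allele1[, j], allele2[, j]))
    seen <- unique(a[a != "0"])
    if (length(seen) > 2L) {
      stop(sprintf("marker %s has more than two alleles", map_df$marker_id[j]),
           call. = FALSE)
    }
    alt <- if (all(seen %in% c("A", "B"))) "B" else seen[1L]
    code <- (allele1[, j] == alt) + (allele2[, j] == alt)
    code[allele1[, j] == "0" | allele2[, j] == "0"] <- NA_integer_
    calls[, j] <- as.integer(code)
  }
  g <- genotype_matrix(calls, animal_ids = animals, marker_ids = map_df$marker_id)
  map <- marker_map(map_df$marker_id, map_df$chromosome, map_df$position_bp,
                    rep("BOTH", n_mark))
  list(genotypes = g, map = map)
}

#' Write a pedigree as tab-separated text
#'
#' Columns: id, sire, dam, sex, birth_year, breed. Unknown parents are
#' written as `0`.
#'
#' @param ped A pedigree tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- tibble::tibble(
    id = ped$animal_id,
    sire = ifelse(is.na(ped$sire_id), "0", ped$sire_id),
    dam = ifelse(is.na(ped$dam_id), "0", ped$dam_id),
    sex = ped$sex,
    birth_year = ped$birth_year,
    breed = ped$breed
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a tab-separated pedigree file written by [write_pedigree()]
#'
#' @param path File path.
#' @return A `pedigree` tibble.
#' @export
read_pedigree <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         id = "c", sire = "c", dam = "c", sex = "c",
                         birth_year = "i", breed = "c"
                       ))
  pedigree(d$id,
           ifelse(d$sire == "0", NA_character_, d$sire),
           ifelse(d$dam == "0", NA_character_, d$dam),
           d$sex, d$birth_year, d$breed)
}

#' Write a marker map as tab-separated text
#'
#' @param map A `marker_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(map, path) {
  readr::write_tsv(tibble::as_tibble(unclass(map)[c("marker_id", "chromosome",
                                                    "position_bp", "panel")]),
                   path)
  invisible(path)
}

#' Read a tab-separated marker map written by [write_marker_map()]
#'
#' @param path File path.
#' @return A `marker_map`.
#' @export
read_marker_map <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         marker_id = "c", chromosome = "i",
                         position_bp = "i", panel = "c"
                       ))
  marker_map(d$marker_id, d$chromosome, d$position_bp, d$panel)
}
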