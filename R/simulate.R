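#' Simulation configuration
#'
#' Parameters of the synthetic two-panel breed generator. Defaults emulate a
#' dairy-type population: a founder pool of 120 animals expanded for two
#' further generations with 2.5 genotyped progeny per sire, five chromosomes
#' carrying 2000 high-density markers each at ~3.5 kb spacing (the density of
#' a 777K-class chip), of which 5% are shared with the 50K-like panel
#' (~70 kb between informative medium-density markers), and founder-haplotype
#' linkage disequilibrium tuned so that mean r-squared at 70 kb falls in the
#' dairy range (about 0.2-0.26).
#'
#' @param n_founders Number of founder animals (positive integer).
#' @param n_generations Total number of generations including founders.
#' @param progeny_per_sire_mean Mean number of genotyped progeny per sire
#'   (Poisson family sizes).
#' @param n_chromosomes Number of autosomes to simulate.
#' @param markers_per_chromosome_hd High-density markers per chromosome.
#' @param fraction_shared_50k Fraction of HD markers also present on the
#'   50K-like panel, in (0, 1].
#' @param chromosome_length_bp Chromosome length in base pairs.
#' @param ld_strength Length scale (bp) of founder-haplotype correlation
#'   decay; 0 gives independent sites, larger values give longer-range LD.
#' @param missing_rate Per-call missingness probability in [0, 1).
#' @param genotype_error_rate Per-call probability of replacement by a random
#'   different code, in [0, 1).
#' @param n_mismapped Number of markers whose map positions are exchanged
#'   with distant positions (mimicking assembly errors).
#' @param seed Integer random seed.
#' @param breed Breed label carried into the pedigree.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 120L,
                       n_generations = 3L,
                       progeny_per_sire_mean = 2.5,
                       n_chromosomes = 5L,
                       markers_per_chromosome_hd = 2000L,
                       fraction_shared_50k = 0.05,
                       chromosome_length_bp = 7e6,
                       ld_strength = 3e5,
                       missing_rate = 0.005,
                       genotype_error_rate = 0.001,
                       n_mismapped = 0L,
                       seed = 1L,
                       breed = "SIMBREED") {
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    progeny_per_sire_mean = as.numeric(progeny_per_sire_mean),
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome_hd = as.integer(markers_per_chromosome_hd),
    fraction_shared_50k = as.numeric(fraction_shared_50k),
    chromosome_length_bp = as.numeric(chromosome_length_bp),
    ld_strength = as.numeric(ld_strength),
    missing_rate = as.numeric(missing_rate),
    genotype_error_rate = as.numeric(genotype_error_rate),
    n_mismapped = as.integer(n_mismapped),
    seed = as.integer(seed),
    breed = as.character(breed)
  )
  stopifnot(
    cfg$n_founders >= 1L, cfg$n_generations >= 1L,
    cfg$progeny_per_sire_mean > 0, cfg$n_chromosomes >= 1L,
    cfg$markers_per_chromosome_hd >= 1L,
    cfg$fraction_shared_50k > 0, cfg$fraction_shared_50k <= 1,
    cfg$chromosome_length_bp >= 1,
    cfg$ld_strength >= 0,
    cfg$missing_rate >= 0, cfg$missing_rate < 1,
    cfg$genotype_error_rate >= 0, cfg$genotype_error_rate < 1,
    cfg$n_mismapped >= 0L
  )
  if (cfg$fraction_shared_50k * cfg$markers_per_chromosome_hd < 2 &&
      cfg$markers_per_chromosome_hd >= 2L) {
    stop("fraction_shared_50k x markers_per_chromosome_hd must be >= 2",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Marker map implied by a simulation configuration
#'
#' Markers are equally spaced along each chromosome; the shared (50K-like)
#' subset is itself equally spaced within the HD grid. The map is a pure
#' function of the configuration (it does not depend on the seed), so
#' replicate populations simulated under the same configuration share one
#' map.
#'
#' @param cfg A `sim_config`.
#' @return A `marker_map`.
#' @export
make_marker_map <- function(cfg) {
  m <- cfg$markers_per_chromosome_hd
  spacing <- cfg$chromosome_length_bp / m
  pos <- as.integer(round(spacing * (seq_len(m) - 0.5)) + 1L)
  n_shared <- max(2L, round(cfg$fraction_shared_50k * m))
  if (cfg$fraction_shared_50k >= 1) n_shared <- m
  if (m == 1L) n_shared <- 1L
  shared_idx <- unique(round(seq(1L, m, length.out = n_shared)))
  panel <- rep("HD_ONLY", m)
  panel[shared_idx] <- "BOTH"
  maps <- lapply(seq_len(cfg$n_chromosomes), function(chr) {
    marker_map(sprintf("c%d_m%04d", chr, seq_len(m)),
               rep(chr, m), pos, panel)
  })
  out <- dplyr::bind_rows(maps)
  class(out) <- c("marker_map", class(out))
  out
}

founder_ids <- function(cfg) {
  sprintf("%s_F%04d", cfg$breed, seq_len(cfg$n_founders))
}

#' Simulate founder haplotypes with distance-dependent LD
#'
#' Each haplotype follows a first-order latent copying process along the
#' markers of a chromosome: a latent uniform variate is retained from the
#' previous marker with probability `exp(-distance / ld_strength)` and
#' redrawn otherwise; the allele is the indicator that the latent variate
#' falls below the marker's allele frequency (drawn uniformly in
#' [0.1, 0.9]). Retention induces positive allele correlation that decays
#' with distance, giving an LD decay curve whose level at 70 kb is governed
#' by `ld_strength`; `ld_strength = 0` gives independent sites. Columns that
#' come out monomorphic are redrawn (and, as a last resort, one allele is
#' flipped) so every marker is polymorphic among the founders.
#'
#' @param cfg A `sim_config` (uses `cfg$seed`).
#' @param map Optional `marker_map`; defaults to `make_marker_map(cfg)`.
#' @return A `haplotype_panel` with `2 * n_founders` haplotypes.
#' @export
simulate_founder_haplotypes <- function(cfg, map = make_marker_map(cfg)) {
  if (cfg$n_founders < 1L || cfg$markers_per_chromosome_hd < 1L) {
    stop("degenerate configuration: need at least one founder and one marker",
         call. = FALSE)
  }
  set.seed(cfg$seed)
  n_hap <- 2L * cfg$n_founders
  blocks <- vector("list", cfg$n_chromosomes)
  for (chr in seq_len(cfg$n_chromosomes)) {
    pos <- map$position_bp[map$chromosome == chr]
    m <- length(pos)
    p <- stats::runif(m, 0.1, 0.9)
    keep_prob <- if (cfg$ld_strength > 0) {
      c(0, exp(-diff(pos) / cfg$ld_strength))
    } else {
      rep(0, m)
    }
    draw_col_block <- function() {
      h <- matrix(0L, n_hap, m)
      for (i in seq_len(n_hap)) {
        reset <- stats::runif(m) >= keep_prob
        reset[1L] <- TRUE
        seg <- cumsum(reset)
        u <- stats::runif(max(seg))[seg]
        h[i, ] <- as.integer(u < p)
      }
      h
    }
    h <- draw_col_block()
    # ensure polymorphism
    for (attempt in seq_len(20L)) {
      mono <- which(colSums(h) == 0L | colSums(h) == n_hap)
      if (!length(mono)) break
      for (j in mono) {
        u <- stats::runif(n_hap)
        h[, j] <- as.integer(u < p[j])
      }
    }
    mono <- which(colSums(h) == 0L | colSums(h) == n_hap)
    for (j in mono) h[sample.int(n_hap, 1L), j] <- 1L - h[1L, j]
    blocks[[chr]] <- h
  }
  alleles <- do.call(cbind, blocks)
  ids <- founder_ids(cfg)
  haplotype_panel(
    alleles,
    haplotype_ids = as.vector(rbind(paste0(ids, "_1"), paste0(ids, "_2"))),
    marker_ids = map$marker_id
  )
}

#' Generate a pedigree with sire-family structure
#'
#' Founders (generation 0, birth year 0) have unknown parents and alternating
#' sex. In each later generation every male of the previous generation is
#' used as a sire with a Poisson(`progeny_per_sire_mean`) number of progeny;
#' dams are drawn with replacement from all earlier-generation females.
#' Birth year equals the generation index.
#'
#' @param cfg A `sim_config` (uses `cfg$seed + 1` for reproducibility of the
#'   pedigree stage).
#' @return A `pedigree` tibble.
#' @export
generate_pedigree <- function(cfg) {
  if (cfg$n_founders < 2L && cfg$n_generations > 1L) {
    stop("need at least 2 founders to breed further generations", call. = FALSE)
  }
  set.seed(cfg$seed + 1L)
  ids <- founder_ids(cfg)
  sex <- rep(c("M", "F"), length.out = cfg$n_founders)
  ped <- tibble::tibble(
    animal_id = ids, sire_id = NA_character_, dam_id = NA_character_,
    sex = sex, birth_year = 0L, breed = cfg$breed
  )
  if (cfg$n_generations > 1L) {
    for (g in seq_len(cfg$n_generations - 1L)) {
      prev <- ped[ped$birth_year == g - 1L, ]
      sires <- prev$animal_id[prev$sex == "M"]
      dams_pool <- ped$animal_id[ped$sex == "F"]
      if (!length(sires) || !length(dams_pool)) break
      n_prog <- stats::rpois(length(sires), cfg$progeny_per_sire_mean)
      total <- sum(n_prog)
      if (total == 0L) next
      sire_col <- rep(sires, n_prog)
      dam_col <- sample(dams_pool, total, replace = TRUE)
      new <- tibble::tibble(
        animal_id = sprintf("%s_G%d_%04d", cfg$breed, g, seq_len(total)),
        sire_id = sire_col,
        dam_id = dam_col,
        sex = sample(c("M", "F"), total, replace = TRUE),
        birth_year = g,
        breed = cfg$breed
      )
      ped <- dplyr::bind_rows(ped, new)
    }
  }
  pedigree(ped$animal_id, ped$sire_id, ped$dam_id, ped$sex, ped$birth_year,
           ped$breed)
}

# one recombined gamete from a parent's two haplotypes on one chromosome
recombine_gamete <- function(h1, h2, pos, genetic_length_morgan) {
  n_xo <- stats::rpois(1L, genetic_length_morgan)
  start <- sample.int(2L, 1L)
  if (n_xo == 0L) {
    return(if (start == 1L) h1 else h2)
  }
  breaks <- sort(stats::runif(n_xo, 0, max(pos)))
  seg <- findInterval(pos, breaks) # 0..n_xo
  use_h1 <- (seg + start) %% 2L == 1L
  out <- h2
  out[use_h1] <- h1[use_h1]
  out
}

#' Drop founder haplotypes through a pedigree
#'
#' Standard Mendelian gene-drop: each non-founder receives one recombined
#' gamete from each parent. Crossover counts per chromosome are Poisson with
#' mean equal to the chromosome's genetic length under a uniform 1 cM/Mb map
#' (Haldane, no interference). Genotypes are the allele sums of the
#' transmitted haplotypes and are therefore Mendelian-consistent.
#'
#' @param founders A `haplotype_panel` covering every pedigree founder.
#' @param ped A `pedigree`.
#' @param cfg A `sim_config` (uses `cfg$seed + 2`).
#' @param map Optional `marker_map`; defaults to `make_marker_map(cfg)`.
#' @return A list of class `sim_dataset` with elements `truth_haplotypes`,
#'   `genotypes`, `map`, `pedigree` and `mismapped_ids` (empty here).
#' @export
gene_drop <- function(founders, ped, cfg, map = make_marker_map(cfg)) {
  set.seed(cfg$seed + 2L)
  order_ids <- pedigree_order(ped)
  founder_rows <- ped$animal_id[is.na(ped$sire_id) & is.na(ped$dam_id)]
  missing_founders <- setdiff(founder_rows, panel_animal_ids(founders))
  if (length(missing_founders)) {
    stop("pedigree founders without founder haplotypes: ",
         paste(utils::head(missing_founders, 5L), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(ped)
  m <- ncol(founders)
  alleles <- matrix(0L, nrow = 2L * n, ncol = m)
  row_of <- stats::setNames(seq_len(n), order_ids)
  ped_idx <- match(order_ids, ped$animal_id)
  sire <- ped$sire_id[ped_idx]
  dam <- ped$dam_id[ped_idx]
  chroms <- unique(map$chromosome)
  chr_cols <- lapply(chroms, function(ch) which(map$chromosome == ch))
  chr_pos <- lapply(chr_cols, function(cc) map$position_bp[cc])
  chr_len_morgan <- vapply(chr_pos, function(p) max(p) * 1e-8, numeric(1))
  for (i in seq_len(n)) {
    id <- order_ids[i]
    if (is.na(sire[i]) != is.na(dam[i])) {
      stop("animal ", id, " has exactly one known parent; gene drop needs both or none",
           call. = FALSE)
    }
    if (is.na(sire[i])) {
      alleles[2L * i - 1L, ] <- unclass(founders)[paste0(id, "_1"), ]
      alleles[2L * i, ] <- unclass(founders)[paste0(id, "_2"), ]
    } else {
      si <- row_of[[sire[i]]]
      di <- row_of[[dam[i]]]
      for (k in seq_along(chroms)) {
        cc <- chr_cols[[k]]
        alleles[2L * i - 1L, cc] <- recombine_gamete(
          alleles[2L * si - 1L, cc], alleles[2L * si, cc],
          chr_pos[[k]], chr_len_morgan[k]
        )
        alleles[2L * i, cc] <- recombine_gamete(
          alleles[2L * di - 1L, cc], alleles[2L * di, cc],
          chr_pos[[k]], chr_len_morgan[k]
        )
      }
    }
  }
  hap_ids <- as.vector(rbind(paste0(order_ids, "_1"), paste0(order_ids, "_2")))
  truth <- haplotype_panel(alleles, hap_ids, colnames(founders))
  out <- list(
    truth_haplotypes = truth,
    genotypes = panel_to_genotypes(truth),
    map = map,
    pedigree = ped,
    mismapped_ids = character(0)
  )
  class(out) <- "sim_dataset"
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d animals, %d markers on %d chromosome(s), %d mismapped\n",
    nrow(x$genotypes), ncol(x$genotypes), length(unique(x$map$chromosome)),
    length(x$mismapped_ids)
  ))
  invisible(x)
}

#' Plan a set of mismapped markers
#'
#' Picks `n` markers (HD-only when possible, since those are the ones whose
#' imputation is evaluated) and pairs them so that the two members of each
#' pair exchange map positions; pairs are redrawn until the exchanged
#' positions are distant (different chromosome, or at least
#' `min_distance_frac` of the chromosome length apart). Assembly errors are a
#' property of the map, so one plan is intended to be shared by all
#' populations genotyped on the same chip.
#'
#' @param map A `marker_map`.
#' @param n Number of mismapped markers (even; odd values are rounded up).
#' @param seed Integer seed.
#' @param min_distance_frac Minimum exchange distance as a fraction of the
#'   chromosome length, for within-chromosome exchanges.
#' @return A tibble (`marker_id`, `new_chromosome`, `new_position_bp`).
#' @export
plan_mismapping <- function(map, n, seed = 1L, min_distance_frac = 0.25) {
  if (n == 0L) {
    return(tibble::tibble(marker_id = character(0),
                          new_chromosome = integer(0),
                          new_position_bp = integer(0)))
  }
  set.seed(seed)
  n <- as.integer(n)
  if (n %% 2L == 1L) n <- n + 1L
  pool <- map$marker_id[map$panel == "HD_ONLY"]
  if (length(pool) < n) pool <- map$marker_id
  if (length(pool) < n) {
    stop("not enough markers to mismap", call. = FALSE)
  }
  chr_len <- max(map$position_bp)
  min_d <- min_distance_frac * chr_len
  info <- map[match(pool, map$marker_id), ]
  # build pairs greedily: each marker is matched with the first remaining
  # candidate that is distant enough
  order_idx <- sample(seq_along(pool))
  used <- rep(FALSE, length(pool))
  a_sel <- integer(0)
  b_sel <- integer(0)
  for (a in order_idx) {
    if (length(a_sel) == n / 2L) break
    if (used[a]) next
    partners <- order_idx[!used[order_idx] & order_idx != a]
    ok <- info$chromosome[partners] != info$chromosome[a] |
      abs(info$position_bp[partners] - info$position_bp[a]) >= min_d
    if (!any(ok)) next
    b <- partners[which(ok)[1L]]
    used[c(a, b)] <- TRUE
    a_sel <- c(a_sel, a)
    b_sel <- c(b_sel, b)
  }
  if (length(a_sel) < n / 2L) {
    stop("could not find a distant mismapping plan; lower min_distance_frac",
         call. = FALSE)
  }
  tibble::tibble(
    marker_id = c(pool[a_sel], pool[b_sel]),
    new_chromosome = c(info$chromosome[b_sel], info$chromosome[a_sel]),
    new_position_bp = c(info$position_bp[b_sel], info$position_bp[a_sel])
  )
}

#' Inject missingness, genotyping error and mismapped markers
#'
#' Each observed genotype call is set to missing independently with
#' probability `missing_rate` and, if still observed, replaced by a random
#' different valid code with probability `genotype_error_rate`. Map positions
#' of the planned mismapped markers are exchanged (genotype values are
#' untouched - the marker's data are real, its claimed position is wrong).
#' Truth haplotypes are never modified.
#'
#' @param data A `sim_dataset` from [gene_drop()].
#' @param cfg A `sim_config` (uses `cfg$seed + 3`).
#' @param mismap_plan Optional plan from [plan_mismapping()]; defaults to a
#'   plan of `cfg$n_mismapped` markers drawn with seed `cfg$seed + 4`.
#' @return The modified `sim_dataset`, with `mismapped_ids` recorded.
#' @export
inject_artifacts <- function(data, cfg, mismap_plan = NULL) {
  set.seed(cfg$seed + 3L)
  g <- unclass(data$genotypes)
  n_cell <- length(g)
  if (cfg$missing_rate > 0) {
    g[stats::runif(n_cell) < cfg$missing_rate] <- NA_integer_
  }
  if (cfg$genotype_error_rate > 0) {
    hit <- which(!is.na(g) & stats::runif(n_cell) < cfg$genotype_error_rate)
    if (length(hit)) {
      shift <- sample.int(2L, length(hit), replace = TRUE)
      g[hit] <- (g[hit] + shift) %% 3L
    }
  }
  data$genotypes <- genotype_matrix(g, rownames(data$genotypes),
                                    colnames(data$genotypes))
  if (is.null(mismap_plan)) {
    mismap_plan <- plan_mismapping(data$map, cfg$n_mismapped,
                                   seed = cfg$seed + 4L)
  }
  if (nrow(mismap_plan)) {
    map <- data$map
    i <- match(mismap_plan$marker_id, map$marker_id)
    if (anyNA(i)) stop("mismap plan refers to unknown markers", call. = FALSE)
    map$chromosome[i] <- mismap_plan$new_chromosome
    map$position_bp[i] <- mismap_plan$new_position_bp
    map <- dplyr::arrange(map, .data$chromosome, .data$position_bp,
                          .data$marker_id)
    class(map) <- c("marker_map", class(tibble::tibble()))
    data$map <- map
    # keep matrices in map order so downstream position-sorted access is cheap
    data$genotypes <- subset_genotypes(data$genotypes, markers = map$marker_id)
    data$truth_haplotypes <- subset_panel(data$truth_haplotypes,
                                          markers = map$marker_id)
    data$mismapped_ids <- sort(unique(mismap_plan$marker_id))
  }
  data
}

#' Extract the HD and 50K-like genotype panels
#'
#' @param data A `sim_dataset`.
#' @return A list with `hd` (all markers) and `k50` (columns restricted to
#'   the shared markers, a strict subset of HD unless every marker is
#'   shared).
#' @export
extract_panels <- function(data) {
  shared <- data$map$marker_id[data$map$panel == "BOTH"]
  if (!length(shared)) stop("no shared (BOTH) markers in map", call. = FALSE)
  list(
    hd = data$genotypes,
    k50 = subset_genotypes(data$genotypes, markers = shared)
  )
}

#' Simulate a complete breed dataset
#'
#' Convenience pipeline: founder haplotypes, pedigree, gene drop, artifact
#' injection. Fully deterministic given the configuration (all stages derive
#' their seeds from `cfg$seed`).
#'
#' @param cfg A `sim_config`.
#' @param mismap_plan Optional shared mismapping plan (see
#'   [plan_mismapping()]).
#' @return A `sim_dataset`.
#' @export
simulate_breed <- function(cfg, mismap_plan = NULL) {
  map <- make_marker_map(cfg)
  founders <- simulate_founder_haplotypes(cfg, map)
  ped <- generate_pedigree(cfg)
  data <- gene_drop(founders, ped, cfg, map)
  inject_artifacts(data, cfg, mismap_plan)
}
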