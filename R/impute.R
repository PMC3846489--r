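#' Imputation / phasing configuration
#'
#' Parameters of the haplotype-copying hidden Markov model. The hidden state
#' is the reference haplotype being copied; between adjacent markers the
#' chain switches template with probability
#' `1 - exp(-recomb_rate_per_bp * delta_bp * n_ref_haplotypes)`, the new
#' template drawn uniformly; the observed allele matches the copied one with
#' probability `1 - copy_error`.
#'
#' @param copy_error Mismatch (emission) probability, in (0, 1).
#' @param recomb_rate_per_bp Transition scale per base pair and per reference
#'   haplotype (default 1e-10). Under the Li-Stephens population-genetic
#'   interpretation the joint switch intensity per bp is about
#'   4 Ne c / K for K reference haplotypes; with a 1 cM/Mb map
#'   (c = 1e-8) and the effective population sizes typical of managed
#'   livestock breeds (Ne of order 100) this is of order 1e-10 per
#'   reference haplotype for panels of a few hundred haplotypes.
#' @param n_phasing_iterations Iterations of conditional re-phasing of the
#'   reference panel (default 20).
#' @param n_target_phasing_passes Path-sampling passes used to pre-phase each
#'   target animal at its observed markers (default 2).
#' @param seed Integer seed for the stochastic phasing stages.
#' @return A list of class `imputation_config`.
#' @export
imputation_config <- function(copy_error = 0.001,
                              recomb_rate_per_bp = 1e-10,
                              n_phasing_iterations = 20L,
                              n_target_phasing_passes = 2L,
                              seed = 1L) {
  cfg <- list(
    copy_error = copy_error,
    recomb_rate_per_bp = recomb_rate_per_bp,
    n_phasing_iterations = as.integer(n_phasing_iterations),
    n_target_phasing_passes = as.integer(n_target_phasing_passes),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$copy_error > 0, cfg$copy_error < 1,
    cfg$recomb_rate_per_bp > 0,
    cfg$n_phasing_iterations >= 1L,
    cfg$n_target_phasing_passes >= 1L
  )
  class(cfg) <- "imputation_config"
  cfg
}

# markers of one chromosome in position order
chromosome_blocks <- function(map, markers) {
  map_use <- map[map$marker_id %in% markers, ]
  split_ord <- order(map_use$chromosome, map_use$position_bp,
                     map_use$marker_id)
  map_use <- map_use[split_ord, ]
  split(map_use, map_use$chromosome)
}

#' Phase a reference panel by iterative conditional haplotype copying
#'
#' Each animal is repeatedly re-phased against the current haplotypes of all
#' other animals: a template path is sampled from the copying model given the
#' genotype-constrained emissions (homozygous sites pin the allele,
#' heterozygous and missing sites are uninformative), the leading haplotype
#' takes the path's alleles at unresolved sites, and the second haplotype is
#' its genotype complement (with its own chain filling missing calls).
#' Haplotype pairs always sum to the genotype at non-missing markers; missing
#' calls are imputed during phasing. Chromosomes are phased independently.
#'
#' @param g A `genotype_matrix` with at least 2 animals.
#' @param map A `marker_map` covering the markers of `g`.
#' @param cfg An `imputation_config`.
#' @return A `haplotype_panel` (two rows per animal, marker columns in map
#'   order).
#' @export
phase_reference <- function(g, map, cfg = imputation_config()) {
  if (nrow(g) < 2L) {
    warning("single-animal panel: heterozygote orientation is arbitrary",
            call. = FALSE)
  }
  set.seed(cfg$seed)
  blocks <- chromosome_blocks(map, colnames(g))
  out <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    gm <- unclass(g)[, blk$marker_id, drop = FALSE]
    gm[is.na(gm)] <- -1L
    rate_dbp <- cfg$recomb_rate_per_bp * diff(blk$position_bp)
    H <- .phase_chromosome_cpp(gm, rate_dbp, cfg$copy_error,
                               cfg$n_phasing_iterations)
    colnames(H) <- blk$marker_id
    out[[b]] <- H
  }
  alleles <- do.call(cbind, out)
  ids <- rownames(g)
  haplotype_panel(
    alleles,
    haplotype_ids = as.vector(rbind(paste0(ids, "_1"), paste0(ids, "_2"))),
    marker_ids = colnames(alleles)
  )
}

#' Impute masked genotypes with the haplotype-copying model
#'
#' Target animals are first pre-phased at their observed markers against the
#' reference panel; each of the two haplotype chains is then run
#' forward-backward over all reference markers, and the genotype posterior is
#' the convolution of the two independent haplotype allele posteriors. No
#' pedigree information is used.
#'
#' @param ref A phased `haplotype_panel` (the reference population).
#' @param target A `genotype_matrix`; markers must be a subset of the
#'   reference markers, with masked (to-impute) entries set to `NA`.
#' @param map A `marker_map` covering the reference markers.
#' @param cfg An `imputation_config`.
#' @return An object of class `imputed_genotypes`: list with `hard_calls`
#'   (a `genotype_matrix` over all reference markers; equal to the observed
#'   call wherever one exists), `dosages` (expected alternate-allele counts
#'   in [0, 2]) and `posterior_max` (probability of the selected genotype).
#' @export
impute_target <- function(ref, target, map, cfg = imputation_config()) {
  if (nrow(ref) == 0L) stop("zero reference haplotypes", call. = FALSE)
  extra <- setdiff(colnames(target), colnames(ref))
  if (length(extra)) {
    stop("target markers absent from reference: ",
         paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  set.seed(cfg$seed + 1000L)
  blocks <- chromosome_blocks(map, colnames(ref))
  animals <- rownames(target)
  n <- length(animals)
  dos <- list()
  pmax_l <- list()
  hard <- list()
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    mk <- blk$marker_id
    m <- length(mk)
    refm <- unclass(ref)[, mk, drop = FALSE]
    gm <- matrix(-1L, nrow = n, ncol = m)
    present <- mk %in% colnames(target)
    tg <- unclass(target)[, mk[present], drop = FALSE]
    tg[is.na(tg)] <- -1L
    gm[, present] <- tg
    rate_dbp <- cfg$recomb_rate_per_bp * diff(blk$position_bp)
    haps <- .phase_target_cpp(refm, gm, rate_dbp, cfg$copy_error,
                              cfg$n_target_phasing_passes)
    p1 <- .impute_posteriors_cpp(refm, haps, rate_dbp, cfg$copy_error)
    pa <- p1[seq(1L, 2L * n, 2L), , drop = FALSE]
    pb <- p1[seq(2L, 2L * n, 2L), , drop = FALSE]
    p0 <- (1 - pa) * (1 - pb)
    p2 <- pa * pb
    p1g <- 1 - p0 - p2
    hc <- (p1g > p0 & p1g >= p2) + 2L * (p2 > p0 & p2 > p1g)
    pm <- pmax(p0, p1g, p2)
    dsg <- pa + pb
    # observed calls are never re-imputed
    obs <- gm >= 0L
    hc[obs] <- gm[obs]
    dsg[obs] <- gm[obs]
    pm[obs] <- 1
    colnames(hc) <- colnames(dsg) <- colnames(pm) <- mk
    hard[[b]] <- hc
    dos[[b]] <- dsg
    pmax_l[[b]] <- pm
  }
  hard_calls <- genotype_matrix(do.call(cbind, hard), animals,
                                unlist(lapply(blocks, `[[`, "marker_id")))
  out <- list(
    hard_calls = hard_calls,
    dosages = {
      d <- do.call(cbind, dos); rownames(d) <- animals; d
    },
    posterior_max = {
      p <- do.call(cbind, pmax_l); rownames(p) <- animals; p
    }
  )
  class(out) <- "imputed_genotypes"
  out
}

#' @export
print.imputed_genotypes <- function(x, ...) {
  cat(sprintf("<imputed_genotypes> %d animals x %d markers\n",
              nrow(x$hard_calls), ncol(x$hard_calls)))
  invisible(x)
}

#' Allele posterior of one haplotype under the copying model
#'
#' Low-level access to the forward-backward recursion, mainly useful for
#' closed-form checks on small instances.
#'
#' @param ref A `haplotype_panel` or 0/1 matrix (haplotypes in rows).
#' @param obs Integer vector of observed alleles (0/1, `NA` = missing), one
#'   per reference marker.
#' @param positions_bp Marker positions in bp.
#' @param cfg An `imputation_config`.
#' @return Numeric vector of `P(allele = 1)` per marker.
#' @export
hap_copy_posterior <- function(ref, obs, positions_bp,
                               cfg = imputation_config()) {
  refm <- unclass(ref)
  storage.mode(refm) <- "integer"
  obs <- as.integer(obs)
  obs[is.na(obs)] <- -1L
  stopifnot(length(obs) == ncol(refm), length(positions_bp) == ncol(refm))
  rate_dbp <- cfg$recomb_rate_per_bp * diff(as.numeric(positions_bp))
  as.numeric(.ls_posterior_cpp(refm, obs, rate_dbp, cfg$copy_error))
}
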