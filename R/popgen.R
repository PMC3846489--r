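#' Squared correlation (r-squared) between two markers from phased haplotypes
#'
#' Computed from haplotype frequencies:
#' \deqn{r^2 = (p_{A1B1} - p_{A1} p_{B1})^2 / (p_{A1} p_{A2} p_{B1} p_{B2})}
#' where frequencies are counted over the haplotypes of the panel. The value
#' is symmetric in the two markers and invariant to allele relabeling.
#'
#' @param h A `haplotype_panel`.
#' @param marker_a,marker_b Marker identifiers.
#' @return r-squared in [0, 1].
#' @export
compute_r2 <- function(h, marker_a, marker_b) {
  a <- unclass(h)[, marker_a]
  b <- unclass(h)[, marker_b]
  pa <- mean(a)
  pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    stop("monomorphic marker: r-squared undefined", call. = FALSE)
  }
  pab <- mean(a * b)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Linkage-disequilibrium decay curve
#'
#' r-squared is computed for every intra-chromosome marker pair within
#' `max_dist_bp` whose two markers both have minor allele frequency at least
#' `maf_min` (the filter is applied pairwise, low-MAF markers are not removed
#' beforehand), then averaged in distance bins of width `bin_width_bp`
#' (`[0, w), [w, 2w), ...`).
#'
#' @param h A `haplotype_panel`.
#' @param map A `marker_map` covering the panel's markers.
#' @param maf_min Pairwise minor-allele-frequency filter (default 0.05).
#' @param bin_width_bp Distance bin width in bp (default 10 kb).
#' @param max_dist_bp Maximum pair distance in bp (default 1 Mb).
#' @param chromosomes Optional subset of chromosomes to use.
#' @return A tibble of class `ld_decay` with columns `bin_start_bp`,
#'   `bin_end_bp`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(h, map, maf_min = 0.05, bin_width_bp = 1e4,
                     max_dist_bp = 1e6, chromosomes = NULL) {
  map_use <- map[map$marker_id %in% colnames(h), ]
  if (!is.null(chromosomes)) {
    map_use <- map_use[map_use$chromosome %in% chromosomes, ]
  }
  n_bins <- ceiling(max_dist_bp / bin_width_bp)
  sum_r2 <- numeric(n_bins)
  n_pairs <- integer(n_bins)
  alle <- unclass(h)
  n_hap <- nrow(alle)
  for (chr in unique(map_use$chromosome)) {
    sub <- map_use[map_use$chromosome == chr, ]
    sub <- sub[order(sub$position_bp), ]
    m <- nrow(sub)
    if (m < 2L) next
    a <- alle[, sub$marker_id, drop = FALSE]
    pos <- sub$position_bp
    p <- colMeans(a)
    maf_ok <- pmin(p, 1 - p) >= maf_min
    for (k in seq_len(m - 1L)) {
      d <- pos[(k + 1L):m] - pos[seq_len(m - k)]
      if (min(d) > max_dist_bp) break
      i <- seq_len(m - k)
      j <- i + k
      keep <- d <= max_dist_bp & maf_ok[i] & maf_ok[j] &
        p[i] > 0 & p[i] < 1 & p[j] > 0 & p[j] < 1
      if (!any(keep)) next
      i <- i[keep]; j <- j[keep]; d <- d[keep]
      pab <- colMeans(a[, i, drop = FALSE] * a[, j, drop = FALSE])
      r2 <- (pab - p[i] * p[j])^2 /
        (p[i] * (1 - p[i]) * p[j] * (1 - p[j]))
      bin <- pmin(floor(d / bin_width_bp) + 1L, n_bins)
      for (bb in unique(bin)) {
        sel <- bin == bb
        sum_r2[bb] <- sum_r2[bb] + sum(r2[sel])
        n_pairs[bb] <- n_pairs[bb] + sum(sel)
      }
    }
  }
  if (!sum(n_pairs)) stop("no eligible marker pairs for LD computation",
                          call. = FALSE)
  out <- tibble::tibble(
    bin_start_bp = (seq_len(n_bins) - 1L) * bin_width_bp,
    bin_end_bp = seq_len(n_bins) * bin_width_bp,
    mean_r2 = ifelse(n_pairs > 0L, sum_r2 / n_pairs, NA_real_),
    n_pairs = n_pairs
  )
  out <- out[out$n_pairs > 0L, ]
  class(out) <- c("ld_decay", class(out))
  out
}

#' LD level at a given distance
#'
#' Returns the mean r-squared of the decay-curve bin containing the requested
#' distance (default 70 kb, the average spacing between informative markers
#' on a 50K-class chip).
#'
#' @param curve An `ld_decay` tibble.
#' @param distance_bp Distance of interest in bp.
#' @return Mean r-squared of the covering bin.
#' @export
ld_at <- function(curve, distance_bp = 70000) {
  row <- curve[curve$bin_start_bp <= distance_bp &
                 curve$bin_end_bp > distance_bp, ]
  if (!nrow(row) || is.na(row$mean_r2[1L])) {
    stop("no LD bin covers the requested distance", call. = FALSE)
  }
  row$mean_r2[1L]
}

#' Pedigree additive (numerator) relationship matrix
#'
#' Wright's numerator relationship by the recursive tabular method:
#' `a(i,i) = 1 + a(sire_i, dam_i) / 2` and, for i later than j,
#' `a(i,j) = (a(j, sire_i) + a(j, dam_i)) / 2`, with unknown parents
#' contributing zero.
#'
#' @param ped A `pedigree`.
#' @param animals Optional animal ids; the returned matrix is restricted to
#'   these rows/columns (the recursion always runs over the whole pedigree).
#' @return A symmetric numeric matrix with dimnames.
#' @export
additive_relationship <- function(ped, animals = NULL) {
  ord <- pedigree_order(ped)
  n <- length(ord)
  idx <- stats::setNames(seq_len(n), ord)
  prow <- match(ord, ped$animal_id)
  s <- ifelse(is.na(ped$sire_id[prow]), 0L, idx[ped$sire_id[prow]])
  d <- ifelse(is.na(ped$dam_id[prow]), 0L, idx[ped$dam_id[prow]])
  A <- matrix(0, n, n, dimnames = list(ord, ord))
  for (i in seq_len(n)) {
    as_row <- if (s[i] > 0L) A[s[i], seq_len(i - 1L)] else numeric(i - 1L)
    ad_row <- if (d[i] > 0L) A[d[i], seq_len(i - 1L)] else numeric(i - 1L)
    if (i > 1L) {
      v <- 0.5 * (as_row + ad_row)
      A[i, seq_len(i - 1L)] <- v
      A[seq_len(i - 1L), i] <- v
    }
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  if (!is.null(animals)) {
    missing <- setdiff(animals, ord)
    if (length(missing)) {
      stop("animals absent from pedigree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    A <- A[animals, animals, drop = FALSE]
  }
  A
}

#' Mean pedigree relationship between training and validation animals
#'
#' Averages the numerator relationship over all (training, validation)
#' pairs, each counted once.
#'
#' @param ped A `pedigree`.
#' @param training,validation Disjoint character vectors of animal ids.
#' @return A tibble with `mean_r_tv` and `n_pairs`.
#' @export
mean_cross_relationship <- function(ped, training, validation) {
  if (!length(training) || !length(validation)) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  if (length(intersect(training, validation))) {
    stop("training and validation sets overlap", call. = FALSE)
  }
  A <- additive_relationship(ped)
  block <- A[training, validation, drop = FALSE]
  tibble::tibble(mean_r_tv = mean(block),
                 n_pairs = length(training) * length(validation))
}

# expected contribution of every animal's genome that originates from the
# selected set (upward recursion; selected animals count as fully explained)
explained_fraction <- function(ord, s, d, selected_idx) {
  n <- length(ord)
  expl <- numeric(n)
  sel <- rep(FALSE, n)
  sel[selected_idx] <- TRUE
  for (i in seq_len(n)) {
    if (sel[i]) {
      expl[i] <- 1
    } else {
      es <- if (s[i] > 0L) expl[s[i]] else 0
      ed <- if (d[i] > 0L) expl[d[i]] else 0
      expl[i] <- 0.5 * (es + ed)
    }
  }
  expl
}

# expected contribution of one candidate to each animal, with transmission
# blocked at previously selected ancestors
blocked_contribution <- function(cand, ord_n, s, d, selected_idx) {
  v <- numeric(ord_n)
  v[cand] <- 1
  blocked <- rep(FALSE, ord_n)
  blocked[selected_idx] <- TRUE
  for (i in seq_len(ord_n)) {
    if (i == cand || blocked[i]) next
    vs <- if (s[i] > 0L) v[s[i]] else 0
    vd <- if (d[i] > 0L) v[d[i]] else 0
    v[i] <- 0.5 * (vs + vd)
  }
  v
}

#' Effective number of ancestors by probabilities of gene origin
#'
#' Greedy selection of the ancestors with the largest marginal expected
#' genetic contribution to a reference set. In each round the marginal
#' contribution of a candidate is its expected contribution to the reference
#' computed with transmission blocked at previously selected ancestors,
#' discounted by the fraction of the candidate's own genome already explained
#' by the selected set. The effective number of ancestors is
#' `1 / sum(marginal contributions squared)`.
#'
#' @param ped A `pedigree`.
#' @param reference Character vector of reference animal ids.
#' @param max_ancestors Maximum ancestors to select (default: until marginal
#'   contributions fall below `tol`).
#' @param tol Stop once the best marginal contribution is below this value.
#' @return A list of class `effective_ancestors` with `n_effective_ancestors`
#'   and a tibble `contributions` (id, marginal contribution, in selection
#'   order).
#' @export
effective_ancestors <- function(ped, reference, max_ancestors = NULL,
                                tol = 1e-4) {
  if (!length(reference)) stop("empty reference set", call. = FALSE)
  ord <- pedigree_order(ped)
  missing <- setdiff(reference, ord)
  if (length(missing)) {
    stop("reference animals absent from pedigree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- length(ord)
  idx <- stats::setNames(seq_len(n), ord)
  prow <- match(ord, ped$animal_id)
  s <- ifelse(is.na(ped$sire_id[prow]), 0L, idx[ped$sire_id[prow]])
  d <- ifelse(is.na(ped$dam_id[prow]), 0L, idx[ped$dam_id[prow]])
  ref_idx <- idx[reference]
  if (is.null(max_ancestors)) max_ancestors <- n
  selected <- integer(0)
  q <- numeric(0)
  repeat {
    if (length(selected) >= max_ancestors) break
    expl <- explained_fraction(ord, s, d, selected)
    best_id <- 0L
    best_q <- 0
    for (cand in seq_len(n)) {
      if (cand %in% selected) next
      if (expl[cand] >= 1 - 1e-12) next
      v <- blocked_contribution(cand, n, s, d, selected)
      qc <- (1 - expl[cand]) * mean(v[ref_idx])
      if (qc > best_q + 1e-12) {
        best_q <- qc
        best_id <- cand
      }
    }
    if (best_id == 0L || best_q < tol) break
    selected <- c(selected, best_id)
    q <- c(q, best_q)
  }
  out <- list(
    n_effective_ancestors = 1 / sum(q^2),
    contributions = tibble::tibble(id = ord[selected], marginal = q)
  )
  class(out) <- "effective_ancestors"
  out
}

#' @export
print.effective_ancestors <- function(x, ...) {
  cat(sprintf("<effective_ancestors> n = %.2f from %d selected ancestor(s)\n",
              x$n_effective_ancestors, nrow(x$contributions)))
  invisible(x)
}
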