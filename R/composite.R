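# Integration of the two probabilistic distances into the single composite
# distance used for clustering. When the composition signal is already
# informative (TDP above the switch) the larger of the two distances wins;
# otherwise the abundance distance is mixed in with the sample-count weight.

#' Composite pairwise distance
#'
#' `tdp` if `adp` is undefined; `max(tdp, adp)` when `tdp > tdp_switch`;
#' otherwise `adp * w + tdp * (1 - w)`. The rule is intentionally
#' discontinuous at the switch. Vectorized with recycling.
#'
#' @param tdp Tetranucleotide distance probability in \[0,1\].
#' @param adp Abundance distance probability in \[0,1\], or `NA` when no
#'   sample was informative for the pair.
#' @param w ADP weight in \[0,1\] (see [abundance_weight()]).
#' @param tdp_switch Branch threshold (default 0.05).
#' @return Composite distance in \[0,1\].
#' @export
composite_distance <- function(tdp, adp, w, tdp_switch = 0.05) {
  n <- max(length(tdp), length(adp), length(w))
  tdp <- rep_len(tdp, n); adp <- rep_len(adp, n); w <- rep_len(w, n)
  if (any(!is.na(w) & (w < 0 | w > 1))) stop_input("weight w must lie in [0, 1]")
  out <- ifelse(tdp > tdp_switch, pmax(tdp, adp), adp * w + tdp * (1 - w))
  undef <- is.na(adp)
  out[undef] <- tdp[undef]
  out
}

#' Dense composite distance matrix over all contig pairs
#'
#' For every unordered contig pair, computes the Euclidean TNF distance, the
#' size-aware TDP, the geometric-mean ADP over informative samples with its
#' per-pair weight, and the composite distance. Computed in row blocks to
#' bound memory; the result is exactly symmetric with a zero diagonal.
#'
#' @param contigs A `contig_set` (already filtered to the minimum binning
#'   size).
#' @param tnf TNF matrix for `contigs` (rows in the same order), as the
#'   `values` element of [tnf_vectors()]; computed here when `NULL`.
#' @param model A `tdp_model`.
#' @param profiles Optional `coverage_profiles`; when `NULL` the matrix is
#'   pure TDP (composition-only mode).
#' @param cfg An [abundance_config()].
#' @param tdp_switch Branch threshold of [composite_distance()].
#' @return `n x n` numeric matrix with contig ids as dimnames. Each
#'   unordered pair is computed once (in compiled code), so the matrix is
#'   exactly symmetric; entries reproduce the R-level per-pair path
#'   `composite_distance(tdp(...), adp_combined(...)$adp, w)`.
#' @export
build_distance_matrix <- function(contigs, tnf = NULL, model, profiles = NULL,
                                  cfg = abundance_config(), tdp_switch = 0.05) {
  ids <- contigs$id
  n <- length(ids)
  if (is.null(tnf)) tnf <- tnf_vectors(contigs)$values
  if (nrow(tnf) != n) stop_input("TNF matrix rows do not match contigs")
  if (!is.null(profiles)) {
    if (!identical(profiles$ids, ids)) {
      idx <- match(ids, profiles$ids)
      if (anyNA(idx)) {
        stop_input("coverage profiles missing contig '%s'", ids[is.na(idx)][1L])
      }
      profiles$ids <- profiles$ids[idx]
      profiles$means <- profiles$means[idx, , drop = FALSE]
      profiles$variances <- profiles$variances[idx, , drop = FALSE]
    }
  }
  W <- size_grid_weights(model, contigs$length)
  WB <- W %*% model$b_surface   # pair b = WB[lo, ] . W[hi, ] (lo = shorter)
  WC <- W %*% model$c_surface
  have_cov <- !is.null(profiles)
  empty <- matrix(0, n, 0L)
  D <- composite_kernel(tnf, WB, WC, W, as.numeric(contigs$length),
                        if (have_cov) profiles$means else empty,
                        if (have_cov) profiles$variances else empty,
                        have_cov, cfg$min_cv, cfg$variance_floor,
                        log(cfg$weight_m + 1), cfg$weight_alpha, tdp_switch)
  dimnames(D) <- list(ids, ids)
  D
}

#' Export a distance matrix as a three-column TSV
#'
#' @param D Matrix from [build_distance_matrix()].
#' @param path Output path.
#' @param threshold Only pairs with distance `<= threshold` are written
#'   (default 1, i.e. all pairs).
#' @export
export_distances <- function(D, path, threshold = 1) {
  ut <- which(upper.tri(D), arr.ind = TRUE)
  keep <- D[ut] <= threshold
  df <- data.frame(id_i = rownames(D)[ut[keep, 1L]],
                   id_j = colnames(D)[ut[keep, 2L]],
                   distance = D[ut][keep])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
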