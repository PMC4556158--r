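# Abundance distance probability (ADP): per sample, the distance between two
# contigs' coverage is the non-shared area (total-variation distance) of the
# normal distributions implied by their observed depth mean and variance;
# per-sample distances combine by geometric mean over informative samples.

#' Abundance distance configuration
#'
#' @param min_cv Minimum informative mean depth `c`: a sample contributes to
#'   a pair's ADP only when at least one of the two contigs exceeds it
#'   (default 1.0 read per base).
#' @param variance_floor Substitute for zero reported depth variance
#'   (default 1e-4); zero variance breaks the density crossing points.
#' @param weight_m The "large number" `m` in the ADP weight
#'   `w = min(log(n+1)/log(m+1), alpha)` (default 100).
#' @param weight_alpha Maximum ADP weight `alpha` (default 0.9).
#' @return List of class `abundance_config`.
#' @export
abundance_config <- function(min_cv = 1.0, variance_floor = 1e-4,
                             weight_m = 100L, weight_alpha = 0.9) {
  stopifnot(min_cv >= 0, variance_floor > 0, weight_m >= 1,
            weight_alpha > 0, weight_alpha <= 1)
  structure(list(min_cv = min_cv, variance_floor = variance_floor,
                 weight_m = as.integer(weight_m), weight_alpha = weight_alpha),
            class = "abundance_config")
}

#' Non-shared area of two normal coverage distributions
#'
#' Computes `(1/2) * integral |phi(mu1, var1) - phi(mu2, var2)|` in closed
#' form: for equal variances it is `2 Phi(|mu1 - mu2| / (2 sigma)) - 1`
#' evaluated via the midpoint `k0 = (mu1 + mu2)/2`; otherwise the four-term
#' CDF expression at the two density crossing points (with the larger
#' variance assigned to the second distribution). Vectorized with recycling.
#'
#' @param mu1,var1,mu2,var2 Depth means and variances (finite; variances are
#'   floored at `variance_floor`).
#' @param variance_floor Lower bound applied to both variances.
#' @return Probability in \[0,1\]; 0 iff the two (mean, variance) pairs
#'   coincide.
#' @export
adp_single <- function(mu1, var1, mu2, var2, variance_floor = 1e-4) {
  n <- max(length(mu1), length(var1), length(mu2), length(var2))
  mu1 <- rep_len(as.numeric(mu1), n); var1 <- rep_len(as.numeric(var1), n)
  mu2 <- rep_len(as.numeric(mu2), n); var2 <- rep_len(as.numeric(var2), n)
  if (!all(is.finite(c(mu1, var1, mu2, var2)))) {
    stop_input("adp_single requires finite means and variances")
  }
  v1 <- pmax(var1, variance_floor)
  v2 <- pmax(var2, variance_floor)
  # enforce var2 >= var1 (the pair is symmetric, so swap freely)
  swap <- v1 > v2
  if (any(swap)) {
    tmp <- mu1[swap]; mu1[swap] <- mu2[swap]; mu2[swap] <- tmp
    tmp <- v1[swap];  v1[swap] <- v2[swap];  v2[swap] <- tmp
  }
  out <- numeric(n)
  eq <- (v2 - v1) <= 1e-12 * v2
  if (any(eq)) {
    s <- sqrt(v1[eq])
    k0 <- (mu1[eq] + mu2[eq]) / 2
    out[eq] <- abs(pnorm(k0, mu1[eq], s) - pnorm(k0, mu2[eq], s))
  }
  ne <- !eq
  if (any(ne)) {
    m1 <- mu1[ne]; m2 <- mu2[ne]; w1 <- v1[ne]; w2 <- v2[ne]
    disc <- w1 * w2 * ((m1 - m2)^2 + 2 * (w2 - w1) * log(sqrt(w2 / w1)))
    s <- sqrt(pmax(disc, 0))
    # density crossing points: roots of the quadratic phi1(x) = phi2(x)
    denom <- w2 - w1
    k1s <- ((m1 * w2 - m2 * w1) - s) / denom
    k2s <- ((m1 * w2 - m2 * w1) + s) / denom
    k1 <- pmin(k1s, k2s)
    k2 <- pmax(k1s, k2s)
    sd1 <- sqrt(w1); sd2 <- sqrt(w2)
    out[ne] <- abs(pnorm(k2, m1, sd1) - pnorm(k1, m1, sd1) +
                     pnorm(k1, m2, sd2) - pnorm(k2, m2, sd2))
  }
  pmin(pmax(out, 0), 1)
}

#' Combine per-sample abundance distances for one contig pair
#'
#' A sample is informative when at least one of the two contigs has mean
#' depth above `cfg$min_cv`; the pair's ADP is the geometric mean of
#' [adp_single()] over informative samples only.
#'
#' @param p1,p2 Coverage profiles: lists with numeric `means` and
#'   `variances` of equal length (one entry per sample).
#' @param cfg An [abundance_config()].
#' @return List with `adp` (`NA` when no sample is informative) and
#'   `n_informative`.
#' @export
adp_combined <- function(p1, p2, cfg = abundance_config()) {
  if (length(p1$means) != length(p2$means) ||
      length(p1$means) != length(p1$variances) ||
      length(p2$means) != length(p2$variances)) {
    stop_input("coverage profiles must cover identical sample sets")
  }
  inf <- p1$means > cfg$min_cv | p2$means > cfg$min_cv
  n_inf <- sum(inf)
  if (n_inf == 0L) return(list(adp = NA_real_, n_informative = 0L))
  p <- adp_single(p1$means[inf], p1$variances[inf],
                  p2$means[inf], p2$variances[inf],
                  variance_floor = cfg$variance_floor)
  gm <- exp(mean(log(pmax(p, 0))))  # log(0) -> -Inf -> geometric mean 0
  list(adp = gm, n_informative = as.integer(n_inf))
}

#' Progressive weight of the abundance distance
#'
#' `w = min(log(n+1)/log(m+1), alpha)`: the more (informative) samples a
#' pair has, the more weight its abundance distance carries, capped at
#' `alpha`. With the defaults `m = 100`, `alpha = 0.9`, ten samples give a
#' weight of about 0.5.
#'
#' @param n_samples Number of informative samples for the pair (>= 0).
#' @param cfg An [abundance_config()].
#' @return Weight in \[0, `alpha`\].
#' @export
abundance_weight <- function(n_samples, cfg = abundance_config()) {
  stopifnot(all(n_samples >= 0))
  pmin(log(n_samples + 1) / log(cfg$weight_m + 1), cfg$weight_alpha)
}

coverage_profiles <- function(ids, lengths, means, variances,
                              sample_names = NULL) {
  means <- as.matrix(means); variances <- as.matrix(variances)
  stopifnot(nrow(means) == length(ids), all(dim(means) == dim(variances)))
  if (is.null(sample_names)) sample_names <- sprintf("sample%d", seq_len(ncol(means)))
  dimnames(means) <- dimnames(variances) <- list(ids, sample_names)
  structure(list(ids = ids, lengths = as.integer(lengths),
                 means = means, variances = variances),
            class = "coverage_profiles")
}

#' @export
print.coverage_profiles <- function(x, ...) {
  cat(sprintf("coverage_profiles: %d contigs x %d samples\n",
              length(x$ids), ncol(x$means)))
  invisible(x)
}

# One contig's profile as the list shape adp_combined() expects.
profile_of <- function(profiles, id) {
  i <- match(id, profiles$ids)
  if (is.na(i)) stop_input("contig '%s' absent from coverage profiles", id)
  list(means = profiles$means[i, ], variances = profiles$variances[i, ])
}

#' Read a per-contig depth table
#'
#' Expects the de-facto depth summarizer layout: a header row
#' `contigName contigLen totalAvgDepth` followed by paired per-sample
#' columns (mean depth, depth variance).
#'
#' @param path Tab-separated depth table with header.
#' @return Object of class `coverage_profiles` (ids, lengths, and
#'   `n x n_samples` matrices `means` and `variances`). The `totalAvgDepth`
#'   column is parsed but not used in distance computations.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stop_input("depth table not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 5L) {
    stop_format("depth table %s needs >= 5 columns (contigName, contigLen, totalAvgDepth, then mean/variance pairs)", path)
  }
  if ((ncol(df) - 3L) %% 2L != 0L) {
    stop_format("depth table %s has an odd number (%d) of per-sample columns",
                path, ncol(df) - 3L)
  }
  num <- df[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]))
    if (length(bad) || anyNA(num[[j]])) {
      row <- if (length(bad)) bad[1L] else which(is.na(num[[j]]))[1L]
      stop_format("non-numeric cell in %s at row %d, column %d", path, row, j + 1L)
    }
    num[[j]] <- v
  }
  n_samples <- (ncol(df) - 3L) %/% 2L
  mean_cols <- 3L + 2L * seq_len(n_samples) - 1L  # columns 4, 6, ... of num-frame offset
  means <- as.matrix(num[, 2L + 2L * seq_len(n_samples) - 1L, drop = FALSE])
  variances <- as.matrix(num[, 2L + 2L * seq_len(n_samples), drop = FALSE])
  sample_names <- sub("-var$", "", colnames(variances))
  prof <- coverage_profiles(df[[1L]], num[[1L]], means, variances,
                            sample_names = colnames(means))
  prof$total_avg_depth <- num[[2L]]
  prof
}

#' Write a depth table in the layout read by [read_depth_table()]
#' @param profiles A `coverage_profiles` object.
#' @param path Output TSV path.
#' @export
write_depth_table <- function(profiles, path) {
  S <- ncol(profiles$means)
  out <- data.frame(contigName = profiles$ids,
                    contigLen = profiles$lengths,
                    totalAvgDepth = rowMeans(profiles$means),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (s in seq_len(S)) {
    nm <- colnames(profiles$means)[s]
    out[[nm]] <- profiles$means[, s]
    out[[paste0(nm, "-var")]] <- profiles$variances[, s]
  }
  write.table(format(out, trim = TRUE, scientific = FALSE, digits = 15),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-contig depth means and variances from sorted BAM files
#'
#' Depth is computed over every contig position (zero-depth positions
#' included) from primary, non-duplicate, non-supplementary alignments; the
#' variance is the population variance of the per-base depth.
#'
#' @param bam_paths One sorted, indexed BAM per sample.
#' @param contigs A `contig_set` (the assembly the reads were aligned to).
#' @param min_mapq Minimum mapping quality (default 0, i.e. no filter).
#' @return Object of class `coverage_profiles`.
#' @export
depths_from_bam <- function(bam_paths, contigs, min_mapq = 0L) {
  n <- nrow(contigs)
  S <- length(bam_paths)
  means <- matrix(0, n, S)
  vars <- matrix(0, n, S)
  for (s in seq_len(S)) {
    bp <- bam_paths[s]
    if (!file.exists(bp)) stop_input("BAM file not found: %s", bp)
    if (!file.exists(paste0(bp, ".bai")) && !file.exists(sub("\\.bam$", ".bai", bp))) {
      stop_input("BAM file %s is not indexed (.bai missing)", bp)
    }
    bf <- Rsamtools::BamFile(bp)
    hdr <- Rsamtools::scanBamHeader(bf)
    missing_ids <- setdiff(contigs$id, names(hdr$targets))
    if (length(missing_ids)) {
      stop_input("assembly/alignment mismatch: contig '%s' absent from BAM header of %s",
                 missing_ids[1L], bp)
    }
    pp <- Rsamtools::PileupParam(max_depth = 250000L, min_base_quality = 0L,
                                 min_mapq = as.integer(min_mapq),
                                 min_nucleotide_depth = 1L,
                                 distinguish_strands = FALSE,
                                 distinguish_nucleotides = FALSE)
    sp <- Rsamtools::ScanBamParam(flag = Rsamtools::scanBamFlag(
      isSecondaryAlignment = FALSE, isDuplicate = FALSE,
      isSupplementaryAlignment = FALSE))
    pu <- Rsamtools::pileup(bf, scanBamParam = sp, pileupParam = pp)
    if (nrow(pu)) {
      idx <- match(as.character(pu$seqnames), contigs$id)
      keep <- !is.na(idx)
      depth_sum <- rowsum(as.numeric(pu$count[keep]), idx[keep])
      depth_sq <- rowsum(as.numeric(pu$count[keep])^2, idx[keep])
      which_c <- as.integer(rownames(depth_sum))
      L <- as.numeric(contigs$length[which_c])
      mu <- depth_sum[, 1L] / L
      means[which_c, s] <- mu
      vars[which_c, s] <- pmax(depth_sq[, 1L] / L - mu^2, 0)
    }
  }
  coverage_profiles(contigs$id, contigs$length, means, vars,
                    sample_names = sub("\\.bam$", "", basename(bam_paths)))
}
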