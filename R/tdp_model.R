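# Empirical calibration of the tetranucleotide distance probability (TDP):
# shred genomes into fragments, sample intra-/inter-genome fragment pairs,
# estimate the posterior P(different genome | TNF distance) with an
# informative prior, and fit a two-parameter logistic per fragment-size pair
# so the score adapts to contig sizes.

#' Shred genomes into non-overlapping fragments
#'
#' Tiles each genome left to right with fragment lengths drawn uniformly on
#' `[min_size, max_size]`; a trailing remainder shorter than `min_size` is
#' discarded (a remainder of at least `min_size` is emitted as the final,
#' shorter fragment). Genomes shorter than `min_size` are skipped.
#'
#' @param genomes Named character vector (or list) of genome sequences; names
#'   are the genome labels.
#' @param min_size,max_size Fragment length bounds in bases.
#' @param seed Integer RNG seed; output is deterministic given the seed.
#' @return `data.frame` with columns `label`, `seq`, `length`; attribute
#'   `n_skipped` counts genomes shorter than `min_size`.
#' @export
shred_genomes <- function(genomes, min_size, max_size, seed = 1L) {
  genomes <- unlist(genomes)
  stopifnot(min_size >= 1, min_size <= max_size)
  if (is.null(names(genomes)) || any(names(genomes) == "")) {
    stop_input("genomes must be named (label -> sequence)")
  }
  with_seed(seed, {
    out <- vector("list", length(genomes))
    n_skipped <- 0L
    for (g in seq_along(genomes)) {
      glen <- nchar(genomes[[g]])
      if (glen < min_size) {
        n_skipped <- n_skipped + 1L
        warning(sprintf("genome '%s' (%d bp) shorter than min_size; skipped",
                        names(genomes)[g], glen))
        next
      }
      pos <- 1L
      starts <- integer(0)
      lens <- integer(0)
      while (glen - pos + 1L >= min_size) {
        L <- if (min_size == max_size) min_size else
          as.integer(floor(runif(1, min_size, max_size + 1)))
        L <- min(L, glen - pos + 1L)
        starts <- c(starts, pos)
        lens <- c(lens, L)
        pos <- pos + L
      }
      out[[g]] <- data.frame(
        label = names(genomes)[g],
        seq = substring(genomes[[g]], starts, starts + lens - 1L),
        length = lens, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(res)) res <- data.frame(label = character(), seq = character(),
                                        length = integer())
    rownames(res) <- NULL
    attr(res, "n_skipped") <- n_skipped
    res
  })
}

#' Sample labelled fragment pairs and their TNF distances
#'
#' Draws `n_pairs` pairs uniformly at random (with replacement) over distinct
#' fragment pairs and records, for each pair, the Euclidean TNF distance, the
#' two fragment sizes, and whether the fragments come from different genomes.
#'
#' @param fragments Output of [shred_genomes()].
#' @param n_pairs Number of pairs to draw.
#' @param seed Integer RNG seed.
#' @return List of class `pair_distance_sample` with elements `distances`,
#'   `size1`, `size2`, `inter_flag`.
#' @export
sample_pairs <- function(fragments, n_pairs, seed = 1L) {
  n <- nrow(fragments)
  if (n < 2L) stop_input("need at least 2 fragments to sample pairs")
  tnf <- tnf_vectors(fragments$seq)$values
  with_seed(seed, {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n - 1L, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)   # uniform over distinct ordered pairs
    pair_sample(tnf, fragments, i, j)
  })
}

pair_sample <- function(tnf, fragments, i, j, tnf2 = NULL, fragments2 = NULL) {
  if (is.null(tnf2)) {
    tnf2 <- tnf
    fragments2 <- fragments
  }
  d <- sqrt(rowSums((tnf[i, , drop = FALSE] - tnf2[j, , drop = FALSE])^2))
  out <- list(distances = d,
              size1 = fragments$length[i],
              size2 = fragments2$length[j],
              inter_flag = fragments$label[i] != fragments2$label[j])
  class(out) <- "pair_distance_sample"
  out
}

#' Empirical posterior that two fragments are from different genomes
#'
#' Estimates the class-conditional densities of the TNF distance with
#' equal-width histograms on a shared grid and applies Bayes' rule with prior
#' odds `prior_ratio` = P(different)/P(same). Bins with no observations are
#' dropped.
#'
#' @param sample A `pair_distance_sample` containing both intra and inter
#'   pairs.
#' @param prior_ratio Prior odds of the inter-genome event (default 10).
#' @param n_bins Number of equal-width distance bins (default 100).
#' @return `data.frame` with columns `d` (bin center), `posterior` in
#'   \[0,1\], and `n` (pair count per bin, usable as a fit weight).
#' @export
empirical_posterior <- function(sample, prior_ratio = 10, n_bins = 100L) {
  stopifnot(prior_ratio > 0, n_bins >= 2L)
  inter <- sample$inter_flag
  if (!any(inter) || all(inter)) {
    stop_input("need both intra and inter pairs to estimate the posterior")
  }
  d <- sample$distances
  rng <- range(d)
  if (rng[1] == rng[2]) rng <- rng + c(-1e-9, 1e-9)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  cT <- tabulate(bin[inter], nbins = n_bins)
  cR <- tabulate(bin[!inter], nbins = n_bins)
  # equal-width bins: histogram densities are proportional to class fractions
  fT <- cT / sum(cT)
  fR <- cR / sum(cR)
  keep <- (cT + cR) > 0L
  post <- prior_ratio * fT[keep] / (prior_ratio * fT[keep] + fR[keep])
  centers <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  data.frame(d = centers[keep], posterior = post, n = (cT + cR)[keep])
}

#' Fit a two-parameter logistic to a posterior curve
#'
#' Weighted maximum-likelihood fit of `p(d) = 1/(1 + exp(-(b + c d)))` to
#' per-bin posterior values, using damped Newton iterations (cap 100,
#' tolerance 1e-10). The slope must come out positive: the probability that
#' two contigs are from different genomes increases with TNF distance.
#'
#' @param curve `data.frame` with columns `d` and `posterior` (and optionally
#'   `n`), as returned by [empirical_posterior()].
#' @param weights Per-bin weights; defaults to `curve$n` or 1.
#' @param max_iter,tol Newton iteration cap and convergence tolerance.
#' @return Named numeric vector `c(b = ..., c = ...)`.
#' @export
fit_logistic <- function(curve, weights = NULL, max_iter = 100L, tol = 1e-10) {
  d <- curve$d
  p <- curve$posterior
  if (is.null(weights)) weights <- if (!is.null(curve$n)) curve$n else rep(1, length(d))
  if (length(unique(d)) < 3L) stop_input("need >= 3 distinct distance bins")
  if (max(p) - min(p) < 1e-12) stop_input("posterior curve is constant; cannot fit")
  w <- weights / mean(weights)
  # start from a weighted linear fit on the logit scale
  z <- qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))
  X <- cbind(1, d)
  wl <- w
  beta <- tryCatch(solve(crossprod(X, wl * X), crossprod(X, wl * z)),
                   error = function(e) matrix(c(0, 1), 2))
  beta <- as.numeric(beta)
  ll <- function(b) {
    q <- plogis(X %*% b)
    q <- pmin(pmax(q, 1e-15), 1 - 1e-15)
    sum(w * (p * log(q) + (1 - p) * log(1 - q)))
  }
  ll_old <- ll(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    q <- as.numeric(plogis(X %*% beta))
    grad <- crossprod(X, w * (p - q))
    H <- crossprod(X, (w * q * (1 - q)) * X)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    step <- as.numeric(step)
    damp <- 1
    repeat {
      cand <- beta + damp * step
      ll_new <- ll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-14) break
      damp <- damp / 2
      if (damp < 1e-8) { cand <- beta; ll_new <- ll_old; break }
    }
    moved <- max(abs(cand - beta))
    beta <- cand
    ll_old <- ll_new
    if (moved < tol) { converged <- TRUE; break }
  }
  if (!converged && max_iter > 1L) {
    # final gradient check: flat gradient counts as converged
    q <- as.numeric(plogis(X %*% beta))
    if (max(abs(crossprod(X, w * (p - q)))) > 1e-6) {
      stop_input("logistic fit did not converge (last ll %.6g)", ll_old)
    }
  }
  if (beta[2] <= 0) {
    stop_input("logistic fit produced non-positive slope c = %.4g", beta[2])
  }
  c(b = beta[1], c = beta[2])
}

#' Build the size-aware TDP model
#'
#' For every pair of fragment sizes on `size_grid`, shreds the training
#' genomes at those fixed sizes, samples fragment pairs (one fragment per
#' size), estimates the empirical inter-genome posterior, and fits the
#' logistic parameters `b` and `c`. Scores for arbitrary contig sizes are
#' later obtained by bilinear interpolation of the parameter surfaces in
#' log-size coordinates.
#'
#' @param genomes Named character vector of training genome sequences (at
#'   least 2).
#' @param size_grid Ascending fragment sizes in bases, within
#'   \[2500, 500000\].
#' @param pairs_per_cell Fragment pairs sampled per size pair (default
#'   10000).
#' @param prior_ratio Prior odds P(different)/P(same) (default 10).
#' @param seed Integer RNG seed.
#' @param n_bins Histogram bins for the posterior (default 100).
#' @param min_size_clamp,max_size_clamp Contig lengths are clamped into this
#'   range before interpolation (defaults 2500 and 500000).
#' @return Object of class `tdp_model`.
#' @export
build_tdp_model <- function(genomes, size_grid = c(2500, 5000, 10000, 20000, 40000),
                            pairs_per_cell = 10000L, prior_ratio = 10,
                            seed = 1L, n_bins = 100L,
                            min_size_clamp = 2500L, max_size_clamp = 500000L) {
  genomes <- unlist(genomes)
  if (length(genomes) < 2L) stop_input("need >= 2 training genomes")
  size_grid <- sort(unique(as.integer(size_grid)))
  if (min(size_grid) < 2500 || max(size_grid) > 500000) {
    stop_input("size_grid must lie within [2500, 500000]")
  }
  G <- length(size_grid)
  # fragments and TNF matrices per size (fixed-size tiling), cached
  frag <- vector("list", G)
  tnfm <- vector("list", G)
  for (k in seq_len(G)) {
    frag[[k]] <- shred_genomes(genomes, size_grid[k], size_grid[k],
                               seed = seed + k)
    tnfm[[k]] <- tnf_vectors(frag[[k]]$seq)$values
  }
  B <- matrix(NA_real_, G, G)
  C <- matrix(NA_real_, G, G)
  failures <- character(0)
  cell_seed <- seed
  for (i in seq_len(G)) {
    for (j in i:G) {
      cell_seed <- cell_seed + 1L
      smp <- with_seed(cell_seed, {
        ni <- nrow(frag[[i]])
        nj <- nrow(frag[[j]])
        if (i == j) {
          a <- sample.int(ni, pairs_per_cell, replace = TRUE)
          b <- sample.int(ni - 1L, pairs_per_cell, replace = TRUE)
          b <- ifelse(b >= a, b + 1L, b)
          pair_sample(tnfm[[i]], frag[[i]], a, b)
        } else {
          a <- sample.int(ni, pairs_per_cell, replace = TRUE)
          b <- sample.int(nj, pairs_per_cell, replace = TRUE)
          pair_sample(tnfm[[i]], frag[[i]], a, b, tnfm[[j]], frag[[j]])
        }
      })
      fit <- tryCatch({
        curve <- empirical_posterior(smp, prior_ratio = prior_ratio,
                                     n_bins = n_bins)
        fit_logistic(curve)
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        failures <- c(failures, sprintf("(%d, %d): %s", size_grid[i],
                                        size_grid[j], conditionMessage(fit)))
      } else {
        B[i, j] <- B[j, i] <- fit[["b"]]
        C[i, j] <- C[j, i] <- fit[["c"]]
      }
    }
  }
  if (length(failures)) {
    stop_input("TDP fit failed for size cells: %s",
               paste(failures, collapse = "; "))
  }
  structure(list(size_grid = size_grid, b_surface = B, c_surface = C,
                 prior_ratio = prior_ratio,
                 min_size_clamp = as.integer(min_size_clamp),
                 max_size_clamp = as.integer(max_size_clamp),
                 meta = list(n_genomes = length(genomes),
                             pairs_per_cell = as.integer(pairs_per_cell),
                             n_bins = as.integer(n_bins),
                             seed = as.integer(seed))),
            class = "tdp_model")
}

#' @export
print.tdp_model <- function(x, ...) {
  cat(sprintf(
    "tdp_model: %d-point size grid [%d..%d], prior odds %.3g, %d training genomes\n",
    length(x$size_grid), min(x$size_grid), max(x$size_grid),
    x$prior_ratio, x$meta$n_genomes))
  invisible(x)
}

# Per-contig interpolation weights over the model size grid (log coords).
# Returns a length(sizes) x G matrix W with at most two non-zeros per row,
# so the interpolated parameter for a pair is W_i %*% B %*% t(W_j).
size_grid_weights <- function(model, sizes) {
  g <- log(model$size_grid)
  s <- pmin(pmax(sizes, model$min_size_clamp), model$max_size_clamp)
  s <- log(pmin(pmax(s, model$size_grid[1]), model$size_grid[length(g)]))
  G <- length(g)
  k <- findInterval(s, g, all.inside = TRUE)
  t <- (s - g[k]) / (g[k + 1L] - g[k])
  W <- matrix(0, length(s), G)
  W[cbind(seq_along(s), k)] <- 1 - t
  W[cbind(seq_along(s), k + 1L)] <- W[cbind(seq_along(s), k + 1L)] + t
  W
}

#' Size-aware tetranucleotide distance probability
#'
#' Evaluates `1/(1 + exp(-(b + c d)))` where `b` and `c` are bilinearly
#' interpolated over the model's fragment-size grid in log-size coordinates;
#' contig lengths are clamped into the model's stability range first.
#'
#' @param model A [build_tdp_model()] result.
#' @param d Euclidean TNF distance(s), non-negative.
#' @param len1,len2 Contig lengths in bases (recycled against `d`).
#' @return Probability (vector) in \[0,1\] that the two contigs come from
#'   different genomes.
#' @export
tdp <- function(model, d, len1, len2) {
  if (!inherits(model, "tdp_model")) stop_state("model is not a built tdp_model")
  if (any(d < 0)) stop_input("TNF distance must be >= 0")
  n <- max(length(d), length(len1), length(len2))
  d <- rep_len(d, n)
  len1 <- rep_len(len1, n)
  len2 <- rep_len(len2, n)
  # order the pair so the score is exactly symmetric in the two lengths
  lo <- pmin(len1, len2)
  hi <- pmax(len1, len2)
  W1 <- size_grid_weights(model, lo)
  W2 <- size_grid_weights(model, hi)
  b <- rowSums((W1 %*% model$b_surface) * W2)
  cc <- rowSums((W1 %*% model$c_surface) * W2)
  plogis(b + cc * d)
}

#' Serialize a TDP model to a versioned JSON file
#' @param model A `tdp_model`.
#' @param path Output file path.
#' @export
write_tdp_model <- function(model, path) {
  payload <- list(format = "tetrabin_tdp_model", version = 1L,
                  size_grid = model$size_grid,
                  b_surface = model$b_surface, c_surface = model$c_surface,
                  prior_ratio = model$prior_ratio,
                  min_size_clamp = model$min_size_clamp,
                  max_size_clamp = model$max_size_clamp,
                  meta = model$meta)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a TDP model written by [write_tdp_model()]
#' @param path Model file path.
#' @return A `tdp_model`.
#' @export
read_tdp_model <- function(path) {
  if (!file.exists(path)) stop_input("model file not found: %s", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "tetrabin_tdp_model")) {
    stop_format("%s is not a tetrabin TDP model file", path)
  }
  structure(list(size_grid = as.integer(p$size_grid),
                 b_surface = matrix(unlist(p$b_surface), length(p$size_grid),
                                    byrow = FALSE),
                 c_surface = matrix(unlist(p$c_surface), length(p$size_grid),
                                    byrow = FALSE),
                 prior_ratio = p$prior_ratio,
                 min_size_clamp = as.integer(p$min_size_clamp),
                 max_size_clamp = as.integer(p$max_size_clamp),
                 meta = p$meta),
            class = "tdp_model")
}

#' Train the package's default TDP model on synthetic genomes
#'
#' Stand-in for calibration against a reference genome collection: generates
#' Markov-chain genomes with distinct compositional biases and runs the full
#' calibration pipeline on them. User-supplied real genomes can be used
#' instead via [build_tdp_model()].
#'
#' @param seed Integer RNG seed.
#' @param n_genomes,genome_length Training corpus dimensions.
#' @param transition_sharpness Compositional distinctiveness of the
#'   synthetic genomes (see [generate_genome()]).
#' @param ... Passed to [build_tdp_model()].
#' @return A `tdp_model`.
#' @export
train_default_model <- function(seed = 7L, n_genomes = 8L,
                                genome_length = 1e6, transition_sharpness = 5,
                                ...) {
  gs <- vapply(seq_len(n_genomes), function(i) {
    generate_genome(markov_order = 2L,
                    transition_sharpness = transition_sharpness,
                    length = genome_length, seed = mix_seed(seed, i))
  }, character(1))
  names(gs) <- sprintf("train%02d", seq_len(n_genomes))
  build_tdp_model(gs, seed = seed, ...)
}
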