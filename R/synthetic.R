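# Synthetic benchmark communities: Markov-chain genomes with distinct
# compositional biases, contigs shredded with an exponential size
# distribution, and multi-sample depth tables with super-Poisson variance,
# plus the ground-truth table needed for precision/recall scoring.

#' Specification of a synthetic community
#'
#' Defaults describe the package's reference benchmark: 10 genomes of 3 Mb,
#' order-2 Markov composition with sharpness 5, 5 samples with log-uniform
#' per-genome abundances between 2 and 100 reads per base, depth variance 5
#' times the mean (super-Poisson), and contigs averaging 8 kb (all at least
#' 2.5 kb).
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param genome_length Genome length in bases.
#' @param markov_order Order of the generating Markov chain.
#' @param transition_sharpness Dirichlet concentration is
#'   `1/transition_sharpness`; larger values give more distinctive
#'   composition.
#' @param n_samples Number of samples in the depth table.
#' @param mean_depth_range Per-genome per-sample abundance is drawn
#'   log-uniformly on this (low, high) range, in reads per base.
#' @param overdispersion Depth variance / mean ratio `k` (>= 1; 1 =
#'   Poisson-like).
#' @param contig_size_mean Mean of the exponential contig-size
#'   distribution.
#' @param min_contig Minimum emitted contig size.
#' @param seed Integer RNG seed; everything downstream is deterministic in
#'   it.
#' @return List of class `community_spec`.
#' @export
community_spec <- function(n_genomes = 10L, genome_length = 3e6,
                           markov_order = 2L, transition_sharpness = 5,
                           n_samples = 5L, mean_depth_range = c(2, 100),
                           overdispersion = 5, contig_size_mean = 8000,
                           min_contig = 2500L, seed = 42L) {
  stopifnot(n_genomes >= 2, n_samples >= 1, overdispersion >= 1,
            contig_size_mean > min_contig, length(mean_depth_range) == 2L,
            mean_depth_range[1] > 0,
            mean_depth_range[2] >= mean_depth_range[1])
  structure(list(n_genomes = as.integer(n_genomes),
                 genome_length = genome_length,
                 markov_order = as.integer(markov_order),
                 transition_sharpness = transition_sharpness,
                 n_samples = as.integer(n_samples),
                 mean_depth_range = mean_depth_range,
                 overdispersion = overdispersion,
                 contig_size_mean = contig_size_mean,
                 min_contig = as.integer(min_contig),
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Generate one genome from a random Markov chain
#'
#' Draws an order-`markov_order` transition matrix with Dirichlet rows
#' (concentration `1/transition_sharpness`) and simulates a sequence from
#' it. Higher sharpness gives sparser transition rows and therefore a more
#' distinctive tetranucleotide signature.
#'
#' @param markov_order Chain order (0 = i.i.d. bases).
#' @param transition_sharpness Positive real; Dirichlet concentration is its
#'   reciprocal.
#' @param length Sequence length (must be at least `10 * 4^(order + 1)`).
#' @param seed Integer RNG seed (same seed, same sequence).
#' @return A DNA string over `ACGT`.
#' @export
generate_genome <- function(markov_order = 2L, transition_sharpness = 5,
                            length = 3e6, seed = 1L) {
  stopifnot(markov_order >= 0, transition_sharpness > 0,
            length >= 10 * 4^(markov_order + 1))
  with_seed(seed, {
    n_states <- 4L^markov_order
    conc <- 1 / transition_sharpness
    P <- matrix(rgamma(n_states * 4L, shape = conc), n_states, 4L)
    P <- pmax(P, 1e-12)
    P <- P / rowSums(P)
    cumP <- t(apply(P, 1L, cumsum))
    cumP <- matrix(cumP, n_states, 4L)
    cumP[, 4L] <- 1
    init <- if (markov_order > 0) {
      sample.int(4L, markov_order, replace = TRUE) - 1L
    } else integer(0)
    v <- markov_sim_cpp(cumP, as.integer(init), as.integer(length))
    paste(c("A", "C", "G", "T")[v + 1L], collapse = "")
  })
}

#' Shred a genome into contigs with exponential size distribution
#'
#' Successive contig lengths are `min_contig + Exp(mean = contig_size_mean -
#' min_contig)`, tiled left to right; a trailing remainder shorter than
#' `min_contig` is discarded.
#'
#' @param genome DNA string.
#' @param contig_size_mean Mean contig size in bases.
#' @param min_contig Minimum contig size.
#' @param seed Integer RNG seed.
#' @param label Genome label; contig ids are `<label>_<ordinal>`.
#' @return A `contig_set` with an extra `genome_label` column.
#' @export
shred_exponential <- function(genome, contig_size_mean = 8000,
                              min_contig = 2500L, seed = 1L, label = "g") {
  glen <- nchar(genome)
  stopifnot(glen > min_contig, contig_size_mean > min_contig)
  with_seed(seed, {
    # draw generously, then tile until the genome is exhausted
    n_guess <- ceiling(glen / min_contig) + 10L
    lens <- as.integer(floor(min_contig +
                               rexp(n_guess, 1 / (contig_size_mean - min_contig))))
    starts <- integer(0)
    out_lens <- integer(0)
    pos <- 1L
    i <- 1L
    while (glen - pos + 1L >= min_contig) {
      L <- min(lens[i], glen - pos + 1L)
      starts <- c(starts, pos)
      out_lens <- c(out_lens, L)
      pos <- pos + L
      i <- i + 1L
    }
    cs <- contig_set(sprintf("%s_%04d", label, seq_along(starts)),
                     substring(genome, starts, starts + out_lens - 1L))
    cs$genome_label <- label
    cs
  })
}

#' Simulate a multi-sample depth table for a shredded community
#'
#' Each genome receives a true per-sample abundance drawn log-uniformly on
#' `mean_depth_range`; each contig reports a mean depth drawn from
#' `Normal(a, a * k * 1000 / contig_length)` truncated at zero (longer
#' contigs estimate their depth more tightly) and a reported variance of
#' `k * mean` (super-Poisson for `k > 1`).
#'
#' @param truth Truth table (`contig_id`, `genome_label`, `length`).
#' @param spec A [community_spec()].
#' @return A `coverage_profiles` object with an `abundances` attribute
#'   (the true genome-by-sample abundance matrix).
#' @export
simulate_depth_table <- function(truth, spec) {
  stopifnot(nrow(truth) > 0)
  labels <- unique(truth$genome_label)
  with_seed(mix_seed(spec$seed, 900001L), {
    lo <- log(spec$mean_depth_range[1])
    hi <- log(spec$mean_depth_range[2])
    A <- matrix(exp(runif(length(labels) * spec$n_samples, lo, hi)),
                length(labels), spec$n_samples,
                dimnames = list(labels, NULL))
    k <- spec$overdispersion
    gidx <- match(truth$genome_label, labels)
    n <- nrow(truth)
    means <- matrix(0, n, spec$n_samples)
    for (s in seq_len(spec$n_samples)) {
      a <- A[gidx, s]
      sd_mean <- sqrt(a * k * 1000 / truth$length)
      means[, s] <- pmax(rnorm(n, a, sd_mean), 0)
    }
    vars <- k * means
    prof <- coverage_profiles(truth$contig_id, truth$length, means, vars)
    attr(prof, "abundances") <- A
    prof
  })
}

#' Generate a complete synthetic community fixture
#'
#' Writes `assembly.fa`, `depth.tsv` and `truth.tsv` to `outdir`; re-running
#' with the same spec reproduces byte-identical files.
#'
#' @param spec A [community_spec()].
#' @param outdir Output directory (created if absent); `NULL` to skip
#'   writing and only return the in-memory objects.
#' @return Invisibly, a list with `contigs` (`contig_set`), `truth`
#'   (`data.frame`), `profiles` (`coverage_profiles`), `genomes` (named
#'   character), and `paths` (when written).
#' @export
make_fixture <- function(spec = community_spec(), outdir = NULL) {
  labels <- sprintf("g%02d", seq_len(spec$n_genomes))
  genomes <- vapply(seq_len(spec$n_genomes), function(i) {
    generate_genome(spec$markov_order, spec$transition_sharpness,
                    spec$genome_length, seed = mix_seed(spec$seed, i))
  }, character(1))
  names(genomes) <- labels
  shredded <- lapply(seq_len(spec$n_genomes), function(i) {
    shred_exponential(genomes[[i]], spec$contig_size_mean, spec$min_contig,
                      seed = mix_seed(spec$seed, 500L + i), label = labels[i])
  })
  contigs <- do.call(rbind, shredded)
  class(contigs) <- c("contig_set", "data.frame")
  truth <- data.frame(contig_id = contigs$id,
                      genome_label = contigs$genome_label,
                      length = contigs$length, stringsAsFactors = FALSE)
  profiles <- simulate_depth_table(truth, spec)
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(assembly = file.path(outdir, "assembly.fa"),
               depth = file.path(outdir, "depth.tsv"),
               truth = file.path(outdir, "truth.tsv"))
    write_fasta(contigs$id, contigs$seq, paths[["assembly"]])
    write_depth_table(profiles, paths[["depth"]])
    write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(list(contigs = contigs, truth = truth, profiles = profiles,
                 genomes = genomes, paths = paths))
}
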