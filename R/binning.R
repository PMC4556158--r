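# Modified iterative medoid clustering: seed on the deepest contig, recruit
# everything within a distance cutoff of the medoid, re-elect the medoid
# until stable, sweep until no contig is left, keep only large bins, then
# optionally recruit leftover contigs by abundance correlation when enough
# samples exist. Every tie-break is a total order so runs are deterministic.

#' Binning configuration
#'
#' @param p1 Seed-recruitment probability cutoff; contigs within distance
#'   `1 - p1` of the medoid are recruited (default 0.90).
#' @param p2 Refinement cutoff applied after medoid convergence; members
#'   farther than `1 - p2` from the final medoid are dropped when
#'   `p2 > p1` (default 0.95).
#' @param min_contig_size Smallest contig admitted to clustering (default
#'   2500 bases; depth statistics are unstable below that).
#' @param min_bin_size Bins with at most this many total bases are dissolved
#'   (default 200000).
#' @param min_samples_for_recruit Minimum sample count for the
#'   correlation-based recruitment step (default 10).
#' @param recruit_corr Minimum Pearson correlation for recruitment (default
#'   0.9).
#' @param max_medoid_iters Iteration cap for the medoid update loop.
#' @param seed Integer RNG seed recorded in run reports (the clustering
#'   itself is deterministic).
#' @return List of class `binning_config`.
#' @export
binning_config <- function(p1 = 0.90, p2 = 0.95, min_contig_size = 2500L,
                           min_bin_size = 200000L,
                           min_samples_for_recruit = 10L, recruit_corr = 0.9,
                           max_medoid_iters = 50L, seed = 0L) {
  stopifnot(p1 > 0, p1 <= p2, p2 < 1, min_contig_size >= 1500,
            min_bin_size > 0, max_medoid_iters >= 1)
  structure(list(p1 = p1, p2 = p2,
                 min_contig_size = as.integer(min_contig_size),
                 min_bin_size = as.numeric(min_bin_size),
                 min_samples_for_recruit = as.integer(min_samples_for_recruit),
                 recruit_corr = recruit_corr,
                 max_medoid_iters = as.integer(max_medoid_iters),
                 seed = as.integer(seed)),
            class = "binning_config")
}

# Total-order ranking used by every tie-break: best = highest criterion,
# then longest contig, then lexicographically smallest id.
pick_best <- function(ids, criterion, lengths) {
  ord <- order(-criterion, -lengths, ids, method = "radix")
  ids[ord[1L]]
}

#' Select the next seed contig
#'
#' The unbinned contig with the greatest summed mean depth across samples;
#' without coverage profiles, the longest contig. Ties go to the longer
#' contig, then the lexicographically smaller id.
#'
#' @param unbinned Character vector of candidate contig ids (non-empty).
#' @param profiles Optional `coverage_profiles`.
#' @param lengths Named vector of contig lengths (bases).
#' @return A single contig id.
#' @export
select_seed <- function(unbinned, profiles = NULL, lengths) {
  if (length(unbinned) == 0L) stop_state("no unbinned contigs to seed from")
  len <- lengths[unbinned]
  crit <- if (is.null(profiles)) {
    rep(0, length(unbinned))
  } else {
    rowSums(profiles$means[match(unbinned, profiles$ids), , drop = FALSE])
  }
  pick_best(unbinned, crit, len)
}

#' Grow one bin around a seed by iterated medoid recruitment
#'
#' Membership is the medoid plus every candidate within `1 - p1` of it; the
#' medoid is then re-elected as the member minimizing its summed distance to
#' all members, and the recruit/re-elect cycle repeats until the medoid is
#' stable (or the iteration cap). When `p2 > p1`, members farther than
#' `1 - p2` from the converged medoid are dropped.
#'
#' @param seed Seed contig id (must be among `candidates`).
#' @param candidates Character vector of ids available for recruitment.
#' @param D Composite distance matrix (ids as dimnames).
#' @param lengths Named vector of contig lengths.
#' @param cfg A [binning_config()].
#' @return List of class `bin` with `member_ids`, `medoid_id`,
#'   `total_bases`.
#' @export
form_bin <- function(seed, candidates, D, lengths, cfg = binning_config()) {
  stopifnot(seed %in% candidates)
  cut1 <- 1 - cfg$p1
  medoid <- seed
  members <- seed
  for (it in seq_len(cfg$max_medoid_iters)) {
    dmed <- D[candidates, medoid]
    members <- candidates[dmed <= cut1]
    if (!(medoid %in% members)) members <- c(members, medoid)
    if (length(members) == 1L) break
    sub <- D[members, members, drop = FALSE]
    new_medoid <- pick_best(members, -colSums(sub), lengths[members])
    if (identical(new_medoid, medoid)) break
    medoid <- new_medoid
  }
  if (cfg$p2 > cfg$p1 && length(members) > 1L) {
    keep <- D[members, medoid] <= (1 - cfg$p2)
    keep[members == medoid] <- TRUE
    members <- members[keep]
  }
  new_bin(members, medoid, lengths)
}

new_bin <- function(members, medoid, lengths, bin_id = NA_integer_) {
  structure(list(bin_id = bin_id, member_ids = members, medoid_id = medoid,
                 total_bases = sum(as.numeric(lengths[members]))),
            class = "bin")
}

#' Bin all contigs by exhaustive iterative clustering
#'
#' Repeats seed selection and [form_bin()] on the remaining contigs until
#' none are left (a single sweep), then dissolves bins with at most
#' `min_bin_size` total bases back into free contigs (dissolved members are
#' not re-seeded). Retained bins are renumbered by descending total bases.
#'
#' @param contigs A `contig_set`, pre-filtered to `min_contig_size`.
#' @param D Composite distance matrix over `contigs`.
#' @param profiles Optional `coverage_profiles` (used for seed selection).
#' @param cfg A [binning_config()].
#' @return List with `bins` (list of `bin` objects) and `free` (character
#'   vector of unbinned contig ids).
#' @export
bin_all <- function(contigs, D, profiles = NULL, cfg = binning_config()) {
  if (nrow(contigs) == 0L) return(list(bins = list(), free = character(0)))
  lengths <- setNames(contigs$length, contigs$id)
  pool <- contigs$id
  raw <- list()
  while (length(pool)) {
    seed <- select_seed(pool, profiles, lengths)
    b <- form_bin(seed, pool, D, lengths, cfg)
    raw[[length(raw) + 1L]] <- b
    pool <- setdiff(pool, b$member_ids)
  }
  keep <- vapply(raw, function(b) b$total_bases > cfg$min_bin_size, logical(1))
  free <- unlist(lapply(raw[!keep], `[[`, "member_ids"), use.names = FALSE)
  bins <- raw[keep]
  if (length(bins)) {
    ord <- order(-vapply(bins, `[[`, numeric(1), "total_bases"),
                 vapply(bins, `[[`, character(1), "medoid_id"),
                 method = "radix")
    bins <- bins[ord]
    for (k in seq_along(bins)) bins[[k]]$bin_id <- k
  }
  list(bins = bins, free = if (is.null(free)) character(0) else free)
}

#' Recruit leftover contigs into bins by abundance correlation
#'
#' Only performed with at least `min_samples_for_recruit` samples. Each free
#' contig's per-sample mean-depth vector is correlated (Pearson) with each
#' bin's profile (the per-sample mean over member depth vectors); the contig
#' joins the best bin if the correlation reaches `recruit_corr` and strictly
#' exceeds the runner-up.
#'
#' @param bins List of `bin` objects (from [bin_all()]).
#' @param small_contigs Character vector of free or sub-threshold contig
#'   ids.
#' @param profiles `coverage_profiles` covering bins' members and the
#'   candidates.
#' @param cfg A [binning_config()].
#' @param lengths Named contig lengths (to update bin totals).
#' @return List with updated `bins` and the still-unassigned `free` ids.
#' @export
recruit_small_contigs <- function(bins, small_contigs, profiles,
                                  cfg = binning_config(), lengths = NULL) {
  S <- ncol(profiles$means)
  if (S < cfg$min_samples_for_recruit) {
    message(sprintf("correlation recruitment skipped: %d sample(s) < %d required",
                    S, cfg$min_samples_for_recruit))
    return(list(bins = bins, free = small_contigs))
  }
  if (length(bins) == 0L || length(small_contigs) == 0L) {
    return(list(bins = bins, free = small_contigs))
  }
  bin_prof <- vapply(bins, function(b) {
    colMeans(profiles$means[match(b$member_ids, profiles$ids), , drop = FALSE])
  }, numeric(S))                       # S x n_bins
  assigned <- integer(0)
  free <- character(0)
  for (cid in small_contigs) {
    v <- profiles$means[match(cid, profiles$ids), ]
    r <- suppressWarnings(as.numeric(cor(v, bin_prof)))
    r[is.na(r)] <- -Inf
    ord <- order(-r, method = "radix")
    best <- ord[1L]
    ok <- r[best] >= cfg$recruit_corr &&
      (length(r) == 1L || r[best] > r[ord[2L]])
    if (ok) {
      assigned <- c(assigned, best)
      bins[[best]]$member_ids <- c(bins[[best]]$member_ids, cid)
      if (!is.null(lengths)) {
        bins[[best]]$total_bases <- bins[[best]]$total_bases +
          as.numeric(lengths[cid])
      }
    } else {
      free <- c(free, cid)
    }
  }
  list(bins = bins, free = free)
}

#' Write bin FASTAs, a membership table and a summary table
#'
#' @param bins List of `bin` objects.
#' @param contigs The full `contig_set` (bin FASTAs pull sequences from it;
#'   the membership table covers every contig, with `bin_id` 0 for unbinned
#'   contigs).
#' @param outdir Output directory (created if absent).
#' @param overwrite Overwrite existing output files (default `FALSE`).
#' @return Invisibly, a character vector of written file paths.
#' @export
write_bins <- function(bins, contigs, outdir, overwrite = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(file.path(outdir, "membership.tsv"),
             file.path(outdir, "bin_summary.tsv"),
             file.path(outdir, sprintf("bin.%d.fa",
                                       vapply(bins, `[[`, integer(1), "bin_id"))))
  clash <- files[file.exists(files)]
  if (length(clash) && !overwrite) {
    stop_input("output exists (use overwrite = TRUE): %s", clash[1L])
  }
  bin_of <- setNames(rep(0L, nrow(contigs)), contigs$id)
  for (b in bins) bin_of[b$member_ids] <- b$bin_id
  membership <- data.frame(contig_id = contigs$id, bin_id = unname(bin_of))
  write.table(membership, files[1L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  summary <- data.frame(
    bin_id = vapply(bins, `[[`, integer(1), "bin_id"),
    n_contigs = vapply(bins, function(b) length(b$member_ids), integer(1)),
    total_bases = vapply(bins, `[[`, numeric(1), "total_bases"),
    medoid_id = vapply(bins, `[[`, character(1), "medoid_id"))
  write.table(format(summary, trim = TRUE, scientific = FALSE), files[2L],
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (k in seq_along(bins)) {
    b <- bins[[k]]
    idx <- match(b$member_ids, contigs$id)
    write_fasta(contigs$id[idx], contigs$seq[idx],
                file.path(outdir, sprintf("bin.%d.fa", b$bin_id)))
  }
  invisible(files)
}
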