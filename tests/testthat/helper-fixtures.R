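# Shared fixtures. Heavy artifacts (trained models, the reference synthetic
# community) are built once per test run and memoized; everything is
# generated in code from fixed seeds, so there are no data files.

.memo <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.memo[[name]])) .memo[[name]] <- build()
  .memo[[name]]
}

# Default TDP model, as the pipeline would train it.
memo_model <- function() memo("model", function() train_default_model(seed = 7L))

# Cheap model for CLI/plumbing tests.
memo_small_model <- function() memo("small_model", function() {
  train_default_model(seed = 11L, n_genomes = 4L, genome_length = 2e5,
                      size_grid = c(2500, 5000, 10000), pairs_per_cell = 3000L)
})

# The reference benchmark community (10 genomes x 5 samples, seed 42).
memo_fixture <- function() memo("fixture", function() make_fixture(community_spec()))

# Full end-to-end run on the reference community with the default model.
memo_e2e <- function() memo("e2e", function() {
  fx <- memo_fixture()
  model <- memo_model()
  D <- build_distance_matrix(fx$contigs, model = model, profiles = fx$profiles)
  res <- bin_all(fx$contigs, D, fx$profiles)
  scores <- score_bins(res$bins, fx$truth)
  list(fx = fx, model = model, D = D, bins = res$bins, free = res$free,
       scores = scores)
})

# Independent total-variation oracle: numerical integration of
# |phi1 - phi2| / 2, split at the density crossing points located by sign
# changes (plain adaptive quadrature is inaccurate at the kinks).
oracle_adp <- function(m1, v1, m2, v2) {
  g <- function(x) stats::dnorm(x, m1, sqrt(v1)) - stats::dnorm(x, m2, sqrt(v2))
  lo <- min(m1, m2) - 12 * sqrt(max(v1, v2))
  hi <- max(m1, m2) + 12 * sqrt(max(v1, v2))
  xs <- seq(lo, hi, length.out = 4001L)
  sg <- sign(g(xs))
  flips <- which(diff(sg) != 0 & sg[-length(sg)] != 0)
  cross <- vapply(flips, function(i) {
    stats::uniroot(g, c(xs[i], xs[i + 1L]), tol = 1e-13)$root
  }, numeric(1))
  pieces <- c(-Inf, sort(cross), Inf)
  sum(vapply(seq_len(length(pieces) - 1L), function(i) {
    stats::integrate(function(x) abs(g(x)) / 2, pieces[i], pieces[i + 1L],
                     rel.tol = 1e-11, abs.tol = 1e-12)$value
  }, numeric(1)))
}

# Independent reverse complement for oracle checks.
oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Random DNA string (no package RNG state leaked).
random_dna <- function(n, seed, alphabet = c("A", "C", "G", "T")) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A tiny contig_set with forced ids/lengths for clustering tests (sequences
# are only needed when FASTA output is exercised).
toy_contigs <- function(ids, lengths, seed = 99L) {
  seqs <- vapply(seq_along(ids), function(i) random_dna(lengths[i], seed + i),
                 character(1))
  df <- data.frame(id = ids, seq = seqs, length = as.integer(lengths),
                   stringsAsFactors = FALSE)
  class(df) <- c("contig_set", "data.frame")
  df
}

# Symmetric distance matrix from an upper-triangle spec list d[["a|b"]].
toy_distance_matrix <- function(ids, entries, default = 1) {
  n <- length(ids)
  D <- matrix(default, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  for (key in names(entries)) {
    pair <- strsplit(key, "|", fixed = TRUE)[[1]]
    D[pair[1], pair[2]] <- D[pair[2], pair[1]] <- entries[[key]]
  }
  D
}

new_bin_for_test <- function(members, medoid, lengths, bin_id) {
  structure(list(bin_id = bin_id, member_ids = members, medoid_id = medoid,
                 total_bases = sum(as.numeric(lengths[members]))),
            class = "bin")
}

write_tmp_fasta <- function(lines, ext = ".fa") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
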