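# Canonical tetranucleotide machinery. The 256 4-mers collapse into 136
# classes under reverse complementation (16 palindromes + 120 collapsed
# pairs); assembled contigs have arbitrary strand, so counts must be
# strand-invariant.

tnf_env <- new.env(parent = emptyenv())

#' Canonical tetranucleotide classes
#'
#' @return Character vector of the 136 canonical tetramers (each the
#'   lexicographically smaller of a 4-mer and its reverse complement),
#'   sorted lexicographically.
#' @export
canonical_tetramers <- function() {
  if (is.null(tnf_env$classes)) {
    bases <- c("A", "C", "G", "T")
    all4 <- do.call(paste0, expand.grid(bases, bases, bases, bases,
                                        stringsAsFactors = FALSE)[, 4:1])
    rc <- reverse_complement(all4)
    canon <- ifelse(all4 <= rc, all4, rc)
    classes <- sort(unique(canon))
    tnf_env$all4 <- all4
    tnf_env$canon_of <- canon
    tnf_env$classes <- classes
    # column-collapse map: 256-long index into the 136 classes
    tnf_env$class_idx <- match(canon, classes)
  }
  tnf_env$classes
}

#' Tetranucleotide frequency vectors for a set of sequences
#'
#' Slides a 4-base window with step 1 over each sequence; windows containing
#' `N` are skipped; each counted 4-mer is pooled with its reverse complement
#' into one of 136 canonical classes, and counts are normalized to
#' frequencies.
#'
#' @param seqs Character vector of DNA sequences (or a `contig_set`).
#' @return List with `values`, an `n x 136` row-normalized frequency matrix
#'   (all zeros for unusable sequences), and `valid_kmers`, the number of
#'   counted windows per sequence.
#' @export
tnf_vectors <- function(seqs) {
  if (inherits(seqs, "contig_set")) {
    ids <- seqs$id
    seqs <- seqs$seq
  } else {
    ids <- names(seqs)
  }
  classes <- canonical_tetramers()
  ss <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(ss, width = 4L, step = 1L)
  # collapse the 256 columns onto canonical classes
  collapsed <- t(rowsum(t(counts), group = tnf_env$class_idx))
  colnames(collapsed) <- classes
  valid <- as.integer(rowSums(collapsed))
  values <- collapsed
  nz <- valid >= 1L
  values[nz, ] <- collapsed[nz, , drop = FALSE] / valid[nz]
  values[!nz, ] <- 0
  rownames(values) <- ids
  list(values = values, valid_kmers = valid)
}

#' Tetranucleotide frequency vector of one sequence
#'
#' @param seq A single DNA string.
#' @return List with `values` (length-136 named frequency vector) and
#'   `valid_kmers` (0 if no countable window exists; the vector is then all
#'   zeros and must not be used in distances).
#' @export
tnf_vector <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  m <- tnf_vectors(seq)
  list(values = m$values[1L, ], valid_kmers = m$valid_kmers[1L])
}

#' Euclidean distance between two TNF vectors
#'
#' @param a,b TNF vectors as returned by [tnf_vector()] (or bare numeric
#'   vectors, assumed usable).
#' @return Non-negative Euclidean (L2) distance.
#' @export
tnf_distance <- function(a, b) {
  va <- if (is.list(a)) a else list(values = a, valid_kmers = 1L)
  vb <- if (is.list(b)) b else list(values = b, valid_kmers = 1L)
  if (va$valid_kmers < 1L || vb$valid_kmers < 1L) {
    stop_input("TNF distance undefined: a vector with no valid 4-mer windows")
  }
  sqrt(sum((va$values - vb$values)^2))
}

# All pairwise Euclidean distances between rows of tnf matrix `m1` and `m2`.
tnf_cross_distances <- function(m1, m2) {
  d2 <- outer(rowSums(m1^2), rowSums(m2^2), "+") - 2 * tcrossprod(m1, m2)
  sqrt(pmax(d2, 0))
}
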