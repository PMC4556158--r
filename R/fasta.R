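#' Read assembled contigs from a FASTA file
#'
#' Reads a (plain or gzip-compressed) FASTA assembly into a contig table.
#' Sequences are upper-cased and any character outside `A/C/G/T` is mapped to
#' `N`; the contig identifier is the header token up to the first whitespace.
#'
#' @param path Path to a FASTA file (`.fa`, `.fasta`, optionally `.gz`).
#' @return A `data.frame` of class `contig_set` with columns `id`, `seq` and
#'   `length` (bases), one row per FASTA record in file order.
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_input("FASTA file not found: %s", as.character(path)[1L])
  }
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop_format("malformed FASTA in %s: %s", path, conditionMessage(e))
  )
  if (length(ss) == 0L) stop_format("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyNA(ids) || any(ids == "")) {
    stop_format("FASTA record %d in %s has an empty header", which(ids == "")[1L], path)
  }
  if (anyDuplicated(ids)) {
    stop_format("duplicate contig id in %s: %s", path, ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGT]", "N", seqs)
  contig_set(ids, unname(seqs))
}

contig_set <- function(ids, seqs) {
  out <- data.frame(id = ids, seq = seqs, length = nchar(seqs),
                    stringsAsFactors = FALSE)
  class(out) <- c("contig_set", "data.frame")
  out
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("contig_set: %d contigs, %.0f bases (min %d, max %d)\n",
              nrow(x), sum(as.numeric(x$length)),
              if (nrow(x)) min(x$length) else 0L,
              if (nrow(x)) max(x$length) else 0L))
  invisible(x)
}

write_fasta <- function(ids, seqs, path, width = 80L) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
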