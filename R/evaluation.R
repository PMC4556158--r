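# Base-weighted scoring of bins against a ground-truth contig -> genome
# table. Precision is the fraction of a bin's bases from its best-matching
# genome; recall is the fraction of that genome's assembled bases the bin
# captured.

#' Score bins against a truth table
#'
#' @param bins List of `bin` objects, or a membership `data.frame` with
#'   columns `contig_id` and `bin_id` (`bin_id` 0 = unbinned).
#' @param truth `data.frame` with columns `contig_id`, `genome_label`,
#'   `length` — every binned contig must appear.
#' @return `data.frame` with one row per bin: `bin_id`, `best_genome`,
#'   `precision`, `recall`, `bin_bases`, `genome_bases`. Ties for the best
#'   genome go to the larger genome.
#' @export
score_bins <- function(bins, truth) {
  stopifnot(all(c("contig_id", "genome_label", "length") %in% names(truth)))
  if (is.data.frame(bins)) {
    bins <- bins[bins$bin_id != 0L, , drop = FALSE]
    bins <- lapply(split(bins$contig_id, bins$bin_id), function(m) {
      list(bin_id = NA_integer_, member_ids = m)
    })
    for (k in seq_along(bins)) bins[[k]]$bin_id <- as.integer(names(bins)[k])
  }
  genome_bases <- tapply(as.numeric(truth$length), truth$genome_label, sum)
  rows <- lapply(bins, function(b) {
    idx <- match(b$member_ids, truth$contig_id)
    if (anyNA(idx)) {
      stop_input("binned contig '%s' absent from the truth table",
                 b$member_ids[is.na(idx)][1L])
    }
    shared <- tapply(as.numeric(truth$length[idx]), truth$genome_label[idx], sum)
    bin_bases <- sum(as.numeric(truth$length[idx]))
    g_sizes <- genome_bases[names(shared)]
    ord <- order(-shared, -g_sizes, names(shared), method = "radix")
    best <- names(shared)[ord[1L]]
    data.frame(bin_id = b$bin_id, best_genome = best,
               precision = shared[[best]] / bin_bases,
               recall = shared[[best]] / genome_bases[[best]],
               bin_bases = bin_bases, genome_bases = genome_bases[[best]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(bin_id = integer(), best_genome = character(),
                      precision = numeric(), recall = numeric(),
                      bin_bases = numeric(), genome_bases = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Count genomes recovered as "good" bins
#'
#' A genome counts when it is the best genome of at least one bin with
#' precision strictly above `precision_min` and recall strictly above
#' `recall_min` (defaults: the >90% purity / >30% completeness bar).
#'
#' @param scores Output of [score_bins()].
#' @param precision_min,recall_min Strict lower thresholds.
#' @return Integer count of distinct genomes.
#' @export
count_good_genomes <- function(scores, precision_min = 0.9, recall_min = 0.3) {
  good <- scores$precision > precision_min & scores$recall > recall_min
  length(unique(scores$best_genome[good]))
}

#' Read a truth table (contig_id, genome_label, length)
#' @param path TSV path with header.
#' @return `data.frame` with the three columns.
#' @export
read_truth_table <- function(path) {
  if (!file.exists(path)) stop_input("truth table not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("contig_id", "genome_label", "length") %in% names(df)))
  df
}
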