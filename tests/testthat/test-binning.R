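test_that("select_seed prefers depth, then length, then id", {
  lengths <- c(c1 = 3000L, c2 = 5000L, c3 = 4000L)
  prof <- list(ids = c("c1", "c2", "c3"),
               means = matrix(c(10, 5, 5), 3, 1,
                              dimnames = list(c("c1", "c2", "c3"), "s1")))
  class(prof) <- "coverage_profiles"
  expect_equal(select_seed(c("c1", "c2", "c3"), prof, lengths), "c1")
  # depth tie between c2 and c3: longer wins
  expect_equal(select_seed(c("c2", "c3"), prof, lengths), "c2")
  # composition-only mode: longest contig
  expect_equal(select_seed(c("c1", "c2", "c3"), NULL, lengths), "c2")
  expect_error(select_seed(character(0), NULL, lengths),
               class = "tetrabin_state_error")
})

test_that("form_bin recruits, re-elects the medoid, and refines", {
  cfg <- binning_config(p1 = 0.9, p2 = 0.95)
  ids <- c("a", "b", "c", "d")
  lengths <- c(a = 3000L, b = 3000L, c = 3000L, d = 3000L)
  # three mutually-identical contigs, one far away
  D <- toy_distance_matrix(ids, list("a|b" = 0, "a|c" = 0, "b|c" = 0))
  bin <- form_bin("a", ids, D, lengths, cfg)
  expect_setequal(bin$member_ids, c("a", "b", "c"))
  expect_equal(bin$total_bases, 9000)

  # everything beyond the cutoff: singleton
  Dfar <- toy_distance_matrix(ids, list())
  solo <- form_bin("a", ids, Dfar, lengths, cfg)
  expect_equal(solo$member_ids, "a")
  expect_equal(solo$medoid_id, "a")

  # hand-traced chain: d(a,b) = d(b,c) = 0.05, d(a,c) = 0.2; the first
  # round recruits {a, b}, the medoid moves to b, the second round pulls in
  # c, and the medoid stays at b
  lengths2 <- c(a = 3000L, b = 5000L, c = 3000L)
  Dch <- toy_distance_matrix(c("a", "b", "c"),
                             list("a|b" = 0.05, "b|c" = 0.05, "a|c" = 0.2))
  chain <- form_bin("a", c("a", "b", "c"), Dch, lengths2, cfg)
  expect_setequal(chain$member_ids, c("a", "b", "c"))
  expect_equal(chain$medoid_id, "b")

  # refinement drop: p2 cutoff 0.05 removes a member at 0.08 from the medoid
  Dref <- toy_distance_matrix(c("a", "b", "c"),
                              list("a|b" = 0.01, "a|c" = 0.08, "b|c" = 0.08))
  ref <- form_bin("a", c("a", "b", "c"), Dref,
                  c(a = 9000L, b = 3000L, c = 3000L), cfg)
  expect_setequal(ref$member_ids, c("a", "b"))
})

test_that("bin_all partitions, dissolves small bins, and is deterministic", {
  # two tight groups, each above the bin-size floor
  ids <- paste0("c", 1:6)
  lengths <- setNames(rep(120000L, 6), ids)
  ent <- list("c1|c2" = 0.01, "c1|c3" = 0.01, "c2|c3" = 0.01,
              "c4|c5" = 0.01, "c4|c6" = 0.01, "c5|c6" = 0.01)
  D <- toy_distance_matrix(ids, ent)
  contigs <- toy_contigs(ids, lengths)
  res <- bin_all(contigs, D, NULL, binning_config())
  expect_length(res$bins, 2L)
  expect_setequal(res$bins[[1]]$member_ids, c("c1", "c2", "c3"))
  expect_setequal(res$bins[[2]]$member_ids, c("c4", "c5", "c6"))
  expect_equal(res$free, character(0))
  # partition property
  all_members <- unlist(lapply(res$bins, `[[`, "member_ids"))
  expect_equal(anyDuplicated(all_members), 0L)

  # a group totalling 150 kb is dissolved
  small <- toy_contigs(c("s1", "s2"), c(75000L, 75000L))
  Ds <- toy_distance_matrix(c("s1", "s2"), list("s1|s2" = 0.01))
  res2 <- bin_all(small, Ds, NULL, binning_config())
  expect_length(res2$bins, 0L)
  expect_setequal(res2$free, c("s1", "s2"))

  expect_equal(bin_all(toy_contigs(character(0), integer(0))[0, ], Ds),
               list(bins = list(), free = character(0)))

  # byte-identical membership across two identical runs
  out1 <- tempfile(); out2 <- tempfile()
  write_bins(res$bins, contigs, out1)
  write_bins(bin_all(contigs, D, NULL, binning_config())$bins, contigs, out2)
  expect_identical(readLines(file.path(out1, "membership.tsv")),
                   readLines(file.path(out2, "membership.tsv")))
})

test_that("bin_all first bin matches the brute-force best medoid cluster", {
  # <= 8 contigs; equal lengths and depths such that the deepest contig
  # seeds inside the dominant block, making the greedy sweep optimal
  ids <- paste0("x", 1:8)
  lengths <- setNames(rep(50000L, 8), ids)
  set.seed(97)
  ent <- list()
  for (i in 1:4) for (j in 1:4) if (i < j) {
    ent[[paste0("x", i, "|x", j)]] <- runif(1, 0, 0.08)
  }
  for (i in 5:8) for (j in 5:8) if (i < j) {
    ent[[paste0("x", i, "|x", j)]] <- runif(1, 0, 0.08)
  }
  D <- toy_distance_matrix(ids, ent)
  depth <- c(10, rep(1, 7))
  prof <- list(ids = ids, means = matrix(depth, 8, 1,
                                         dimnames = list(ids, "s1")))
  class(prof) <- "coverage_profiles"
  cfg <- binning_config(p1 = 0.9, p2 = 0.9, min_bin_size = 100000)
  res <- bin_all(toy_contigs(ids, lengths), D, prof, cfg)

  # oracle: enumerate every possible medoid; its cluster is everything
  # within the cutoff; the seed x1 lies in the 4-block, whose best medoid
  # cluster is the full block
  cut <- 1 - cfg$p1
  clusters <- lapply(ids, function(m) ids[D[, m] <= cut])
  best <- clusters[[which.max(vapply(clusters, length, integer(1)))]]
  expect_setequal(res$bins[[1]]$member_ids, best)
})

test_that("recruit_small_contigs uses correlation with strict tie rules", {
  S <- 12L
  ids <- c(paste0("m", 1:4), "free1", "free2")
  base1 <- seq(2, 24, length.out = S)
  base2 <- rev(base1)
  means <- rbind(base1 * 1.0, base1 * 1.1, base2 * 1.0, base2 * 0.9,
                 base1 * 3.0, runif(S, 1, 30))
  rownames(means) <- ids
  prof <- list(ids = ids, means = means)
  class(prof) <- "coverage_profiles"
  lengths <- setNames(rep(10000L, 6), ids)
  bins <- list(structure(list(bin_id = 1L, member_ids = c("m1", "m2"),
                              medoid_id = "m1", total_bases = 20000),
                         class = "bin"),
               structure(list(bin_id = 2L, member_ids = c("m3", "m4"),
                              medoid_id = "m3", total_bases = 20000),
                         class = "bin"))
  cfg <- binning_config()
  out <- recruit_small_contigs(bins, c("free1", "free2"), prof, cfg, lengths)
  # free1 is an exact scalar multiple of bin 1's profile: r = 1
  expect_true("free1" %in% out$bins[[1]]$member_ids)
  expect_equal(out$bins[[1]]$total_bases, 30000)

  # fewer than 10 samples: no-op with a notice
  prof5 <- prof
  prof5$means <- prof$means[, 1:5]
  expect_message(out5 <- recruit_small_contigs(bins, c("free1"), prof5, cfg,
                                               lengths), "skipped")
  expect_equal(out5$free, "free1")
  expect_false("free1" %in% out5$bins[[1]]$member_ids)

  # exact correlation tie between two bins: unassigned
  prof_tie <- prof
  prof_tie$means["m2", ] <- prof$means["m1", ]
  prof_tie$means["m3", ] <- prof$means["m1", ] * 2
  prof_tie$means["m4", ] <- prof$means["m1", ] * 2
  out_tie <- recruit_small_contigs(bins, "free1", prof_tie, cfg, lengths)
  expect_equal(out_tie$free, "free1")
})

test_that("write_bins emits consistent FASTA and tables", {
  ids <- paste0("c", 1:5)
  contigs <- toy_contigs(ids, c(4000L, 3000L, 5000L, 2500L, 2600L))
  lengths <- setNames(contigs$length, ids)
  bins <- list(new_bin_for_test(c("c1", "c2"), "c1", lengths, 1L),
               new_bin_for_test(c("c3", "c4"), "c3", lengths, 2L))
  outdir <- tempfile()
  files <- write_bins(bins, contigs, outdir)
  expect_true(all(file.exists(file.path(outdir, c("membership.tsv",
                                                  "bin_summary.tsv",
                                                  "bin.1.fa", "bin.2.fa")))))
  membership <- read.table(file.path(outdir, "membership.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(membership), 5L)
  expect_equal(membership$bin_id[membership$contig_id == "c5"], 0L)
  summary <- read.table(file.path(outdir, "bin_summary.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
  fa1 <- Biostrings::readDNAStringSet(file.path(outdir, "bin.1.fa"))
  expect_equal(sum(Biostrings::width(fa1)),
               summary$total_bases[summary$bin_id == 1])
  expect_error(write_bins(bins, contigs, outdir),
               class = "tetrabin_input_error")
  expect_silent(write_bins(bins, contigs, outdir, overwrite = TRUE))
})
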