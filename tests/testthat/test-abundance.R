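test_that("adp_single matches the closed forms and the integration oracle", {
  expect_equal(adp_single(5, 1, 5, 1), 0)
  expect_equal(adp_single(0, 1, 2, 1), 2 * pnorm(1) - 1, tolerance = 1e-12)
  # equal means, unequal variances: crossings at +/- sqrt((8/3) log 2)
  expect_equal(adp_single(0, 1, 0, 4), oracle_adp(0, 1, 0, 4),
               tolerance = 1e-9)
  expect_equal(adp_single(0, 1, 0, 4), 0.3227, tolerance = 5e-4)
  # symmetry in the two contigs
  expect_identical(adp_single(1.3, 2.1, 4.5, 0.7),
                   adp_single(4.5, 0.7, 1.3, 2.1))
  expect_error(adp_single(1, 1, NaN, 1), class = "tetrabin_input_error")
})

test_that("adp_single randomized oracle check including branch stress", {
  set.seed(71)
  for (i in 1:200) {
    m1 <- runif(1, -5, 20); m2 <- runif(1, -5, 20)
    v1 <- runif(1, 0.05, 25)
    v2 <- if (i %% 4 == 0) v1 * exp(runif(1, -1e-9, 1e-9)) else runif(1, 0.05, 25)
    got <- adp_single(m1, v1, m2, v2)
    expect_true(got >= 0 && got <= 1)
    expect_equal(got, oracle_adp(m1, v1, m2, v2), tolerance = 1e-6)
  }
})

test_that("adp_single is monotone in the mean separation", {
  deltas <- seq(0, 10, by = 0.5)
  vals <- adp_single(rep(0, length(deltas)), 2, deltas, 3)
  expect_true(all(diff(vals) >= -1e-12))
  vals_eq <- adp_single(rep(0, length(deltas)), 1.5, deltas, 1.5)
  expect_true(all(diff(vals_eq) >= -1e-12))
})

test_that("adp_combined filters uninformative samples and takes geometric means", {
  cfg <- abundance_config()
  p1 <- list(means = c(10, 20, 0.5), variances = c(5, 8, 1))
  p2 <- list(means = c(12, 3, 0.2), variances = c(6, 2, 1))
  out <- adp_combined(p1, p2, cfg)
  expect_equal(out$n_informative, 2L)   # third sample below min_cv for both
  exp_p <- adp_single(p1$means[1:2], p1$variances[1:2],
                      p2$means[1:2], p2$variances[1:2])
  expect_equal(out$adp, exp(mean(log(exp_p))))

  # two-value geometric mean sanity: sqrt(p_a * p_b)
  expect_equal(out$adp, sqrt(prod(exp_p)))

  # invariance to sample order
  perm <- c(2, 3, 1)
  out_p <- adp_combined(lapply(p1, `[`, perm), lapply(p2, `[`, perm), cfg)
  expect_equal(out_p$adp, out$adp)
  expect_equal(out_p$n_informative, out$n_informative)

  # everything below the cutoff: undefined
  low <- list(means = c(0.1, 0.4), variances = c(1, 1))
  expect_equal(adp_combined(low, low, cfg), list(adp = NA_real_,
                                                 n_informative = 0L))
  expect_error(adp_combined(p1, list(means = 1, variances = 1), cfg),
               class = "tetrabin_input_error")
})

test_that("abundance_weight follows min(log(n+1)/log(m+1), alpha)", {
  cfg <- abundance_config()
  expect_equal(abundance_weight(10, cfg), log(11) / log(101))
  expect_equal(round(abundance_weight(10, cfg), 1), 0.5)
  expect_equal(abundance_weight(100, cfg), 0.9)    # capped at alpha
  expect_equal(abundance_weight(1, cfg), log(2) / log(101))
  expect_equal(abundance_weight(0, cfg), 0)
  w <- abundance_weight(0:200, cfg)
  expect_true(all(diff(w) >= 0))
  expect_true(all(w <= cfg$weight_alpha))
})

test_that("read_depth_table parses the standard layout and validates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("contigName\tcontigLen\ttotalAvgDepth\ts1\ts1-var",
               "c1\t3000\t2.0\t2.0\t1.5"), path)
  prof <- read_depth_table(path)
  expect_equal(prof$ids, "c1")
  expect_equal(unname(prof$means[1, ]), 2.0)
  expect_equal(unname(prof$variances[1, ]), 1.5)

  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("contigName\tcontigLen\ttotalAvgDepth\ts1\ts1-var\ts2\ts2-var",
               "c1\t3000\t2.0\t2.0\t1.5\t4.0\t9.0",
               "c2\t5000\t1.0\t1.0\t0.5\t0.0\t0.0"), path2)
  prof2 <- read_depth_table(path2)
  expect_equal(dim(prof2$means), c(2L, 2L))
  expect_equal(unname(prof2$means[1, ]), c(2, 4))
  expect_equal(unname(prof2$variances[2, ]), c(0.5, 0))

  bad1 <- tempfile(); writeLines(c("contigName\tcontigLen\ttotalAvgDepth\ts1",
                                   "c1\t3000\t2.0\t2.0"), bad1)
  expect_error(read_depth_table(bad1), class = "tetrabin_format_error")
  bad2 <- tempfile(); writeLines(c("contigName\tcontigLen\ttotalAvgDepth\ts1\ts1-var",
                                   "c1\t3000\t2.0\tx\t1.5"), bad2)
  expect_error(read_depth_table(bad2), "row 1")
  expect_error(read_depth_table(tempfile()), class = "tetrabin_input_error")
})

test_that("depth table write/read round-trips", {
  prof <- simulate_depth_table(
    data.frame(contig_id = c("a", "b"), genome_label = c("g1", "g1"),
               length = c(4000L, 6000L)),
    community_spec(n_genomes = 2, genome_length = 1e4, n_samples = 3,
                   seed = 5))
  path <- tempfile(fileext = ".tsv")
  write_depth_table(prof, path)
  back <- read_depth_table(path)
  expect_equal(back$ids, prof$ids)
  expect_equal(unname(back$means), unname(prof$means), tolerance = 1e-12)
  expect_equal(unname(back$variances), unname(prof$variances),
               tolerance = 1e-12)
})

test_that("depths_from_bam computes per-base depth statistics", {
  ref <- random_dna(10, seed = 8)
  contigs <- data.frame(id = c("c1", "c2"), seq = c(ref, random_dna(10, 9)),
                        length = c(10L, 10L), stringsAsFactors = FALSE)
  class(contigs) <- c("contig_set", "data.frame")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:c1\tLN:10",
    "@SQ\tSN:c2\tLN:10",
    sprintf("r1\t0\tc1\t1\t60\t10M\t*\t0\t0\t%s\t%s", ref, strrep("I", 10)),
    sprintf("r2\t0\tc1\t1\t60\t5M\t*\t0\t0\t%s\t%s",
            substr(ref, 1, 5), strrep("I", 5))), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  prof <- depths_from_bam(bam, contigs)
  # c1: positions 1..5 at depth 2, 6..10 at depth 1 -> mean 1.5, var 0.25
  expect_equal(unname(prof$means[1, 1]), 1.5)
  expect_equal(unname(prof$variances[1, 1]), 0.25)
  # c2: no reads
  expect_equal(unname(prof$means[2, 1]), 0)
  expect_equal(unname(prof$variances[2, 1]), 0)

  # single full-span read: mean 1, variance 0
  sam2 <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:c1\tLN:10",
               sprintf("r1\t0\tc1\t1\t60\t10M\t*\t0\t0\t%s\t%s", ref,
                       strrep("I", 10))), sam2)
  bam2 <- Rsamtools::asBam(sam2, tempfile(), overwrite = TRUE,
                           indexDestination = TRUE)
  contigs1 <- contigs[1, , drop = FALSE]
  class(contigs1) <- c("contig_set", "data.frame")
  prof2 <- depths_from_bam(bam2, contigs1)
  expect_equal(unname(prof2$means[1, 1]), 1)
  expect_equal(unname(prof2$variances[1, 1]), 0)

  # contig missing from the BAM header is a hard error
  expect_error(depths_from_bam(bam2, contigs), class = "tetrabin_input_error")
  # half-covered contig: five 1s and five 0s -> mean 0.5, var 0.25
  sam3 <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:c1\tLN:10",
               sprintf("r1\t0\tc1\t1\t60\t5M\t*\t0\t0\t%s\t%s",
                       substr(ref, 1, 5), strrep("I", 5))), sam3)
  bam3 <- Rsamtools::asBam(sam3, tempfile(), overwrite = TRUE,
                           indexDestination = TRUE)
  prof3 <- depths_from_bam(bam3, contigs1)
  expect_equal(unname(prof3$means[1, 1]), 0.5)
  expect_equal(unname(prof3$variances[1, 1]), 0.25)
})
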