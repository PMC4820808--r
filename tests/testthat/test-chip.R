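test_that("multi-map weights follow the 1/n rule with the best-20 cap", {
  # a read with 20 records: 1/20 each
  rec20 <- data.frame(read_id = "r1", chrom = "chr1",
                      pos = seq(1, 20001, by = 1000)[1:20], width = 36)
  wa <- weighted_alignments(rec20)
  expect_equal(S4Vectors::mcols(wa$records)$weight, rep(1 / 20, 20))
  expect_equal(unique(S4Vectors::mcols(wa$records)$n_reported), 20L)

  # uniquely mapped read: weight 1
  wa1 <- weighted_alignments(data.frame(read_id = "u", chrom = "chr1",
                                        pos = 5, width = 36))
  expect_equal(S4Vectors::mcols(wa1$records)$weight, 1)

  # 50 equal-score records: best 20 kept, deterministic by coordinate
  rec50 <- data.frame(read_id = "r2", chrom = "chr1",
                      pos = seq(1, 49001, by = 1000), width = 36, score = 10)
  wa50 <- weighted_alignments(rec50)
  expect_equal(length(wa50$records), 20L)
  expect_equal(S4Vectors::mcols(wa50$records)$weight, rep(1 / 20, 20))
  expect_equal(GenomicRanges::start(wa50$records),
               seq(1, 19001, by = 1000))

  # weight conservation for every read with <= cap records
  set.seed(71)
  nrec <- sample(1:20, 50, replace = TRUE)
  recs <- data.frame(
    read_id = rep(sprintf("r%02d", 1:50), nrec),
    chrom = "chr1",
    pos = sample.int(1e6, sum(nrec)), width = 36)
  wam <- weighted_alignments(recs)
  sums <- tapply(S4Vectors::mcols(wam$records)$weight,
                 S4Vectors::mcols(wam$records)$read_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("weighted coverage equals direct accounting exactly", {
  # one read fully inside a 50 bp region, library of one read
  wa <- weighted_alignments(data.frame(read_id = "r", chrom = "chr1",
                                       pos = 11, width = 50))
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 60))
  expect_equal(weighted_coverage(wa, reg, scale = FALSE), 1)
  expect_equal(weighted_coverage(wa, reg), 1e6)  # 1 read, per-million

  # total weighted coverage = sum of weight x aligned length, exactly
  set.seed(72)
  nrec <- sample(1:25, 1000, replace = TRUE)
  recs <- data.frame(
    read_id = rep(sprintf("q%04d", 1:1000), nrec),
    chrom = "chr1", pos = sample.int(2e6, sum(nrec)), width = 36)
  wam <- weighted_alignments(recs)
  cov <- GenomicRanges::coverage(
    wam$records, weight = S4Vectors::mcols(wam$records)$weight)
  total_cov <- sum(as.numeric(sum(cov)))
  expect_equal(total_cov,
               sum(S4Vectors::mcols(wam$records)$weight * 36),
               tolerance = 1e-12)

  expect_error(weighted_coverage(wam, GenomicRanges::GRanges()), "empty")
})

test_that("per-million scaling is invariant under library duplication", {
  set.seed(73)
  recs <- data.frame(read_id = sprintf("r%03d", 1:200), chrom = "chr1",
                     pos = sample.int(5e4, 200), width = 36)
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5e4 + 36))
  wa1 <- weighted_alignments(recs)
  dup <- rbind(recs, transform(recs, read_id = paste0(read_id, "_dup")))
  wa2 <- weighted_alignments(dup)
  expect_equal(weighted_coverage(wa1, reg), weighted_coverage(wa2, reg))
})

test_that("SAM round trip preserves records, weights and coverage", {
  ex <- simulate_chip_experiment(genome_length = 20000, n_copies = 5,
                                 depth = 30, fold = 5, seed = 74)
  sl <- stats::setNames(Biostrings::width(ex$assembly), names(ex$assembly))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(ex$chip, sl, sam)
  from_sam <- load_alignments(sam)
  direct <- wa_from_records(ex$chip, ex$assembly)
  expect_equal(length(from_sam$records), length(direct$records))
  expect_equal(from_sam$total_weighted_reads, direct$total_weighted_reads)
  expect_equal(weighted_coverage(from_sam, ex$instances),
               weighted_coverage(direct, ex$instances))
  # a multi-mapped read keeps its NH-derived weight through the round trip
  mm <- S4Vectors::mcols(from_sam$records)
  expect_true(all(abs(mm$weight - 1 / mm$n_reported) < 1e-12))
})

test_that("family reads multi-map across near-identical copies", {
  ex <- simulate_chip_experiment(genome_length = 20000, n_copies = 8,
                                 divergence = 0, depth = 20, fold = 8,
                                 seed = 75)
  nrep <- S4Vectors::mcols(wa_from_records(ex$chip, ex$assembly)$records)$n_reported
  # identical copies: every family read reports one record per copy
  expect_true(any(nrep == 8))
})

test_that("enrichment of a library against itself is 1", {
  ex <- simulate_chip_experiment(genome_length = 30000, n_copies = 6,
                                 depth = 50, fold = 1, seed = 76)
  wa <- wa_from_records(ex$input, ex$assembly)
  er <- permutation_poisson_test(wa, wa, ex$instances, ex$assembly,
                                 n_perm = 20, seed = 77)
  expect_lt(abs(er$enrichment - 1), 0.01)
})

test_that("the Poisson tail uses the ceiling of the observed enrichment", {
  ex <- simulate_chip_experiment(genome_length = 30000, n_copies = 6,
                                 depth = 50, fold = 6, seed = 78)
  er <- permutation_poisson_test(wa_from_records(ex$chip, ex$assembly),
                                 wa_from_records(ex$input, ex$assembly),
                                 ex$instances, ex$assembly,
                                 n_perm = 20, seed = 79)
  expect_equal(er$p_value,
               stats::ppois(ceiling(er$enrichment) - 1, er$lambda,
                            lower.tail = FALSE))
  expect_equal(er$lambda, mean(er$perm_scores))
  expect_length(er$perm_scores, 20)
  expect_error(
    permutation_poisson_test(wa_from_records(ex$chip, ex$assembly),
                             wa_from_records(ex$input, ex$assembly),
                             ex$instances, ex$assembly, n_perm = 5),
    "n_perm")
})

test_that("bedGraph export reconstructs the weighted coverage", {
  recs <- data.frame(read_id = c("a", "b", "b"), chrom = "chr1",
                     pos = c(1, 1, 101), width = 50)
  wa <- weighted_alignments(recs)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(wa, f, scale = FALSE)
  bg <- utils::read.delim(f, header = FALSE)
  # base 1-50: weights 1 + 0.5; base 101-150: 0.5
  expect_equal(bg$V4[1], 1.5)
  expect_equal(bg$V4[2], 0.5)
  expect_equal(bg$V2[1], 0L)  # bedGraph is 0-based half-open
  expect_equal(bg$V3[1], 50L)
})
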