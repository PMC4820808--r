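test_that("mask_te applies union semantics and leaves the input untouched", {
  a <- Biostrings::DNAStringSet(c(chr1 = "ACGTAC"))
  m0 <- mask_te(a, GenomicRanges::GRanges())
  expect_identical(as.character(m0$assembly), as.character(a))

  # 0-based half-open (2,4) is 1-based closed 3..4
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3, 4))
  expect_message(m <- mask_te(a, gr), "masked 2 bp")
  expect_equal(as.character(m$assembly[["chr1"]]), "ACNNAC")
  expect_equal(as.character(a[["chr1"]]), "ACGTAC")

  a8 <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  ov <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 3), c(4, 6)))
  m2 <- suppressMessages(mask_te(a8, ov))
  expect_equal(as.character(m2$assembly[["chr1"]]), "NNNNNNGT")

  bad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 20))
  expect_error(mask_te(a8, bad), "off the end")
})

test_that("find_seeds counts a homopolymer run and pools strands", {
  a <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 100)))
  seeds <- find_seeds(a, k = 16, min_count = 2)
  expect_length(seeds, 1)
  expect_equal(length(seeds[[1]]$pos), 85L)  # 100 - 16 + 1
  expect_true(all(seeds[[1]]$strand == "+"))
})

test_that("random genomes yield no repeated 16-mers", {
  for (s in 1:5) {
    a <- Biostrings::DNAStringSet(c(chr1 = rand_dna(10000, seed = s)))
    expect_length(find_seeds(a, k = 16, min_count = 5), 0)
  }
})

test_that("every 16-mer of a 5-copy planted repeat seeds at least 5 hits", {
  g <- plant_genome(rand_dna(200, seed = 7), strands = rep("+", 5), seed = 8)
  seeds <- find_seeds(g$assembly, min_count = 5)
  expect_gte(length(seeds), 200 - 16 + 1)
  expect_true(all(lengths(lapply(seeds, `[[`, "pos")) >= 5))
})

test_that("extension recovers an exact planted consensus on both strands", {
  cons <- rand_dna(200, seed = 42)
  g <- plant_genome(cons, strands = c("+", "-", "+", "-", "+"), seed = 43)
  fams <- discover_repeats(g$assembly, min_count = 3)
  expect_length(fams, 1)
  f <- fams[[1]]
  expect_true(f$consensus %in% c(cons, revcomp_chr(cons)))
  expect_length(f$instances, 5)
  expect_true(all(S4Vectors::mcols(f$instances)$identity == 1))
  expect_equal(sort(GenomicRanges::start(f$instances)), sort(g$starts))
  # objective: 5 copies x 200 matches - penalty 2 x 200
  expect_equal(f$objective_score, 5 * 200 - 2 * 200)
})

test_that("a single copy cannot form a family", {
  g <- plant_genome(rand_dna(200, seed = 1), strands = "+", seed = 2)
  expect_length(discover_repeats(g$assembly, min_count = 2), 0)
})

test_that("diverged copies majority-vote back to the planted consensus", {
  cons <- rand_dna(300, seed = 10)
  ok <- 0
  for (rep in 1:10) {
    set.seed(100 + rep)
    copies <- vapply(1:6, function(i) mutate_copy(cons, 0.10, 0), "")
    geno <- rand_dna(500)
    for (cp in copies) geno <- paste0(geno, cp, rand_dna(500))
    fams <- discover_repeats(Biostrings::DNAStringSet(c(chr1 = geno)),
                             min_count = 3, refine_instances = FALSE)
    if (!length(fams)) next
    f <- fams[[which.max(vapply(fams, function(x) length(x$instances), 1L))]]
    ident <- max(vapply(c(f$consensus, revcomp_chr(f$consensus)), function(cs) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(cs), Biostrings::DNAString(cons),
        type = "overlap",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          1, -1, baseOnly = TRUE), gapOpening = 4, gapExtension = 1)
      Biostrings::nmatch(pa) / nchar(cons)
    }, numeric(1)))
    if (ident >= 0.95 && abs(nchar(f$consensus) - 300) <= 10) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("discovery is deterministic and respects min_count monotonicity", {
  set.seed(77)
  geno <- rand_dna(2000)
  c1 <- rand_dna(150); c2 <- rand_dna(120)
  for (i in 1:4) geno <- paste0(geno, c1, rand_dna(300))
  for (i in 1:3) geno <- paste0(geno, c2, rand_dna(300))
  a <- Biostrings::DNAStringSet(c(chr1 = geno))
  f1 <- discover_repeats(a, min_count = 3)
  f2 <- discover_repeats(a, min_count = 3)
  expect_identical(vapply(f1, `[[`, "", "consensus"),
                   vapply(f2, `[[`, "", "consensus"))
  n_by_count <- vapply(c(2L, 3L, 4L, 5L), function(mc)
    length(discover_repeats(a, min_count = mc)), integer(1))
  expect_true(all(diff(n_by_count) <= 0))
})

test_that("strand closure: reverse-complemented genome gives the same families", {
  cons <- rand_dna(180, seed = 20)
  g <- plant_genome(cons, strands = c("+", "+", "-"), seed = 21)
  rc_asm <- Biostrings::reverseComplement(g$assembly)
  names(rc_asm) <- names(g$assembly)
  f_fwd <- discover_repeats(g$assembly, min_count = 3)
  f_rev <- discover_repeats(rc_asm, min_count = 3)
  expect_equal(length(f_fwd), length(f_rev))
  cons_fwd <- f_fwd[[1]]$consensus
  expect_true(f_rev[[1]]$consensus %in% c(cons_fwd, revcomp_chr(cons_fwd)))
  expect_equal(length(f_rev[[1]]$instances), length(f_fwd[[1]]$instances))
})

test_that("fully masked genomes yield nothing", {
  a <- Biostrings::DNAStringSet(c(chr1 = strrep("N", 5000)))
  expect_length(discover_repeats(a), 0)
})
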