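test_that("read_fasta folds case, converts U, replaces odd characters", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgt"), f)
  a <- read_fasta(f)
  expect_equal(as.character(a[["chr1"]]), "ACGT")
  expect_equal(unname(Biostrings::width(a)), 4L)

  writeLines(c(">r", "ACGU"), f)
  expect_equal(as.character(read_fasta(f)[["r"]]), "ACGT")

  writeLines(c(">x", "ACRT"), f)
  expect_warning(a <- read_fasta(f), "replaced by N")
  expect_equal(as.character(a[["x"]]), "ACNT")
})

test_that("read_fasta rejects duplicate headers and empty files", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate.*a")
  writeLines(character(0), f)
  expect_error(read_fasta(f))
})

test_that("FASTA round-trips exactly", {
  f <- withr::local_tempfile(fileext = ".fa")
  seqs <- Biostrings::DNAStringSet(c(s1 = rand_dna(301, seed = 1),
                                     s2 = rand_dna(57, seed = 2)))
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_identical(as.character(back), as.character(seqs))
})

test_that("BED and GTF coordinate conventions convert and round-trip", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tx\t0\t+", f)
  gr <- read_intervals(f, "bed")
  # 0-based half-open [10, 20) is 1-based closed [11, 20]
  expect_equal(GenomicRanges::start(gr), 11L)
  expect_equal(GenomicRanges::end(gr), 20L)

  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, out)
  fields <- strsplit(readLines(out), "\t")[[1]]
  expect_equal(as.integer(fields[2:3]), c(10L, 20L))
  gr2 <- read_intervals(out, "bed")
  expect_equal(GenomicRanges::ranges(gr), GenomicRanges::ranges(gr2))

  g <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "gene", "11", "20", ".", "+", ".",
                   'gene_id "g1"; gene_type "lncRNA";', sep = "\t"), g)
  gg <- read_intervals(g, "gtf")
  expect_equal(GenomicRanges::start(gg), 11L)
  expect_equal(GenomicRanges::end(gg), 20L)
  expect_equal(S4Vectors::mcols(gg)$biotype, "lncRNA")
})

test_that("invalid intervals error with the line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t5\t9", "chr1\t20\t10"), f)
  expect_error(read_intervals(f, "bed"), "line 2")
})

test_that("JASPAR PFM parsing handles both row styles and bad input", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 test",
               "A [10  0]", "C [ 0 10]", "G [ 0  0]", "T [ 0  0]",
               ">M2", "A 1 2 3", "C 1 2 3", "G 1 2 3", "T 1 2 3"), f)
  pfms <- read_pfm(f)
  expect_length(pfms, 2)
  expect_equal(pfms[[1]]$motif_id, "MA0001.1")
  expect_equal(ncol(pfms[[1]]$counts), 2L)
  expect_equal(unname(pfms[[1]]$counts["A", 1]), 10)
  expect_equal(pfms[[1]]$background, rep(0.25, 4))

  writeLines(c(">bad", "A 1 2", "C 1 2 3", "G 1 2", "T 1 2"), f)
  expect_error(read_pfm(f), "bad.*unequal width")

  writeLines(character(0), f)
  expect_identical(read_pfm(f), list())
})

test_that("the shipped synthetic motif file parses", {
  f <- system.file("extdata", "example_motifs_synthetic.pfm",
                   package = "locrep")
  pfms <- read_pfm(f)
  expect_length(pfms, 2)
  expect_equal(vapply(pfms, function(p) ncol(p$counts), integer(1)),
               c(8L, 5L))
  expect_equal(pfms[[1]]$motif_id, "SYN0001.1")
})

test_that("newick trees round-trip with supports as node labels", {
  tr <- ape::read.tree(text = "((A:1,B:2)90:0.5,(C:1,D:1)75:0.4);")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(sort(back$tip.label), c("A", "B", "C", "D"))
  expect_true(all(c("90", "75") %in% back$node.label))
  # unlabelled internals also accepted
  f2 <- withr::local_tempfile()
  writeLines("((A:1,B:2):0.5,C:1);", f2)
  expect_s3_class(read_newick(f2), "phylo")
})
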