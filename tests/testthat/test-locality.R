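test_that("map_consensus finds exact, diverged and truncated copies correctly", {
  cons <- rand_dna(300, seed = 31)
  g <- plant_genome(cons, strands = "+", gap = 2000, seed = 32)
  hits <- map_consensus(g$assembly, cons)
  expect_length(hits, 1)
  expect_equal(S4Vectors::mcols(hits)$identity, 1)
  expect_equal(GenomicRanges::start(hits), g$starts)
  expect_equal(GenomicRanges::end(hits), g$ends)

  # 20% divergence: identity ~ 0.80
  set.seed(33)
  div <- mutate_copy(cons, 0.20, 0)
  a2 <- Biostrings::DNAStringSet(c(chr1 = paste0(rand_dna(2000), div,
                                                 rand_dna(2000))))
  h2 <- map_consensus(a2, cons)
  expect_length(h2, 1)
  expect_lt(abs(S4Vectors::mcols(h2)$identity - 0.80), 0.05)

  # 40% of length: below the aligned-length floor, no hit
  trunc <- substr(cons, 1, 120)
  a3 <- Biostrings::DNAStringSet(c(chr1 = paste0(rand_dna(2000), trunc,
                                                 rand_dna(2000))))
  expect_length(map_consensus(a3, cons), 0)

  # 60% of length: mapped
  trunc2 <- substr(cons, 1, 180)
  a4 <- Biostrings::DNAStringSet(c(chr1 = paste0(rand_dna(2000), trunc2,
                                                 rand_dna(2000))))
  expect_length(map_consensus(a4, cons), 1)
})

test_that("map_consensus finds minus-strand and adjacent copies", {
  cons <- rand_dna(250, seed = 35)
  set.seed(36)
  adjacent <- paste0(rand_dna(1000), cons, rand_dna(30), cons,
                     rand_dna(1000), revcomp_chr(cons), rand_dna(1000))
  hits <- map_consensus(Biostrings::DNAStringSet(c(chr1 = adjacent)), cons)
  expect_length(hits, 3)
  expect_equal(sum(GenomicRanges::strand(hits) == "-"), 1L)
})

gene_set <- function(starts, widths, ids = NULL) {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, width = widths))
  S4Vectors::mcols(g)$gene_id <-
    if (is.null(ids)) sprintf("g%d", seq_along(starts)) else ids
  S4Vectors::mcols(g)$biotype <- rep("lncRNA", length(starts))
  g
}

inst_set <- function(starts, width = 100) {
  GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, width = width))
}

test_that("classify_locality applies the 80% rule and dispersal diagnostics", {
  genes <- gene_set(1, 50000)
  lc <- classify_locality(inst_set(seq(1000, 23000, by = 2000)), genes)
  expect_equal(lc$call, "LOCAL")
  expect_equal(lc$locality_fraction, 1)
  expect_equal(lc$host_locus, "g1")

  # 8 of 10 inside; 2 outside, 60% length, 400 kb apart
  genes2 <- gene_set(1, 50000)
  inside <- inst_set(seq(1000, 15001, by = 2000), width = 100)
  outside <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100000, 500000), width = 60))
  lc2 <- classify_locality(c(inside, outside), genes2)
  expect_equal(lc2$call, "LOCAL")
  expect_equal(lc2$locality_fraction, 0.8)
  expect_true(all(lc2$outside$shorter_than_locus_median))
  expect_true(all(lc2$outside$farther_than_threshold))

  # spread over 5 genes: dispersed
  genes5 <- gene_set(seq(1, 40001, by = 10000), 5000)
  spread <- inst_set(rep(seq(1000, 31001, by = 10000), each = 2) +
                       c(0, 2000), width = 100)
  lc3 <- classify_locality(spread, genes5)
  expect_equal(lc3$call, "DISPERSED")
  expect_lte(lc3$locality_fraction, 0.3)

  expect_warning(
    lc4 <- classify_locality(inst_set(c(1, 1000)), GenomicRanges::GRanges()),
    "no loci")
  expect_equal(lc4$call, "DISPERSED")
})

test_that("burden normalizes per kb and is additive over gene sets", {
  genes <- gene_set(1, 100000, ids = "gene1")
  inst <- inst_set(seq(1000, 97001, by = 4000), width = 150)  # 25 instances
  classification <- list(
    calls = data.frame(family_id = "famA", call = "LOCAL",
                       host_locus = "gene1", locality_fraction = 1,
                       n_instances = 25L, n_inside = 25L),
    instance_maps = list(famA = inst))
  b <- compute_burden(classification, GenomicRanges::GRanges(), genes)
  expect_equal(b$n_lr, 25L)
  expect_equal(b$lr_per_kb, 0.25)   # 25 per 100 kb
  expect_equal(b$n_tr, 0L)

  # empty gene
  genes2 <- gene_set(c(1, 200001), c(100000, 50000))
  b2 <- compute_burden(classification, GenomicRanges::GRanges(), genes2)
  expect_equal(b2$n_lr, c(25L, 0L))
  expect_true(all(b2[2, c("n_lr", "n_tr")] == 0))

  # additivity: burdens of two disjoint gene sets concatenate unchanged
  b_split <- rbind(
    compute_burden(classification, GenomicRanges::GRanges(), genes2[1]),
    compute_burden(classification, GenomicRanges::GRanges(), genes2[2]))
  expect_equal(b2$lr_per_kb, b_split$lr_per_kb)
  expect_equal(b2$gene_id, b_split$gene_id)

  # family-level counting collapses instances to one
  b3 <- compute_burden(classification, GenomicRanges::GRanges(), genes,
                       count = "families")
  expect_equal(b3$n_lr, 1L)
})

test_that("each family receives exactly one locality call", {
  sim <- simulate_genome(sim_config(seed = 13))
  cons <- as.character(sim$consensi[c("R0", "D1")])
  fams <- list(
    structure(list(family_id = "R0", consensus = cons[["R0"]],
                   instances = GenomicRanges::GRanges(),
                   objective_score = 0), class = "repeat_family"),
    structure(list(family_id = "D1", consensus = cons[["D1"]],
                   instances = GenomicRanges::GRanges(),
                   objective_score = 0), class = "repeat_family"))
  cl <- classify_families(fams, sim$genes, sim$assembly)
  expect_equal(nrow(cl$calls), 2L)
  expect_equal(cl$calls$family_id, c("R0", "D1"))
  expect_equal(cl$calls$call[cl$calls$family_id == "R0"], "LOCAL")
  expect_equal(cl$calls$call[cl$calls$family_id == "D1"], "DISPERSED")
})
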