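test_that("mutate_copy respects its preconditions and the zero case", {
  expect_identical(mutate_copy("ACGTACGT", 0, 0), "ACGTACGT")
  expect_error(mutate_copy("", 0.1), "empty")
  expect_error(mutate_copy("ACGT", 0.6), "divergence")
  expect_error(mutate_copy("ACGT", 0.1, 0.6), "indel_rate")
})

test_that("mutate_copy realizes the requested substitution rate", {
  cons <- rand_dna(10000, seed = 1)
  cc <- strsplit(cons, "")[[1]]
  rates <- vapply(1:50, function(i) {
    set.seed(i)
    m <- mutate_copy(cons, 0.10, 0)
    mean(strsplit(m, "")[[1]] != cc)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.10), 0.01)
})

test_that("simulated genomes are deterministic with consistent truth", {
  sim1 <- simulate_genome(sim_config(seed = 11))
  sim2 <- simulate_genome(sim_config(seed = 11))
  expect_identical(as.character(sim1$assembly), as.character(sim2$assembly))
  expect_identical(sim1$truth, sim2$truth)

  tr <- sim1$truth
  G <- sum(Biostrings::width(sim1$assembly))
  expect_true(all(tr$start >= 1 & tr$end <= G))
  # no planted element overlaps another planted element
  ir <- IRanges::IRanges(tr$start, tr$end)
  expect_equal(max(IRanges::countOverlaps(ir, ir)), 1L)
})

test_that("locality_fraction 1 places every copy inside the host locus", {
  sim <- simulate_genome(sim_config(seed = 3))
  fam <- sim$config$families
  full <- fam$family_id[fam$host == "local" & fam$locality == 1]
  tt <- sim$truth[sim$truth$kind == "family" & sim$truth$family_id %in% full, ]
  expect_true(all(tt$inside_host))
})

test_that("planted instance identity is reproducible from the genome", {
  sim <- simulate_genome(sim_config(seed = 5))
  tt <- sim$truth[sim$truth$kind == "family", ]
  tt <- tt[sample.int(nrow(tt), 10), ]  # spot check
  for (i in seq_len(nrow(tt))) {
    s <- as.character(Biostrings::subseq(sim$assembly[[tt$chrom[i]]],
                                         tt$start[i], tt$end[i]))
    if (tt$strand[i] == "-") s <- revcomp_chr(s)
    cons <- as.character(sim$consensi[[tt$family_id[i]]])
    pa <- Biostrings::pairwiseAlignment(
      s, cons, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        1, -1, baseOnly = TRUE),
      gapOpening = 4, gapExtension = 1)
    expect_lt(abs(Biostrings::pid(pa, "PID1") / 100 - tt$identity[i]), 0.01)
  }
})

test_that("preset medians match the intended study conditions", {
  cfg <- sim_config(seed = 1)
  loc <- cfg$families[cfg$families$host == "local", ]
  expect_equal(stats::median(loc$length), 167)
  expect_equal(stats::median(loc$copies), 12)
  expect_true(all(loc$length >= 100 & loc$length <= 750))
  expect_true(all(loc$copies >= 3 & loc$copies <= 40))
  expect_true(all(loc$divergence <= 0.10))
  sim <- simulate_genome(cfg)
  tt <- sim$truth[sim$truth$kind == "family", ]
  n_by_fam <- table(tt$family_id)[loc$family_id]
  expect_equal(unname(stats::median(as.integer(n_by_fam))), 12)
})

test_that("Jukes-Cantor ortholog simulation matches the closed form", {
  # zero branch lengths: identical leaves
  tr0 <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  root <- rand_dna(2000, seed = 1)
  seqs <- simulate_ortholog_set(tr0, root, seed = 2)
  expect_true(all(seqs == root))

  # two leaves at b = 0.1 each: identity ~ 1 - 3/4 (1 - exp(-4*0.2/3))
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  root <- rand_dna(10000, seed = 3)
  seqs <- simulate_ortholog_set(tr, root, seed = 4)
  obs <- mean(strsplit(seqs[["a"]], "")[[1]] == strsplit(seqs[["b"]], "")[[1]])
  expected <- 1 - 0.75 * (1 - exp(-4 * 0.2 / 3))
  expect_lt(abs(obs - expected), 0.03)

  expect_error(
    simulate_ortholog_set(ape::read.tree(text = "(a:-0.1,b:0.1);"), "ACGT"),
    "non-negative")
})

test_that("two-clade ortholog sets hit the identity targets", {
  tc <- simulate_two_clade_orthologs(n_per_clade = 5, seq_len = 5000,
                                     within_identity = 0.90,
                                     cross_identity = 0.60, seed = 6)
  pid <- pairwise_identity(dna_msa(tc$sequences))
  w <- c(pid[tc$clades$A, tc$clades$A][upper.tri(diag(5))],
         pid[tc$clades$B, tc$clades$B][upper.tri(diag(5))])
  x <- pid[tc$clades$A, tc$clades$B]
  expect_lt(abs(stats::median(w) - 0.90), 0.03)
  expect_lt(abs(stats::median(x) - 0.60), 0.03)
})

test_that("simulated gene burdens realize the per-100kb targets", {
  b <- simulate_gene_burdens(n_per_class = 200, seed = 9)
  lnc <- b[b$biotype == "lncRNA", ]
  mr <- b[b$biotype == "mRNA", ]
  lnc_rate <- sum(lnc$n_lr) / sum(lnc$length) * 1e5
  mr_rate <- sum(mr$n_lr) / sum(mr$length) * 1e5
  expect_lt(abs(lnc_rate - 25) / 25, 0.2)
  expect_lt(abs(mr_rate - 6) / 6, 0.2)
})

test_that("written simulation artifacts are byte-identical across runs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_genome(sim_config(seed = 21)), d1)
  write_simulation(simulate_genome(sim_config(seed = 21)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})
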