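# Shared fixtures and independent oracles, built in code at test time.

rand_dna <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# genome with planted exact copies (both strands) of one consensus
plant_genome <- function(consensus, strands = c("+", "-", "+"),
                         gap = 1000L, seed = 99L) {
  set.seed(seed)
  parts <- rand_dna(gap)
  starts <- integer(length(strands))
  for (i in seq_along(strands)) {
    s <- if (strands[i] == "-") revcomp_chr(consensus) else consensus
    starts[i] <- nchar(parts) + 1L
    parts <- paste0(parts, s, rand_dna(gap))
  }
  list(assembly = Biostrings::DNAStringSet(c(chr1 = parts)),
       starts = starts,
       ends = starts + nchar(consensus) - 1L,
       strands = strands)
}

make_pfm <- function(counts, id = "m1", background = rep(0.25, 4)) {
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(motif_id = id, counts = counts, background = background),
            class = "pfm")
}

# consensus-only PFM: count `n` on one base per column
consensus_pfm <- function(word, n = 100, id = "cons") {
  idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  cnt <- matrix(0, 4, length(idx))
  cnt[cbind(idx, seq_along(idx))] <- n
  make_pfm(cnt, id = id)
}

# brute-force motif oracle: score of every length-W word plus tail p-values
motif_brute_force <- function(pfm, pseudocount = 0.8) {
  S <- pfm_logodds(pfm, pseudocount)
  W <- ncol(S)
  words <- as.matrix(expand.grid(rep(list(1:4), W)))
  sc <- numeric(nrow(words))
  for (j in seq_len(W)) sc <- sc + S[cbind(words[, j], j)]
  wp <- apply(words, 1, function(w) prod(pfm$background[w]))
  list(scores = sc, probs = wp,
       pval = function(s) sum(wp[sc >= s - 1e-9]))
}

# exhaustive NJ oracle: best topology among all unrooted trees on the taxa,
# by least-squares branch fitting (phangorn::nnls.tree)
best_topology_lsq <- function(dm) {
  labs <- rownames(dm)
  all_t <- phangorn::allTrees(length(labs), rooted = FALSE,
                              tip.label = labs)
  ssq <- vapply(all_t, function(t) {
    ft <- phangorn::nnls.tree(dm, t, method = "unrooted")
    d2 <- as.matrix(stats::cophenetic(ft))[labs, labs]
    sum((d2 - dm)^2)
  }, numeric(1))
  all_t[[which.min(ssq)]]
}

# weighted alignments from chip_records (adds the AS-equivalent score)
wa_from_records <- function(rec, assembly, cap = 20L) {
  weighted_alignments(
    data.frame(read_id = rec$read_id, chrom = rec$chrom, pos = rec$pos,
               width = rec$width, strand = rec$strand,
               score = rec$width - rec$mismatches),
    cap = cap,
    seqlengths = stats::setNames(Biostrings::width(assembly),
                                 names(assembly)))
}
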