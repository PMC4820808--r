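# Synthetic genomes with planted local repeats, tandem arrays, TEs, reads and
# ortholog sets. Every simulated artifact is emitted together with its ground
# truth so downstream stages can be validated against what was planted.

#' Mutate a repeat copy away from its consensus
#'
#' Applies independent per-base substitutions (to a uniformly chosen different
#' base) at rate `divergence`, and single-base insertions and deletions each at
#' rate `indel_rate`. Uses the current RNG stream; call `set.seed()` first for
#' reproducibility.
#'
#' @param consensus Nucleotide string (A/C/G/T).
#' @param divergence Expected per-base substitution fraction, in `[0, 0.5)`.
#' @param indel_rate Per-base rate of 1-bp insertions and of deletions, in
#'   `[0, 0.5)`.
#' @return The mutated nucleotide string.
#' @export
mutate_copy <- function(consensus, divergence, indel_rate = 0) {
  if (!nzchar(consensus)) stop("empty consensus", call. = FALSE)
  if (divergence < 0 || divergence >= 0.5)
    stop("divergence must be in [0, 0.5)", call. = FALSE)
  if (indel_rate < 0 || indel_rate >= 0.5)
    stop("indel_rate must be in [0, 0.5)", call. = FALSE)
  b <- .chars(consensus)
  n <- length(b)
  bases <- c("A", "C", "G", "T")
  sub_at <- which(stats::runif(n) < divergence)
  if (length(sub_at)) {
    # shift by 1..3 positions in the base alphabet: always a different base
    cur <- match(b[sub_at], bases)
    b[sub_at] <- bases[((cur - 1L + sample(1:3, length(sub_at), TRUE)) %% 4L) + 1L]
  }
  if (indel_rate > 0) {
    del_at <- stats::runif(n) < indel_rate
    ins_at <- which(stats::runif(n) < indel_rate)
    pre <- character(n)
    if (length(ins_at)) pre[ins_at] <- sample(bases, length(ins_at), TRUE)
    b[del_at] <- ""
    b <- paste0(pre, b)
  }
  paste(b, collapse = "")
}

#' Simulation configuration
#'
#' Assembles (and range-checks) the parameters driving [simulate_genome()].
#' `preset = "firre_like"` returns the default study conditions: a 500 kb
#' chromosome carrying 13 local-repeat families (lengths 100-750 bp, median
#' 167 bp; 3-40 copies, median 12; divergence up to 10%), 2 dispersed
#' families, 5 tandem arrays, 20 interspersed TE copies, 13 lncRNA-like host
#' genes and 15 mRNA-like genes.
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param preset `"firre_like"` or `NULL` for a fully manual configuration.
#' @param ... Overrides for any configuration field (see Details in the
#'   package vignette).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, preset = c("firre_like", "none"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = as.integer(seed),
    chrom = "chrX",
    genome_length = 500000L,
    gc_content = 0.45,
    families = NULL,
    tandems = NULL,
    te_library = NULL,
    n_te_copies = 20L,
    te_divergence = 0.08,
    genes = list(n_mrna = 15L, mrna_len = c(5000L, 15000L)),
    outside_trunc_frac = 0.6,
    outside_min_sep = 250000L
  )
  if (preset == "firre_like") {
    len <- c(100L, 110L, 120L, 140L, 150L, 160L, 167L,
             180L, 220L, 300L, 400L, 550L, 750L)
    cop <- c(40L, 32L, 25L, 20L, 16L, 14L, 12L, 11L, 9L, 7L, 5L, 4L, 3L)
    cfg$families <- data.frame(
      family_id = sprintf("R%d", seq_along(len) - 1L),
      length = len, copies = cop,
      divergence = round(seq(0.02, 0.10, length.out = length(len)), 3),
      indel_rate = 0,
      locality = c(0.9, 1, 0.9, 0.9, 0.9, 1, 1, 0.9, 1, 1, 1, 1, 1),
      host = "local",
      stringsAsFactors = FALSE)
    disp <- data.frame(
      family_id = c("D1", "D2"), length = c(150L, 200L), copies = c(8L, 6L),
      divergence = 0.05, indel_rate = 0, locality = 0, host = "dispersed",
      stringsAsFactors = FALSE)
    cfg$families <- rbind(cfg$families, disp)
    cfg$tandems <- data.frame(
      tandem_id = sprintf("TA%d", 1:5),
      period = c(4L, 10L, 24L, 60L, 120L),
      copies = c(30L, 20L, 10L, 6L, 5L),
      purity = c(1, 0.96, 0.96, 0.92, 0.92))
    cfg$te_library <- c(TE1 = 300L, TE2 = 250L, TE3 = 180L)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(over)] <- over
  stopifnot(cfg$gc_content >= 0, cfg$gc_content <= 1,
            is.null(cfg$families) ||
              all(cfg$families$divergence < 0.5 & cfg$families$copies >= 2))
  structure(cfg, class = "sim_config")
}

# Place `widths` non-overlapping intervals uniformly inside [lo, hi] (1-based,
# inclusive), avoiding `occupied` (an IRanges), with optional minimum
# separation between the placed intervals themselves.
.place_intervals <- function(widths, lo, hi, occupied, min_sep = 0L,
                             retries = 2000L, what = "element") {
  placed <- IRanges::IRanges()
  starts <- integer(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    ok <- FALSE
    for (try in seq_len(retries)) {
      if (hi - w + 1L < lo) break
      s <- sample.int(hi - w + 1L - lo + 1L, 1L) + lo - 1L
      cand <- IRanges::IRanges(s, s + w - 1L)
      if (length(occupied) && length(IRanges::findOverlaps(cand, occupied)) > 0) next
      if (min_sep > 0 && length(placed) &&
          min(abs(IRanges::start(placed) - s)) < min_sep) next
      ok <- TRUE
      starts[i] <- s
      placed <- c(placed, cand)
      occupied <- c(occupied, cand)
      break
    }
    if (!ok) stop("could not place ", what, " of width ", w,
                  " without overlap after ", retries, " retries", call. = FALSE)
  }
  starts
}

.identity_to_consensus <- function(copy, consensus) {
  pa <- Biostrings::pairwiseAlignment(copy, consensus,
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1, type = "global")
  Biostrings::pid(pa, type = "PID1") / 100
}

#' Simulate a genome with planted repeat families
#'
#' Generates an i.i.d. background sequence at the configured GC content and
#' plants, without mutual overlap: interspersed TE copies, tandem arrays, and
#' the configured repeat families. For a family with `host = "local"`,
#' `ceiling(locality * copies)` copies are placed inside its own lncRNA-like
#' host gene; remaining copies are truncated to `outside_trunc_frac` of the
#' consensus and scattered in intergenic space, kept at least
#' `outside_min_sep` apart when the genome length permits (otherwise the
#' separation is relaxed to what fits). Dispersed families are placed
#' genome-wide. Copies are mutated by [mutate_copy()] and planted on a random
#' strand. mRNA-like genes carry no planted repeats.
#'
#' @param config A [sim_config()].
#' @return A `lr_simulation` list: `assembly` (DNAStringSet), `genes`,
#'   `te`, `tandem` (GRanges), `truth` (per-instance data.frame with realized
#'   identity to consensus), `consensi` (DNAStringSet), `gene_truth`
#'   (per-gene true LR/TR counts) and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$genome_length
  fam <- config$families
  bases <- c("A", "C", "G", "T")

  # family and TE consensi
  consensi <- character(0)
  if (!is.null(fam))
    consensi <- stats::setNames(
      vapply(fam$length, .random_dna, "", gc = 0.5), fam$family_id)
  te_lib <- character(0)
  if (!is.null(config$te_library))
    te_lib <- stats::setNames(
      vapply(config$te_library, .random_dna, "", gc = 0.5),
      names(config$te_library))

  # host genes sized to hold their copies with room to spare
  genes <- data.frame(gene_id = character(0), biotype = character(0),
                      length = integer(0), family_id = character(0))
  if (!is.null(fam)) {
    loc <- fam[fam$host == "local", , drop = FALSE]
    if (nrow(loc))
      genes <- rbind(genes, data.frame(
        gene_id = paste0("lnc_", loc$family_id), biotype = "lncRNA",
        length = as.integer(ceiling(1.3 * loc$copies * (loc$length + 200))),
        family_id = loc$family_id))
  }
  gm <- config$genes
  if (gm$n_mrna > 0)
    genes <- rbind(genes, data.frame(
      gene_id = sprintf("mrna_%02d", seq_len(gm$n_mrna)), biotype = "mRNA",
      length = as.integer(round(stats::runif(gm$n_mrna, gm$mrna_len[1],
                                             gm$mrna_len[2]))),
      family_id = NA_character_))
  if (sum(genes$length) > 0.75 * G)
    stop("gene models exceed 75% of the genome; enlarge genome_length",
         call. = FALSE)

  # lay genes out left to right with random intergenic gaps
  genes <- genes[sample.int(nrow(genes)), , drop = FALSE]
  free <- G - sum(genes$length)
  gaps <- stats::rexp(nrow(genes) + 1L)
  gaps <- floor(free * gaps / sum(gaps))
  gene_start <- cumsum(c(1L, genes$length[-nrow(genes)])) +
    cumsum(gaps[-length(gaps)])
  genes$start <- as.integer(gene_start)
  genes$end <- genes$start + genes$length - 1L

  gene_ir <- IRanges::IRanges(genes$start, genes$end)
  occupied <- IRanges::IRanges()          # planted sequence elements
  truth <- list()

  add_truth <- function(kind, id, start, end, strand, identity, inside_host) {
    truth[[length(truth) + 1L]] <<- data.frame(
      kind = kind, family_id = id, chrom = config$chrom,
      start = start, end = end, strand = strand,
      identity = identity, inside_host = inside_host)
  }

  plant <- list()  # sequences to write: list(start, seq)
  add_plant <- function(start, seq) {
    plant[[length(plant) + 1L]] <<- list(start = start, seq = seq)
    occupied <<- c(occupied, IRanges::IRanges(start, start + nchar(seq) - 1L))
  }

  intergenic_place <- function(widths, min_sep = 0L, what = "element",
                               avoid_genes = TRUE) {
    occ <- if (avoid_genes) c(occupied, gene_ir) else occupied
    # relax the separation constraint stepwise if the genome cannot honour it
    for (sep in unique(c(min_sep, min_sep %/% 2L, min_sep %/% 4L, 0L))) {
      st <- tryCatch(
        .place_intervals(widths, 1L, G, occ, min_sep = sep, what = what),
        error = function(e) NULL)
      if (!is.null(st)) {
        if (sep < min_sep)
          message("relaxed min separation for ", what, " to ", sep, " bp")
        return(st)
      }
    }
    stop("could not place ", what, " even without separation constraint",
         call. = FALSE)
  }

  # tandem arrays (intergenic)
  tnd <- config$tandems
  tandem_rows <- NULL
  if (!is.null(tnd) && nrow(tnd)) {
    arr_seq <- character(nrow(tnd))
    for (i in seq_len(nrow(tnd))) {
      motif <- .random_dna(tnd$period[i], gc = 0.5)
      arr <- strrep(motif, tnd$copies[i])
      s_rate <- (1 - tnd$purity[i]) / 2
      if (s_rate > 0) arr <- mutate_copy(arr, s_rate, 0)
      arr_seq[i] <- arr
    }
    st <- intergenic_place(nchar(arr_seq), what = "tandem array")
    for (i in seq_len(nrow(tnd))) {
      add_plant(st[i], arr_seq[i])
      add_truth("tandem", tnd$tandem_id[i], st[i],
                st[i] + nchar(arr_seq[i]) - 1L, "+", tnd$purity[i], FALSE)
    }
    tandem_rows <- cbind(tnd, start = st, end = st + nchar(arr_seq) - 1L)
  }

  # TE copies (intergenic)
  if (length(te_lib) && config$n_te_copies > 0) {
    pick <- sample(names(te_lib), config$n_te_copies, replace = TRUE)
    seqs <- vapply(pick, function(nm)
      mutate_copy(te_lib[[nm]], config$te_divergence, 0.002), "")
    strands <- sample(c("+", "-"), length(seqs), TRUE)
    st <- intergenic_place(nchar(seqs), what = "TE copy")
    for (i in seq_along(seqs)) {
      s <- if (strands[i] == "-") .revcomp(seqs[i]) else seqs[i]
      add_plant(st[i], s)
      add_truth("te", pick[i], st[i], st[i] + nchar(s) - 1L, strands[i],
                NA_real_, FALSE)
    }
  }

  # repeat-family copies
  if (!is.null(fam)) for (i in seq_len(nrow(fam))) {
    fid <- fam$family_id[i]
    cons <- consensi[[fid]]
    n_in <- if (fam$host[i] == "local")
      as.integer(ceiling(fam$locality[i] * fam$copies[i])) else 0L
    n_out <- fam$copies[i] - n_in

    make_copy <- function(truncate = FALSE) {
      src <- cons
      if (truncate) {
        w <- as.integer(round(config$outside_trunc_frac * nchar(cons)))
        off <- sample.int(nchar(cons) - w + 1L, 1L)
        src <- substr(cons, off, off + w - 1L)
      }
      mutate_copy(src, fam$divergence[i], fam$indel_rate[i])
    }

    if (n_in > 0) {
      g <- genes[!is.na(genes$family_id) & genes$family_id == fid, ]
      seqs <- vapply(seq_len(n_in), function(j) make_copy(FALSE), "")
      strands <- sample(c("+", "-"), n_in, TRUE)
      occ_in <- IRanges::restrict(occupied, g$start, g$end)
      st <- .place_intervals(nchar(seqs), g$start, g$end, occ_in,
                             what = paste0("copy of ", fid))
      for (j in seq_len(n_in)) {
        s <- if (strands[j] == "-") .revcomp(seqs[j]) else seqs[j]
        add_plant(st[j], s)
        add_truth("family", fid, st[j], st[j] + nchar(s) - 1L, strands[j],
                  .identity_to_consensus(seqs[j], cons), TRUE)
      }
    }
    if (n_out > 0) {
      truncate <- fam$host[i] == "local"
      seqs <- vapply(seq_len(n_out), function(j) make_copy(truncate), "")
      strands <- sample(c("+", "-"), n_out, TRUE)
      dispersed <- fam$host[i] == "dispersed"
      sep <- if (dispersed) 0L
             else min(config$outside_min_sep, (G %/% (n_out + 1L)))
      st <- intergenic_place(nchar(seqs), min_sep = sep,
                             what = paste0("outside copy of ", fid),
                             avoid_genes = !dispersed)
      for (j in seq_len(n_out)) {
        s <- if (strands[j] == "-") .revcomp(seqs[j]) else seqs[j]
        add_plant(st[j], s)
        add_truth("family", fid, st[j], st[j] + nchar(s) - 1L, strands[j],
                  .identity_to_consensus(seqs[j], cons), FALSE)
      }
    }
  }

  # assemble the chromosome
  chrom <- .chars(.random_dna(G, config$gc_content))
  for (p in plant)
    chrom[p$start:(p$start + nchar(p$seq) - 1L)] <- .chars(p$seq)
  assembly <- Biostrings::DNAStringSet(stats::setNames(
    paste(chrom, collapse = ""), config$chrom))

  truth <- do.call(rbind, truth)
  genes_gr <- .gr(config$chrom, genes$start, genes$end, assembly = assembly)
  S4Vectors::mcols(genes_gr)$gene_id <- genes$gene_id
  S4Vectors::mcols(genes_gr)$biotype <- genes$biotype
  S4Vectors::mcols(genes_gr)$name <- genes$gene_id

  te_tab <- truth[truth$kind == "te", , drop = FALSE]
  te_gr <- .gr(te_tab$chrom, te_tab$start, te_tab$end, te_tab$strand,
               assembly = assembly)
  S4Vectors::mcols(te_gr)$name <- te_tab$family_id

  tandem_gr <- GenomicRanges::GRanges()
  if (!is.null(tandem_rows)) {
    tandem_gr <- .gr(config$chrom, tandem_rows$start, tandem_rows$end,
                     assembly = assembly)
    S4Vectors::mcols(tandem_gr) <- tandem_rows[c("tandem_id", "period",
                                                 "copies", "purity")]
  }

  # per-gene truth: LR instances inside each gene; TR arrays overlapping it
  fam_tab <- truth[truth$kind == "family", , drop = FALSE]
  gene_truth <- data.frame(gene_id = genes$gene_id, biotype = genes$biotype,
                           length = genes$length, n_lr = 0L, n_tr = 0L)
  if (nrow(fam_tab)) {
    inst_ir <- IRanges::IRanges(fam_tab$start, fam_tab$end)
    ov <- IRanges::findOverlaps(inst_ir, gene_ir, type = "within")
    cnt <- table(factor(S4Vectors::subjectHits(ov), levels = seq_len(nrow(genes))))
    gene_truth$n_lr <- as.integer(cnt)
  }
  if (length(tandem_gr)) {
    ov <- IRanges::findOverlaps(IRanges::ranges(tandem_gr), gene_ir)
    cnt <- table(factor(S4Vectors::subjectHits(ov), levels = seq_len(nrow(genes))))
    gene_truth$n_tr <- as.integer(cnt)
  }

  structure(list(
    assembly = assembly, genes = genes_gr, te = te_gr, tandem = tandem_gr,
    truth = truth, gene_truth = gene_truth,
    consensi = Biostrings::DNAStringSet(consensi),
    te_library = Biostrings::DNAStringSet(te_lib),
    config = config), class = "lr_simulation")
}

#' @export
print.lr_simulation <- function(x, ...) {
  fam <- x$truth[x$truth$kind == "family", , drop = FALSE]
  cat("lr_simulation:", sum(Biostrings::width(x$assembly)), "bp genome,",
      length(x$consensi), "planted families (",
      nrow(fam), "instances ),", length(x$tandem), "tandem arrays,",
      length(x$te), "TE copies,", length(x$genes), "genes\n")
  invisible(x)
}

#' Write the simulated artifacts to disk
#'
#' Emits `genome.fa`, `genes.bed`, `te.bed`, `tandem.bed`, `consensi.fa` and
#' `truth.tsv` under `dir`. Identical simulations produce byte-identical
#' files.
#'
#' @param sim An `lr_simulation`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "lr_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$assembly, file.path(dir, "genome.fa"))
  write_fasta(sim$consensi, file.path(dir, "consensi.fa"))
  write_bed(sim$genes, file.path(dir, "genes.bed"))
  write_bed(sim$te, file.path(dir, "te.bed"))
  if (length(sim$tandem)) {
    tg <- sim$tandem
    S4Vectors::mcols(tg)$name <- S4Vectors::mcols(tg)$tandem_id
    write_bed(tg, file.path(dir, "tandem.bed"))
  }
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Evolve a root sequence down a phylogeny under Jukes-Cantor
#'
#' Each branch of expected length `b` substitutions/site changes every site
#' independently with probability `p = 3/4 (1 - exp(-4 b / 3))`, to a
#' uniformly chosen different base.
#'
#' @param tree An ape `phylo`, or a newick string / file path.
#' @param root_sequence Nucleotide string at the root.
#' @param seed Integer seed.
#' @return Named character vector of leaf sequences.
#' @export
simulate_ortholog_set <- function(tree, root_sequence, seed = 1L) {
  if (is.character(tree))
    tree <- if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("tree leaves must be uniquely labelled", call. = FALSE)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths", call. = FALSE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- .chars(root_sequence)
  # parents precede children in a preorder edge walk
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    b <- ord$edge.length[e]
    p <- 0.75 * (1 - exp(-4 * b / 3))
    s <- seqs[[par]]
    hit <- which(stats::runif(length(s)) < p)
    if (length(hit)) {
      cur <- match(s[hit], bases)
      s[hit] <- bases[((cur - 1L + sample(1:3, length(hit), TRUE)) %% 4L) + 1L]
    }
    seqs[[child]] <- s
  }
  stats::setNames(
    vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""), ""),
    tree$tip.label)
}

# Inverse Jukes-Cantor: total path length giving an expected identity.
.jc_path_for_identity <- function(identity) {
  p <- 1 - identity
  -0.75 * log(1 - 4 * p / 3)
}

#' Simulate a two-clade ortholog set
#'
#' Builds a two-clade tree (for example rodents vs primates) whose branch
#' lengths are chosen by inverse Jukes-Cantor so that expected pairwise
#' identity is `within_identity` inside each clade and `cross_identity`
#' across clades, then evolves a random root sequence down it.
#'
#' @param n_per_clade Leaves per clade.
#' @param seq_len Root sequence length (bp).
#' @param within_identity,cross_identity Target expected pairwise identities.
#' @param seed Integer seed.
#' @return List with `sequences` (named character), `tree` (phylo), and
#'   `clades` (named list of leaf labels).
#' @export
simulate_two_clade_orthologs <- function(n_per_clade = 5L, seq_len = 2000L,
                                         within_identity = 0.90,
                                         cross_identity = 0.60, seed = 1L) {
  stopifnot(n_per_clade >= 2, cross_identity < within_identity)
  t_within <- .jc_path_for_identity(within_identity)
  t_cross <- .jc_path_for_identity(cross_identity)
  d <- t_within / 2                      # leaf depth below clade root
  s <- (t_cross - t_within) / 2          # clade-root stem
  lab_a <- sprintf("cladeA_%d", seq_len(n_per_clade))
  lab_b <- sprintf("cladeB_%d", seq_len(n_per_clade))
  clade <- function(labs) paste0("(", paste0(labs, ":", d, collapse = ","), ")")
  nwk <- paste0("(", clade(lab_a), ":", s, ",", clade(lab_b), ":", s, ");")
  tree <- ape::read.tree(text = nwk)
  set.seed(seed)
  root <- .random_dna(seq_len, gc = 0.5)
  seqs <- simulate_ortholog_set(tree, root, seed = seed + 1L)
  list(sequences = seqs, tree = tree, clades = list(A = lab_a, B = lab_b))
}

#' Simulate per-gene repeat burdens for two gene classes
#'
#' Draws gene lengths from a shared log-normal distribution and LR/TR counts
#' from Poisson distributions at the configured per-100-kb rates, mirroring
#' the contrast between lncRNA-like and mRNA-like loci.
#'
#' @param n_per_class Genes per class.
#' @param lr_per_100kb Named (lncRNA, mRNA) LR rates per 100 kb.
#' @param tr_per_100kb Named TR rates per 100 kb (equal by default).
#' @param len_meanlog,len_sdlog Log-normal gene-length parameters (bp).
#' @param seed Integer seed.
#' @return Data frame with `gene_id`, `biotype`, `length`, `n_lr`, `n_tr`,
#'   `lr_per_kb`, `tr_per_kb`.
#' @export
simulate_gene_burdens <- function(n_per_class = 200L,
                                  lr_per_100kb = c(lncRNA = 25, mRNA = 6),
                                  tr_per_100kb = c(lncRNA = 10, mRNA = 10),
                                  len_meanlog = log(3e4), len_sdlog = 0.6,
                                  seed = 1L) {
  set.seed(seed)
  cls <- c("lncRNA", "mRNA")
  out <- do.call(rbind, lapply(cls, function(b) {
    len <- pmax(1000, round(stats::rlnorm(n_per_class, len_meanlog, len_sdlog)))
    data.frame(
      gene_id = sprintf("%s_%03d", b, seq_len(n_per_class)), biotype = b,
      length = len,
      n_lr = stats::rpois(n_per_class, lr_per_100kb[[b]] * len / 1e5),
      n_tr = stats::rpois(n_per_class, tr_per_100kb[[b]] * len / 1e5))
  }))
  out$lr_per_kb <- out$n_lr / (out$length / 1000)
  out$tr_per_kb <- out$n_tr / (out$length / 1000)
  out
}
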