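# Simulation of ChIP and input libraries over a genome with a bound repeat
# family. Alignment records are produced by direct string placement: a read is
# reported at every candidate position (the corresponding offset in every
# family copy) whose sequence is within one mismatch of the read, so reads
# from near-identical copies come out multi-mapped.

#' Simulate ChIP (or input) alignments over a repeat family
#'
#' Read start positions are uniform over the genome except for a
#' `fold`-enrichment multiplier over the `instances` of the bound family.
#' Each read is emitted as one alignment record per genomic position within
#' one mismatch of the read among the corresponding offsets of all family
#' copies (plus its true origin); the record count is carried as the
#' `n_reported` field (SAM tag `NH`), the alignment score (read length minus
#' mismatches) as `AS`.
#'
#' @param assembly `DNAStringSet` genome.
#' @param instances `GRanges` of the bound family's copies (strand-aware).
#' @param n_reads Total reads to draw.
#' @param fold Enrichment multiplier over the family (1 = input-like).
#' @param read_length Read length in bp.
#' @param seed Integer seed.
#' @return A data.frame of alignment records (`read_id`, `chrom`, `pos`,
#'   `strand`, `width`, `n_reported`, `mismatches`, `seq`), class
#'   `chip_records`.
#' @export
simulate_chip_reads <- function(assembly, instances, n_reads, fold = 1,
                                read_length = 36L, seed = 1L) {
  .stopifnot_assembly(assembly)
  stopifnot(fold >= 0, n_reads >= 1)
  rl <- as.integer(read_length)
  set.seed(seed)
  chrom <- names(assembly)[1]
  if (length(assembly) > 1L)
    warning("only the first sequence of the assembly is used", call. = FALSE)
  G <- Biostrings::width(assembly)[1]
  geno <- as.character(assembly[[1]])

  inst <- instances[as.character(GenomeInfoDb::seqnames(instances)) == chrom]
  ni <- length(inst)
  ist <- GenomicRanges::start(inst); ien <- GenomicRanges::end(inst)
  ilen <- ien - ist + 1L
  istr <- as.character(GenomicRanges::strand(inst))
  istr[istr == "*"] <- "+"
  if (length(unique(ilen)) > 1L)
    stop("family instances must be length-matched (indel-free family model)",
         call. = FALSE)
  L <- ilen[1]
  placeable <- pmax(L - rl + 1L, 0L)
  if (L < rl)
    warning("read length exceeds the repeat instances; no family reads",
            call. = FALSE)

  # background stratum excludes start positions whose read touches the family
  blocked <- logical(G - rl + 1L)
  for (i in seq_len(ni))
    blocked[max(ist[i] - rl + 1L, 1L):min(ien[i], G - rl + 1L)] <- TRUE
  bg_starts <- which(!blocked)
  fam_mass <- fold * ni * placeable
  bg_mass <- length(bg_starts)
  p_fam <- if (fam_mass + bg_mass > 0) fam_mass / (fam_mass + bg_mass) else 0
  from_fam <- stats::runif(n_reads) < p_fam & placeable > 0
  n_fam <- sum(from_fam); n_bg <- n_reads - n_fam

  rid_all <- sprintf("read_%06d", seq_len(n_reads))
  out_bg <- NULL
  if (n_bg > 0) {
    pos <- bg_starts[sample.int(bg_mass, n_bg, replace = TRUE)]
    out_bg <- data.frame(read_id = rid_all[!from_fam], chrom = chrom,
                         pos = pos, strand = "+", width = rl,
                         n_reported = 1L, mismatches = 0L)
  }
  out_fam <- NULL
  if (n_fam > 0) {
    # oriented copy sequences share the consensus coordinate frame
    copy_seq <- vapply(seq_len(ni), function(i)
      .extract_seq(assembly, chrom, ist[i], ien[i], istr[i]), "")
    copy_chars <- do.call(rbind, strsplit(copy_seq, "", fixed = TRUE))
    # per-pair mismatch profile over consensus offsets (0-based)
    mmprof <- array(0L, dim = c(ni, ni, placeable))
    for (i in seq_len(ni)) for (j in seq_len(ni)) if (i < j) {
      cs <- cumsum(c(0L, as.integer(copy_chars[i, ] != copy_chars[j, ])))
      v <- cs[(rl + 1L):(L + 1L)] - cs[1:placeable]
      mmprof[i, j, ] <- v; mmprof[j, i, ] <- v
    }
    org <- sample.int(ni, n_fam, replace = TRUE)
    off <- sample.int(placeable, n_fam, replace = TRUE) - 1L  # consensus frame
    rid_fam <- rid_all[from_fam]
    rec_list <- vector("list", ni)
    for (j in seq_len(ni)) {
      mm <- mmprof[cbind(org, j, off + 1L)]
      hit <- which(mm <= 1L)
      if (!length(hit)) next
      pj <- if (istr[j] == "+") ist[j] + off[hit]
            else ist[j] + (L - rl - off[hit])
      rec_list[[j]] <- data.frame(
        read_id = rid_fam[hit], chrom = chrom, pos = pj,
        strand = ifelse(istr[j] == istr[org[hit]], "+", "-"),
        width = rl, n_reported = 0L, mismatches = mm[hit])
    }
    out_fam <- do.call(rbind, rec_list)
    nrep <- table(out_fam$read_id)
    out_fam$n_reported <- as.integer(nrep[out_fam$read_id])
  }
  out <- rbind(out_bg, out_fam)
  out <- out[order(out$read_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out$seq <- substring(geno, out$pos, out$pos + rl - 1L)
  neg <- out$strand == "-"
  if (any(neg)) out$seq[neg] <- .revcomp(out$seq[neg])
  class(out) <- c("chip_records", "data.frame")
  out
}

#' Write alignment records as SAM
#'
#' Minimal single-end SAM: `@HD`/`@SQ` header, flag 0/16 (strand) with 0x100
#' added on non-primary records of a multi-mapped read, CIGAR `<width>M`, and
#' tags `NH:i` (reported locations) and `AS:i` (width minus mismatches).
#'
#' @param records A `chip_records` data.frame (see [simulate_chip_reads()]).
#' @param seqlengths Named integer vector of reference lengths.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, seqlengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(seqlengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, seqlengths[[nm]]), con)
  first <- !duplicated(records$read_id)
  flag <- ifelse(records$strand == "-", 16L, 0L) + ifelse(first, 0L, 256L)
  qual <- strrep("I", records$width)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d\tAS:i:%d",
                   records$read_id, flag, records$chrom, records$pos,
                   ifelse(records$n_reported > 1L, 0L, 60L), records$width,
                   records$seq, qual, records$n_reported,
                   records$width - records$mismatches)
  writeLines(lines, con)
  invisible(path)
}

#' Simulate a complete ChIP experiment on a small dedicated genome
#'
#' Builds a genome with one planted low-divergence repeat family (the bound
#' family), then draws a ChIP library at the requested fold enrichment over
#' its copies and a matched uniform input library. Depth is expressed as mean
#' read depth over the family in the ChIP library.
#'
#' @param genome_length Genome size in bp.
#' @param n_copies,copy_length Family copy number and consensus length.
#' @param divergence Per-base substitution rate of the copies (kept low so
#'   that reads genuinely multi-map).
#' @param fold ChIP fold enrichment over the family.
#' @param depth Target mean ChIP read depth over family bases.
#' @param read_length Read length (bp).
#' @param seed Integer seed.
#' @return List: `assembly`, `instances` (GRanges), `chip`, `input`
#'   (chip_records), `fold`, `seed`.
#' @export
simulate_chip_experiment <- function(genome_length = 100000L, n_copies = 10L,
                                     copy_length = 200L, divergence = 0.01,
                                     fold = 10, depth = 100, read_length = 36L,
                                     seed = 1L) {
  set.seed(seed)
  cons <- .random_dna(copy_length, 0.5)
  copies <- vapply(seq_len(n_copies), function(i)
    mutate_copy(cons, divergence, 0), "")
  starts <- .place_intervals(nchar(copies), 1L, genome_length,
                             IRanges::IRanges(), what = "family copy")
  strands <- sample(c("+", "-"), n_copies, TRUE)
  chrom <- .chars(.random_dna(genome_length, 0.45))
  for (i in seq_len(n_copies)) {
    s <- if (strands[i] == "-") .revcomp(copies[i]) else copies[i]
    chrom[starts[i]:(starts[i] + nchar(s) - 1L)] <- .chars(s)
  }
  assembly <- Biostrings::DNAStringSet(c(chr1 = paste(chrom, collapse = "")))
  inst <- .gr("chr1", starts, starts + nchar(copies) - 1L, strands,
              assembly = assembly)
  # expected family depth = n * fold * rl / mass  =>  solve for n
  mass <- (genome_length - read_length + 1) +
    (fold - 1) * sum(pmax(GenomicRanges::width(inst) - read_length + 1, 0))
  n_chip <- as.integer(ceiling(depth * mass / (fold * read_length)))
  chip <- simulate_chip_reads(assembly, inst, n_chip, fold = fold,
                              read_length = read_length, seed = seed + 1L)
  input <- simulate_chip_reads(assembly, inst, n_chip, fold = 1,
                               read_length = read_length, seed = seed + 2L)
  list(assembly = assembly, instances = inst, chip = chip, input = input,
       fold = fold, seed = seed)
}
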