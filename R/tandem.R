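# Tandem-repeat detection by lag correlation: for each candidate period p the
# sequence is compared with itself shifted by p; maximal high-purity runs of
# matches are tandem arrays. Harmonic calls (the same array at multiples of
# its true period) are resolved in favour of the smallest period whose purity
# is within 0.05 of the best.

#' Detect tandem arrays in a sequence
#'
#' For each lag `p` in `[1, max_period]`, positions matching their `p`-shifted
#' neighbour are computed; maximal segments whose match purity is at least
#' `purity_min` and whose interval length is at least `max(2p, min_len)` are
#' reported. Overlapping calls at different periods are resolved in favour of
#' the smallest period whose purity is within 0.05 of the best in the
#' overlap group. The motif is the majority consensus of the period frames.
#'
#' @param x A `DNAStringSet`, or a single nucleotide string.
#' @param max_period Largest period searched (default 2000 bp).
#' @param purity_min Minimum fraction of positions matching at the period
#'   lag (default 0.8).
#' @param min_len Minimum array length in bp regardless of period
#'   (default 8).
#' @return A `GRanges` with metadata `period`, `copy_number`, `purity`,
#'   `motif`; empty when nothing is found.
#' @export
detect_tandem_arrays <- function(x, max_period = 2000L, purity_min = 0.8,
                                 min_len = 8L) {
  if (is.character(x) && length(x) == 1L)
    x <- Biostrings::DNAStringSet(c(seq = x))
  .stopifnot_assembly(x)
  out <- list()
  for (nm in names(x)) {
    s <- as.character(x[[nm]])
    cand <- .tandem_one_seq(s, max_period, purity_min, min_len)
    if (nrow(cand)) {
      cand$chrom <- nm
      out[[length(out) + 1L]] <- cand
    }
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  df <- do.call(rbind, out)
  gr <- .gr(df$chrom, df$start, df$end, "+", assembly = x)
  S4Vectors::mcols(gr)$period <- df$period
  S4Vectors::mcols(gr)$copy_number <- df$copy_number
  S4Vectors::mcols(gr)$purity <- df$purity
  S4Vectors::mcols(gr)$motif <- df$motif
  sort(gr, ignore.strand = TRUE)
}

.tandem_one_seq <- function(s, max_period, purity_min, min_len) {
  n <- nchar(s)
  if (n < 2L) return(data.frame())
  cand <- .tandem_scan(s, as.integer(max_period), purity_min,
                       as.integer(min_len))
  if (!nrow(cand)) return(data.frame())
  cand$start_seq <- cand$start
  cand$end_seq <- cand$end + cand$period
  # resolve overlap groups in favour of the smallest adequate period
  ir <- IRanges::IRanges(cand$start_seq, cand$end_seq)
  grp <- S4Vectors::subjectHits(
    IRanges::findOverlaps(ir, IRanges::reduce(ir)))
  pick <- unlist(lapply(split(seq_len(nrow(cand)), grp), function(i) {
    best <- max(cand$purity[i])
    ok <- i[cand$purity[i] >= best - 0.05]
    ok <- ok[cand$period[ok] == min(cand$period[ok])]
    ok[which.max(cand$end_seq[ok] - cand$start_seq[ok])]
  }))
  res <- cand[sort(pick), , drop = FALSE]
  data.frame(
    start = res$start_seq, end = res$end_seq, period = res$period,
    copy_number = (res$end_seq - res$start_seq + 1L) / res$period,
    purity = res$purity,
    motif = vapply(seq_len(nrow(res)), function(i)
      .tandem_motif(s, res$start_seq[i], res$end_seq[i], res$period[i]), ""))
}

.tandem_motif <- function(s, start, end, p) {
  b <- .chars(substr(s, start, end))
  n_frames <- length(b) %/% p
  if (n_frames < 1L) return(substr(s, start, start + p - 1L))
  m <- matrix(b[seq_len(n_frames * p)], nrow = p)
  paste(apply(m, 1L, function(col) {
    tt <- table(col[col %in% c("A", "C", "G", "T")])
    if (!length(tt)) "N" else names(tt)[which.max(tt)]
  }), collapse = "")
}

#' Split discovered families into tandem and local-repeat candidates
#'
#' A family is routed to the tandem catalogue if at least `tandem_overlap` of
#' its instance base pairs lie inside detected tandem arrays, or if its
#' instances are adjacent (inter-instance gap at most `gap_max` bp) in at
#' least half of consecutive sorted pairs. Every input family lands in
#' exactly one catalogue.
#'
#' @param families List of `repeat_family` objects.
#' @param arrays `GRanges` of tandem arrays (see [detect_tandem_arrays()]).
#' @param tandem_overlap Base-pair overlap fraction routing to TR
#'   (default 0.5).
#' @param gap_max Adjacency gap threshold in bp (default 10).
#' @return List with `tr_catalog` and `lr_candidates` (each a list of
#'   `repeat_family`).
#' @export
split_tandem <- function(families, arrays, tandem_overlap = 0.5,
                         gap_max = 10L) {
  is_tr <- vapply(families, function(f) {
    inst <- f$instances
    tot <- sum(GenomicRanges::width(inst))
    ov <- sum(GenomicRanges::width(GenomicRanges::intersect(
      GenomicRanges::reduce(inst, ignore.strand = TRUE),
      GenomicRanges::reduce(arrays, ignore.strand = TRUE),
      ignore.strand = TRUE)))
    if (tot > 0 && ov / tot >= tandem_overlap) return(TRUE)
    if (length(inst) >= 2L) {
      so <- sort(inst, ignore.strand = TRUE)
      same <- as.character(GenomeInfoDb::seqnames(so))[-1] ==
        as.character(GenomeInfoDb::seqnames(so))[-length(so)]
      gaps <- GenomicRanges::start(so)[-1] -
        GenomicRanges::end(so)[-length(so)] - 1L
      adj <- same & gaps <= gap_max
      if (mean(adj) >= 0.5) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(tr_catalog = families[is_tr], lr_candidates = families[!is_tr])
}

#' Write tandem arrays as BED6 plus a detail table
#'
#' @param arrays `GRanges` from [detect_tandem_arrays()].
#' @param bed_path,table_path Output paths (either may be `NULL`).
#' @return `arrays`, invisibly.
#' @export
write_tandem <- function(arrays, bed_path = NULL, table_path = NULL) {
  if (!is.null(bed_path)) {
    g <- arrays
    S4Vectors::mcols(g)$name <- sprintf("TR_p%d", S4Vectors::mcols(g)$period)
    S4Vectors::mcols(g)$score <-
      as.integer(round(S4Vectors::mcols(g)$purity * 1000))
    write_bed(g, bed_path)
  }
  if (!is.null(table_path)) {
    df <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(arrays)),
      start = GenomicRanges::start(arrays) - 1L,
      end = GenomicRanges::end(arrays),
      period = S4Vectors::mcols(arrays)$period,
      copy_number = S4Vectors::mcols(arrays)$copy_number,
      purity = S4Vectors::mcols(arrays)$purity,
      motif = S4Vectors::mcols(arrays)$motif)
    utils::write.table(df, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(arrays)
}
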