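# Multi-mapping-aware ChIP-Seq enrichment: fractional 1/n read weights with a
# best-20 cap, weighted coverage over repeat-family instances, and a
# permutation-calibrated Poisson significance test on the ChIP/input ratio.

#' Build a weighted alignment set from alignment records
#'
#' Records sharing a `read_id` are one multi-mapped read. If a read has more
#' than `cap` records, the `cap` best by alignment score are kept (ties broken
#' by coordinate order) and `n_reported` is reset to the kept count. Each kept
#' record then carries weight `1 / n_reported`, so every read with at most
#' `cap` alignments contributes total weight exactly 1.
#'
#' @param records Data frame with columns `read_id`, `chrom`, `pos` (1-based
#'   leftmost), `width`, and optionally `strand` and `score` (alignment
#'   score, used for the cap).
#' @param cap Maximum records kept per read (default 20).
#' @param seqlengths Optional named reference lengths for the result.
#' @return A `weighted_alignments` object: a list with `records` (a `GRanges`
#'   carrying `read_id`, `n_reported` and `weight` metadata),
#'   `total_weighted_reads` and `cap`.
#' @export
weighted_alignments <- function(records, cap = 20L, seqlengths = NULL) {
  stopifnot(cap >= 1L)
  need <- c("read_id", "chrom", "pos", "width")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyNA(records$pos) || anyNA(records$width))
    stop("malformed record(s) at index ",
         paste(utils::head(which(is.na(records$pos) | is.na(records$width))),
               collapse = ","), call. = FALSE)
  score <- if ("score" %in% names(records)) records$score else rep(0, nrow(records))
  # order: read, then score desc, then coordinates (deterministic tie-break)
  o <- order(records$read_id, -score, records$chrom, records$pos)
  records <- records[o, , drop = FALSE]
  grp <- match(records$read_id, unique(records$read_id))
  rank_in_read <- stats::ave(seq_len(nrow(records)), grp, FUN = seq_along)
  keep <- rank_in_read <= cap
  records <- records[keep, , drop = FALSE]
  grp <- grp[keep]
  n_rep <- as.integer(table(grp))[grp]
  strand <- if ("strand" %in% names(records)) records$strand else "*"
  gr <- GenomicRanges::GRanges(
    records$chrom,
    IRanges::IRanges(records$pos, width = records$width),
    strand = ifelse(strand %in% c("+", "-"), strand, "*"))
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  S4Vectors::mcols(gr)$read_id <- records$read_id
  S4Vectors::mcols(gr)$n_reported <- n_rep
  S4Vectors::mcols(gr)$weight <- 1 / n_rep
  structure(list(records = gr,
                 total_weighted_reads = length(unique(records$read_id)),
                 cap = as.integer(cap)),
            class = "weighted_alignments")
}

#' @export
print.weighted_alignments <- function(x, ...) {
  cat("weighted_alignments:", length(x$records), "records from",
      x$total_weighted_reads, "reads (cap", paste0(x$cap, ")"), "\n")
  invisible(x)
}

#' Load multi-mapped alignments from SAM/BAM with fractional weights
#'
#' SAM input is converted with [Rsamtools::asBam()]; records are grouped by
#' read name and weighted 1/n with the best-`cap` rule of
#' [weighted_alignments()]. The alignment score is taken from the `AS` tag
#' when present.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @param cap Maximum records kept per read (default 20).
#' @return A `weighted_alignments` object.
#' @export
load_alignments <- function(path, cap = 20L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "cigar"),
    tag = c("NH", "AS"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  ok <- !is.na(x$pos)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  # reference span from CIGAR (M/D/N/=/X consume reference)
  ref_w <- x$qwidth
  cig <- x$cigar
  has_indel <- grepl("[DIN]", cig)
  if (any(has_indel, na.rm = TRUE)) {
    ref_w[which(has_indel)] <- vapply(which(has_indel), function(i) {
      ops <- gregexpr("\\d+[MIDNSHP=X]", cig[i])[[1]]
      toks <- regmatches(cig[i], gregexpr("\\d+[MIDNSHP=X]", cig[i]))[[1]]
      n <- as.integer(sub("[A-Z=]", "", toks))
      op <- sub("\\d+", "", toks)
      sum(n[op %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
  }
  rec <- data.frame(
    read_id = x$qname[ok],
    chrom = as.character(x$rname[ok]),
    pos = x$pos[ok],
    width = ref_w[ok],
    strand = ifelse(bitwAnd(x$flag[ok], 16L) > 0L, "-", "+"),
    score = if (!is.null(x$tag$AS)) x$tag$AS[ok] else rep(0, sum(ok)))
  weighted_alignments(rec, cap = cap, seqlengths = hdr)
}

#' Mean weighted read depth over a region set
#'
#' Depth at a base is the sum of weights of overlapping records; the value
#' returned is the mean depth over the union of `regions`, scaled to
#' depth-per-million by `1e6 / total_weighted_reads`.
#'
#' @param alignments A `weighted_alignments` object.
#' @param regions `GRanges` of target regions.
#' @param scale Scale to per-million weighted reads (default TRUE).
#' @return A single numeric mean weighted depth.
#' @export
weighted_coverage <- function(alignments, regions, scale = TRUE) {
  if (length(regions) == 0L) stop("empty region list", call. = FALSE)
  cov <- .weighted_cov_rle(alignments)
  .mean_cov(cov, regions) *
    (if (scale) 1e6 / alignments$total_weighted_reads else 1)
}

.weighted_cov_rle <- function(alignments) {
  gr <- alignments$records
  GenomicRanges::coverage(gr, weight = S4Vectors::mcols(gr)$weight)
}

.mean_cov <- function(cov, regions) {
  regions <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  tot <- 0; nb <- 0
  for (ch in unique(as.character(GenomeInfoDb::seqnames(regions)))) {
    if (!ch %in% names(cov)) next
    r <- IRanges::ranges(regions[GenomeInfoDb::seqnames(regions) == ch])
    v <- IRanges::Views(cov[[ch]], r)
    tot <- tot + sum(IRanges::viewSums(v))
    nb <- nb + sum(IRanges::width(r))
  }
  if (nb == 0L) stop("regions fall outside covered sequence space", call. = FALSE)
  tot / nb
}

#' ChIP enrichment over a repeat family with a permutation Poisson test
#'
#' Computes the observed enrichment (mean weighted per-million ChIP depth over
#' the family instances divided by the input depth, both with pseudocount
#' `eps`), then draws `n_perm` random region sets with the same width
#' multiset (permutation `i` reseeded with `seed + i`), avoiding N-masked
#' bases, and scores each identically. The mean permuted enrichment is the
#' rate `lambda` of a Poisson null; the p-value is
#' `P(X >= ceiling(observed))` for `X ~ Poisson(lambda)` (conservative for a
#' continuous ratio).
#'
#' @param chip,input `weighted_alignments` for ChIP and input libraries.
#' @param regions `GRanges` of the family instances.
#' @param assembly `DNAStringSet` genome (defines bounds and the N-mask).
#' @param n_perm Number of permutations (>= 10; default 100).
#' @param seed Integer seed.
#' @param eps Pseudocount in per-million depth units (default 0.1).
#' @param family_id Label carried into the result.
#' @return An `enrichment_result`: `family_id`, `chip_cov`, `input_cov`,
#'   `enrichment`, `perm_scores`, `lambda`, `p_value`.
#' @export
permutation_poisson_test <- function(chip, input, regions, assembly,
                                     n_perm = 100L, seed = 1L, eps = 0.1,
                                     family_id = "family") {
  if (n_perm < 10L) stop("n_perm must be >= 10 (lambda unstable)", call. = FALSE)
  if (length(regions) == 0L) stop("empty region list", call. = FALSE)
  .stopifnot_assembly(assembly)
  sl <- .seqlengths_of(assembly)

  chip_cov_rle <- .weighted_cov_rle(chip)
  input_cov_rle <- .weighted_cov_rle(input)
  chip_scale <- 1e6 / chip$total_weighted_reads
  input_scale <- 1e6 / input$total_weighted_reads

  chip_cov <- .mean_cov(chip_cov_rle, regions) * chip_scale
  input_cov <- .mean_cov(input_cov_rle, regions) * input_scale
  observed <- (chip_cov + eps) / (input_cov + eps)

  # usable (non-N) space per chromosome for permuted placements
  n_mask <- lapply(names(assembly), function(ch) {
    at <- Biostrings::matchPattern("N", assembly[[ch]])
    IRanges::reduce(IRanges::ranges(at))
  })
  names(n_mask) <- names(assembly)

  widths <- GenomicRanges::width(regions)
  chroms <- names(sl)
  tot_w <- sum(widths)
  perm_scores <- vapply(seq_len(n_perm), function(i) {
    set.seed(seed + i)
    df <- .random_regions_df(widths, chroms, sl, n_mask)
    cc <- 0; ic <- 0
    for (ch in unique(df$chrom)) {
      r <- IRanges::IRanges(df$start[df$chrom == ch],
                            width = df$width[df$chrom == ch])
      cc <- cc + sum(IRanges::viewSums(IRanges::Views(chip_cov_rle[[ch]], r)))
      ic <- ic + sum(IRanges::viewSums(IRanges::Views(input_cov_rle[[ch]], r)))
    }
    (cc / tot_w * chip_scale + eps) / (ic / tot_w * input_scale + eps)
  }, numeric(1))

  lambda <- mean(perm_scores)
  p <- stats::ppois(ceiling(observed) - 1, lambda, lower.tail = FALSE)
  structure(list(family_id = family_id, chip_cov = chip_cov,
                 input_cov = input_cov, enrichment = observed,
                 perm_scores = perm_scores, lambda = lambda,
                 p_value = max(p, .Machine$double.xmin), n_perm = n_perm),
            class = "enrichment_result")
}

# Draw one random region set with the given width multiset, uniformly over
# chromosomes (weighted by length), avoiding the `avoid` interval lists;
# non-overlap within the set is enforced. Plain-integer implementation (no
# ranges churn) because this sits inside permutation loops.
.random_regions_df <- function(widths, chroms, seqlengths, avoid,
                               retries = 2000L) {
  av_st <- lapply(avoid, IRanges::start)
  av_en <- lapply(avoid, IRanges::end)
  pl_st <- stats::setNames(vector("list", length(chroms)), chroms)
  pl_en <- pl_st
  out_ch <- character(length(widths)); out_st <- integer(length(widths))
  clashes <- function(s, e, st, en) {
    if (!length(st)) return(FALSE)
    k <- findInterval(e, st)             # intervals starting at or before e
    k >= 1L && en[k] >= s
  }
  # widest first: large windows need the large free gaps
  for (i in order(widths, decreasing = TRUE)) {
    w <- widths[i]
    ok <- FALSE
    for (try in seq_len(retries)) {
      ch <- if (length(chroms) == 1L) chroms else
        sample(chroms, 1L, prob = seqlengths[chroms])
      hi <- seqlengths[[ch]] - w + 1L
      if (hi < 1L) next
      s <- sample.int(hi, 1L); e <- s + w - 1L
      if (clashes(s, e, av_st[[ch]], av_en[[ch]])) next
      ps <- pl_st[[ch]]
      if (length(ps) && any(pl_en[[ch]] >= s & ps <= e)) next
      pl_st[[ch]] <- c(ps, s); pl_en[[ch]] <- c(pl_en[[ch]], e)
      out_ch[i] <- ch; out_st[i] <- s
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place permuted region of width ", w, call. = FALSE)
  }
  data.frame(chrom = out_ch, start = out_st, width = widths)
}

# GRanges wrapper used by the null-ensemble builder
.random_regions <- function(widths, chroms, seqlengths, avoid,
                            retries = 1000L) {
  df <- .random_regions_df(widths, chroms, seqlengths, avoid, retries)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, width = df$width))
  GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
  GenomeInfoDb::seqlengths(gr) <- seqlengths
  gr
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("ChIP enrichment at", x$family_id, "\n")
  cat(sprintf("  chip depth/M: %.3f  input depth/M: %.3f\n",
              x$chip_cov, x$input_cov))
  cat(sprintf("  enrichment: %.2f  lambda (mean of %d permutations): %.3f\n",
              x$enrichment, x$n_perm, x$lambda))
  cat(sprintf("  Poisson p-value: %.3g\n", x$p_value))
  invisible(x)
}

#' Export weighted coverage as bedGraph
#'
#' @param alignments A `weighted_alignments` object.
#' @param path Output path.
#' @param scale Per-million scaling (default TRUE).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(alignments, path, scale = TRUE) {
  cov <- .weighted_cov_rle(alignments)
  k <- if (scale) 1e6 / alignments$total_weighted_reads else 1
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(cov)) {
    r <- cov[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, ends[-length(ends)])
    val <- S4Vectors::runValue(r) * k
    keep <- val != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", ch, starts[keep], ends[keep],
                         val[keep]), con)
  }
  invisible(path)
}
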