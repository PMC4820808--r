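# Length-matched sampling, shuffled null ensembles, and rank-sum comparison
# of per-gene repeat burdens between gene classes.

#' Sample length-matched gene subsets
#'
#' Pooled gene lengths are binned into deciles of the log10-length
#' distribution; from each bin, `min(count_a, count_b)` genes are drawn
#' without replacement from each set, giving equal-sized subsamples with
#' matched length distributions. A two-sided rank-sum test on the matched
#' lengths is run as a sanity check; p <= 0.05 raises a warning.
#'
#' @param set_a,set_b Data frames with a `length` column (bp).
#' @param seed Integer seed.
#' @return List with `a` and `b` (row subsets of the inputs, equal sizes)
#'   and `length_p` (the matching-check p-value).
#' @export
sample_length_matched <- function(set_a, set_b, seed = 1L) {
  if (!nrow(set_a) || !nrow(set_b)) stop("both sets must be non-empty", call. = FALSE)
  set.seed(seed)
  la <- log10(set_a$length); lb <- log10(set_b$length)
  br <- stats::quantile(c(la, lb), probs = seq(0, 1, 0.1), names = FALSE)
  br[1] <- -Inf; br[length(br)] <- Inf
  br <- unique(br)
  bin_a <- cut(la, br); bin_b <- cut(lb, br)
  idx_a <- integer(0); idx_b <- integer(0)
  for (lev in levels(bin_a)) {
    ia <- which(bin_a == lev); ib <- which(bin_b == lev)
    m <- min(length(ia), length(ib))
    if (m == 0L) next
    idx_a <- c(idx_a, sample(ia, m))
    idx_b <- c(idx_b, sample(ib, m))
  }
  if (!length(idx_a))
    stop("length ranges are disjoint: no bin is occupied by both sets",
         call. = FALSE)
  p <- suppressWarnings(stats::wilcox.test(la[idx_a], lb[idx_b])$p.value)
  if (is.finite(p) && p <= 0.05)
    warning("length distributions of matched subsamples differ (p = ",
            signif(p, 3), ")", call. = FALSE)
  list(a = set_a[idx_a, , drop = FALSE], b = set_b[idx_b, , drop = FALSE],
       length_p = p)
}

#' Build a shuffled null ensemble of annotation windows
#'
#' Each permutation places windows with the original width multiset uniformly
#' at random (non-overlapping within a permutation); in
#' `"shuffled_intergenic"` mode any placement overlapping a gene is rejected.
#' Permutation `i` is reseeded with `seed + i`, so individual permutations
#' are reproducible in isolation.
#'
#' @param genes Source annotation `GRanges` (its widths are reused).
#' @param assembly `DNAStringSet` genome (defines bounds and the N-mask).
#' @param mode `"shuffled"` or `"shuffled_intergenic"`.
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed.
#' @param exclude Annotation `GRanges` that intergenic windows must not
#'   overlap; defaults to `genes`, but should be the complete gene
#'   annotation when only a subset (for example the lncRNA catalogue) is
#'   being shuffled.
#' @return A `null_ensemble`: list with `mode`, `n_perm`, `seed`, and
#'   `windows` (list of `GRanges`, one per permutation).
#' @export
build_null <- function(genes, assembly, mode = c("shuffled",
                                                 "shuffled_intergenic"),
                       n_perm = 100L, seed = 1L, exclude = genes) {
  mode <- match.arg(mode)
  .stopifnot_assembly(assembly)
  sl <- .seqlengths_of(assembly)
  widths <- GenomicRanges::width(genes)
  avoid <- lapply(names(assembly), function(ch) {
    at <- Biostrings::matchPattern("N", assembly[[ch]])
    ir <- IRanges::reduce(IRanges::ranges(at))
    if (mode == "shuffled_intergenic") {
      g <- exclude[as.character(GenomeInfoDb::seqnames(exclude)) == ch]
      ir <- IRanges::reduce(c(ir, IRanges::ranges(g)))
    }
    ir
  })
  names(avoid) <- names(assembly)
  if (mode == "shuffled_intergenic") {
    free <- sum(sl) - sum(vapply(avoid, function(x) sum(IRanges::width(x)),
                                 numeric(1)))
    if (free < sum(widths))
      stop("intergenic space (", free, " bp) smaller than total annotation (",
           sum(widths), " bp)", call. = FALSE)
  }
  windows <- lapply(seq_len(n_perm), function(i) {
    set.seed(seed + i)
    .random_regions(widths, names(sl), sl, avoid)
  })
  structure(list(mode = mode, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), windows = windows),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("null_ensemble:", x$n_perm, "permutations, mode", x$mode,
      "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Per-window repeat burden of a null ensemble
#'
#' Counts repeat instances falling in each permuted window (an instance
#' counts when at least `inside_frac` of its bases overlap the window) and
#' normalizes per kb, pooling windows across permutations.
#'
#' @param ensemble A `null_ensemble` from [build_null()].
#' @param instances `GRanges` of repeat instances (for example all instances
#'   of LOCAL families).
#' @param inside_frac Base-overlap fraction counting an instance as inside.
#' @return Numeric vector of per-kb burdens, one entry per window per
#'   permutation.
#' @export
null_burden <- function(ensemble, instances, inside_frac = 0.5) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  unlist(lapply(ensemble$windows, function(w) {
    n <- integer(length(w))
    ov <- GenomicRanges::findOverlaps(instances, w, ignore.strand = TRUE)
    if (length(ov)) {
      pint <- GenomicRanges::pintersect(
        instances[S4Vectors::queryHits(ov)], w[S4Vectors::subjectHits(ov)],
        ignore.strand = TRUE)
      frac <- GenomicRanges::width(pint) /
        GenomicRanges::width(instances[S4Vectors::queryHits(ov)])
      tt <- table(factor(S4Vectors::subjectHits(ov)[frac >= inside_frac],
                         levels = seq_along(w)))
      n <- as.integer(tt)
    }
    n / (GenomicRanges::width(w) / 1000)
  }), use.names = FALSE)
}

#' Compare per-gene repeat burdens between two groups
#'
#' Two-sided Mann-Whitney rank-sum test with tie correction on per-kb burden
#' values, plus empirical CDF tables for plotting.
#'
#' @param burden_a,burden_b Numeric vectors of per-gene per-kb burdens.
#' @param label_a,label_b Group labels.
#' @return A `burden_comparison`: `statistic` (rank-sum U), `p_value`,
#'   `n_a`, `n_b`, `median_a`, `median_b`, and `cdf` (long data.frame of
#'   sorted values with cumulative fractions).
#' @export
compare_burdens <- function(burden_a, burden_b, label_a = "group_a",
                            label_b = "group_b") {
  if (!length(burden_a) || !length(burden_b))
    stop("both groups must be non-empty", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(burden_a, burden_b,
                                            alternative = "two.sided"))
  cdf <- rbind(
    data.frame(group = label_a, value = sort(burden_a),
               cum_fraction = seq_along(burden_a) / length(burden_a)),
    data.frame(group = label_b, value = sort(burden_b),
               cum_fraction = seq_along(burden_b) / length(burden_b)))
  structure(list(group_a = label_a, group_b = label_b,
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_a = length(burden_a), n_b = length(burden_b),
                 median_a = stats::median(burden_a),
                 median_b = stats::median(burden_b), cdf = cdf),
            class = "burden_comparison")
}

#' @export
print.burden_comparison <- function(x, ...) {
  cat(sprintf("rank-sum comparison %s (n=%d, median %.3g) vs %s (n=%d, median %.3g)\n",
              x$group_a, x$n_a, x$median_a, x$group_b, x$n_b, x$median_b))
  cat(sprintf("  U = %.1f, two-sided p = %.3g\n", x$statistic, x$p_value))
  invisible(x)
}
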