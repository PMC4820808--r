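# PSSM motif scanning with exact match p-values: the log-odds score
# distribution under the background model is computed by dynamic programming
# over per-column score atoms, so a window's p-value is the exact background
# probability of a score at least as high.

#' Log-odds scoring matrix from a PFM
#'
#' Counts are converted to probabilities with a pseudocount per cell, then to
#' log2 odds against the background.
#'
#' @param pfm A `pfm` object (see [read_pfm()]).
#' @param pseudocount Added to every cell (default 0.8).
#' @return A 4 x W numeric matrix (rows A/C/G/T) of log2-odds scores.
#' @export
pfm_logodds <- function(pfm, pseudocount = 0.8) {
  cnt <- pfm$counts
  p <- sweep(cnt + pseudocount, 2, colSums(cnt) + 4 * pseudocount, "/")
  log2(p / pfm$background)
}

# Exact score distribution under the background: atoms of (score, prob),
# partial sums accumulated left to right exactly as a word-by-word
# enumeration would. Atom merging keys on the exact double, so the score set
# equals the brute-force one. For wide motifs (4^W atoms impractical) scores
# are binned at `grid` resolution instead.
.score_distribution <- function(S, background, max_exact_width = 10L,
                                grid = 1e-4) {
  W <- ncol(S)
  exact <- W <= max_exact_width
  if (!exact) S <- round(S / grid) * grid
  sc <- 0; pr <- 1
  for (j in seq_len(W)) {
    ns <- rep(sc, each = 4L) + S[, j]
    np <- rep(pr, each = 4L) * background
    key <- format(ns, digits = 17)
    agg <- rowsum(np, key, reorder = FALSE)
    sc <- ns[!duplicated(key)]
    pr <- as.vector(agg)[match(unique(key), rownames(agg))]
  }
  o <- order(sc, decreasing = TRUE)
  sc <- sc[o]; pr <- pr[o]
  list(score = sc, tail_p = cumsum(pr))   # P(S >= score[i]) with score desc
}

#' Exact match p-values for motif scores
#'
#' Returns `P(background score >= s)` for each `s`, computed from the exact
#' score distribution of the motif under its background model.
#'
#' @param pfm A `pfm` object.
#' @param scores Numeric vector of observed window scores.
#' @param pseudocount Pseudocount for [pfm_logodds()].
#' @return Numeric vector of p-values.
#' @export
motif_score_pvalue <- function(pfm, scores, pseudocount = 0.8) {
  S <- pfm_logodds(pfm, pseudocount)
  d <- .score_distribution(S, pfm$background)
  asc <- rev(d$score)                 # ascending
  tail_asc <- rev(d$tail_p)           # tail_asc[m] = P(S >= asc[m])
  k <- findInterval(scores - 1e-9, asc)  # atoms strictly below s (fp-tolerant)
  ifelse(k < length(asc), tail_asc[pmin(k + 1L, length(asc))], 0)
}

#' Scan sequences for motif matches with exact p-values
#'
#' Both strands of every sequence are scanned with the log-odds matrix of
#' each PFM; windows containing N are skipped. Hits with exact match p-value
#' at most `cutoff` are reported; q-values are Benjamini-Hochberg adjusted
#' over all windows tested per motif.
#'
#' @param pfms A list of `pfm` objects (or a single `pfm`).
#' @param sequences Named character vector of nucleotide strings, or a
#'   `DNAStringSet`.
#' @param cutoff Match p-value cutoff (default 1e-6).
#' @param pseudocount Pseudocount for [pfm_logodds()].
#' @return Data frame of hits: `motif_id`, `seq_name`, `start`, `end`
#'   (1-based on the forward strand), `strand`, `score`, `p_value`,
#'   `q_value`.
#' @export
scan_motifs <- function(pfms, sequences, cutoff = 1e-6, pseudocount = 0.8) {
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  bases <- c("A", "C", "G", "T")
  hits <- list()
  for (pfm in pfms) {
    W <- ncol(pfm$counts)
    if (all(nchar(sequences) < W)) {
      warning("motif ", pfm$motif_id, " wider than every sequence; skipped",
              call. = FALSE)
      next
    }
    S <- pfm_logodds(pfm, pseudocount)
    d <- .score_distribution(S, pfm$background)
    all_rows <- list()
    for (nm in names(sequences)) {
      n <- nchar(sequences[[nm]])
      if (n < W) next
      for (st in c("+", "-")) {
        s <- if (st == "+") sequences[[nm]] else .revcomp(sequences[[nm]])
        code <- match(.chars(s), bases)
        nw <- n - W + 1L
        sc <- numeric(nw)
        for (j in seq_len(W))
          sc <- sc + S[cbind(code[j:(j + nw - 1L)], j)]
        ok <- which(!is.na(sc))
        if (!length(ok)) next
        start_fwd <- if (st == "+") ok else n - (ok + W - 1L) + 1L
        all_rows[[paste(nm, st)]] <- data.frame(
          seq_name = nm, start = start_fwd, end = start_fwd + W - 1L,
          strand = st, score = sc[ok])
      }
    }
    if (!length(all_rows)) next
    df <- do.call(rbind, all_rows)
    df$p_value <- motif_score_pvalue(pfm, df$score, pseudocount)
    df$q_value <- stats::p.adjust(df$p_value, method = "BH")
    df <- df[df$p_value <= cutoff, , drop = FALSE]
    if (nrow(df)) {
      df <- cbind(motif_id = pfm$motif_id, df)
      hits[[pfm$motif_id]] <- df
    }
  }
  if (!length(hits))
    return(data.frame(motif_id = character(0), seq_name = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      p_value = numeric(0), q_value = numeric(0)))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$motif_id, out$seq_name, out$start), , drop = FALSE]
}
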