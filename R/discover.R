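# De novo repeat discovery: TE masking, k-mer seed families pooled across
# strands under the canonical k-mer, and greedy gapless bidirectional
# consensus extension with an X-drop stop, in descending seed-count order
# with tombstoning of claimed genome positions.

#' Mask annotated transposable elements with N
#'
#' @param assembly `DNAStringSet` genome.
#' @param te_intervals `GRanges` of TE annotations (union semantics for
#'   overlaps). Intervals extending beyond a chromosome end are an error.
#' @return A `masked_genome`: list with `assembly` (masked copy),
#'   `masked_intervals` (reduced `GRanges`) and `masked_fraction`.
#' @export
mask_te <- function(assembly, te_intervals) {
  .stopifnot_assembly(assembly)
  sl <- .seqlengths_of(assembly)
  red <- GenomicRanges::reduce(te_intervals, ignore.strand = TRUE)
  ch <- as.character(GenomeInfoDb::seqnames(red))
  if (!all(ch %in% names(sl)))
    stop("TE interval on unknown sequence: ",
         paste(setdiff(unique(ch), names(sl)), collapse = ", "), call. = FALSE)
  if (any(GenomicRanges::end(red) > sl[ch]) || any(GenomicRanges::start(red) < 1))
    stop("TE interval off the end of a chromosome", call. = FALSE)
  seqs <- as.character(assembly)
  masked_bp <- 0L
  for (nm in unique(ch)) {
    r <- red[ch == nm]
    b <- .chars(seqs[[nm]])
    for (i in seq_along(r))
      b[GenomicRanges::start(r)[i]:GenomicRanges::end(r)[i]] <- "N"
    seqs[[nm]] <- paste(b, collapse = "")
    masked_bp <- masked_bp + sum(GenomicRanges::width(r))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(assembly)
  frac <- masked_bp / sum(sl)
  message(sprintf("masked %d bp (%.2f%%) in %d interval(s)",
                  masked_bp, 100 * frac, length(red)))
  structure(list(assembly = out, masked_intervals = red,
                 masked_fraction = frac), class = "masked_genome")
}

#' @export
print.masked_genome <- function(x, ...) {
  cat(sprintf("masked_genome: %d sequence(s), %.2f%% masked\n",
              length(x$assembly), 100 * x$masked_fraction))
  invisible(x)
}

#' Find repeated k-mer seed families
#'
#' Enumerates every k-mer not containing N, pools forward and
#' reverse-complement occurrences under the lexicographically smaller of the
#' k-mer and its reverse complement, and returns families with at least
#' `min_count` occurrences, sorted by descending occurrence count (ties by
#' k-mer).
#'
#' @param masked A `masked_genome` (or `DNAStringSet`).
#' @param k Seed length (default 16; must be >= 8).
#' @param min_count Minimum pooled occurrence count (>= 2).
#' @return List of seed families: `kmer`, and parallel vectors `chrom`,
#'   `pos` (1-based start of the k-mer on the forward strand) and `strand`
#'   (`+` if the forward k-mer equals the canonical k-mer).
#' @export
find_seeds <- function(masked, k = 16L, min_count = 3L) {
  if (k < 8L) stop("k must be >= 8", call. = FALSE)
  if (min_count < 2L) stop("min_count must be >= 2", call. = FALSE)
  assembly <- if (inherits(masked, "masked_genome")) masked$assembly else masked
  .stopifnot_assembly(assembly)
  if (all(Biostrings::width(assembly) < k)) {
    warning("k exceeds every sequence length; no seeds", call. = FALSE)
    return(list())
  }
  all_km <- character(0); all_ch <- character(0); all_pos <- integer(0)
  for (nm in names(assembly)) {
    s <- as.character(assembly[[nm]])
    n <- nchar(s)
    if (n < k) next
    km <- substring(s, 1:(n - k + 1L), k:n)
    ok <- !grepl("N", km, fixed = TRUE)
    all_km <- c(all_km, km[ok])
    all_ch <- c(all_ch, rep(nm, sum(ok)))
    all_pos <- c(all_pos, which(ok))
  }
  if (!length(all_km)) return(list())
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(all_km)))
  fwd_is_canon <- all_km <= rc
  canon <- ifelse(fwd_is_canon, all_km, rc)
  cnt <- table(canon)
  keep_km <- names(cnt)[cnt >= min_count]
  if (!length(keep_km)) return(list())
  sel <- canon %in% keep_km
  idx <- split(which(sel), canon[sel])
  fams <- lapply(names(idx), function(km) {
    i <- idx[[km]]
    list(kmer = km, chrom = all_ch[i], pos = all_pos[i],
         strand = ifelse(fwd_is_canon[i], "+", "-"))
  })
  o <- order(-lengths(lapply(fams, `[[`, "pos")),
             vapply(fams, `[[`, "", "kmer"))
  fams[o]
}

#' Extend a seed family into a repeat-family consensus
#'
#' Greedy gapless extension one column at a time, leftward then rightward
#' from the seed k-mer, in the canonical orientation of the seed. At each
#' column the consensus base is the majority base over live copies (ties
#' broken alphabetically); the column score is
#' `n_agree - mismatch_penalty * n_disagree` (N and off-sequence positions
#' disagree; the penalty keeps the expected score strictly negative over
#' random sequence at any copy number); extension in a direction stops when
#' the running score drops more than `x_drop` below its maximum, and the
#' consensus is trimmed to the maximum-scoring extent. A copy whose identity
#' to the growing consensus falls below `min_identity` is dropped from the
#' live set. The objective score is the summed per-copy alignment score
#' (matches minus mismatches) minus `c_penalty` times the consensus length.
#'
#' @param masked A `masked_genome` or `DNAStringSet`.
#' @param seed One element of [find_seeds()] output.
#' @param min_identity Identity floor for live copies (default 0.8).
#' @param x_drop X-drop threshold (default 20).
#' @param c_penalty Consensus length penalty (default 2).
#' @param mismatch_penalty Weight of a disagreeing copy in the column score
#'   (default 3).
#' @param max_extend Maximum extension per direction in bp (default 2000).
#' @return A `repeat_family` (list: `family_id`, `consensus`, `instances`
#'   GRanges with `identity`, `objective_score`), or `NULL` when fewer than
#'   two copies survive.
#' @export
extend_seed <- function(masked, seed, min_identity = 0.8, x_drop = 20,
                        c_penalty = 2, mismatch_penalty = 3,
                        max_extend = 2000L) {
  assembly <- if (inherits(masked, "masked_genome")) masked$assembly else masked
  k <- nchar(seed$kmer)
  n_cop <- length(seed$pos)
  if (n_cop < 2L) return(NULL)
  sl <- .seqlengths_of(assembly)
  W <- 2L * max_extend + k
  ctr <- (max_extend + 1L):(max_extend + k)

  # oriented windows, padded with N beyond sequence ends
  M <- matrix("N", nrow = n_cop, ncol = W)
  for (i in seq_len(n_cop)) {
    ch <- seed$chrom[i]; p <- seed$pos[i]
    ws <- p - max_extend; we <- p + k - 1L + max_extend
    lo <- max(ws, 1L); hi <- min(we, sl[[ch]])
    b <- .chars(as.character(Biostrings::subseq(assembly[[ch]], lo, hi)))
    row <- rep("N", W)
    row[(lo - ws + 1L):(hi - ws + 1L)] <- b
    if (seed$strand[i] == "-") row <- rev(unname(.COMP[row]))
    M[i, ] <- row
  }

  live <- rep(TRUE, n_cop)
  match_mat <- matrix(FALSE, nrow = n_cop, ncol = W)
  match_mat[, ctr] <- TRUE              # copies contain the seed exactly
  cons <- rep(NA_character_, W)
  cons[ctr] <- .chars(seed$kmer)
  cum_match <- rep(k, n_cop)            # matches over adopted extent so far
  cum_len <- k

  extend_dir <- function(cols) {
    run <- 0; best <- 0; best_at <- 0L   # 0 = no extension
    taken <- 0L
    best_cm <- cum_match; best_len <- cum_len   # state at the best extent
    on.exit({ cum_match <<- best_cm; cum_len <<- best_len })
    for (j in cols) {
      col <- M[live, j]
      tabu <- c(A = 0L, C = 0L, G = 0L, T = 0L)
      tt <- table(col[col %in% c("A", "C", "G", "T")])
      tabu[names(tt)] <- as.integer(tt)
      n_agree <- max(tabu)
      base <- names(tabu)[which.max(tabu)]   # alphabetical tie-break
      n_dis <- sum(live) - n_agree
      run <- run + (n_agree - mismatch_penalty * n_dis)
      taken <- taken + 1L
      cons[j] <<- base
      mm <- M[, j] == base
      match_mat[, j] <<- mm
      cum_match <<- cum_match + as.integer(mm)
      cum_len <<- cum_len + 1L
      if (run > best) {
        best <- run; best_at <- taken
        best_cm <- cum_match; best_len <- cum_len
        # drop copies whose identity over the accepted extent collapses
        drop <- live & (best_cm / best_len) < min_identity
        if (any(drop)) live[drop] <<- FALSE
        if (sum(live) < 2L) return(best_at)
      }
      if (run < best - x_drop) return(best_at)
    }
    best_at
  }

  left_cols <- if (max_extend > 0) (ctr[1] - 1L):1L else integer(0)
  right_cols <- if (max_extend > 0) (ctr[k] + 1L):W else integer(0)
  n_left <- extend_dir(left_cols)
  n_right <- if (sum(live) >= 2L) extend_dir(right_cols) else 0L

  lo_col <- ctr[1] - n_left
  hi_col <- ctr[k] + n_right
  span <- lo_col:hi_col
  consensus <- paste(cons[span], collapse = "")
  len <- length(span)

  ident <- rowSums(match_mat[, span, drop = FALSE]) / len
  keep <- live & ident >= min_identity
  if (sum(keep) < 2L) {
    message("seed ", seed$kmer, ": all copies dropped; family discarded")
    return(NULL)
  }

  idx <- which(keep)
  g_start <- integer(length(idx)); g_end <- integer(length(idx))
  for (u in seq_along(idx)) {
    i <- idx[u]
    p <- seed$pos[i]
    ws <- p - max_extend; we <- p + k - 1L + max_extend
    if (seed$strand[i] == "+") {
      g_start[u] <- ws + lo_col - 1L
      g_end[u] <- ws + hi_col - 1L
    } else {
      g_start[u] <- we - hi_col + 1L
      g_end[u] <- we - lo_col + 1L
    }
    g_start[u] <- max(g_start[u], 1L)
    g_end[u] <- min(g_end[u], sl[[seed$chrom[i]]])
  }
  inst <- .gr(seed$chrom[idx], g_start, g_end, seed$strand[idx],
              assembly = assembly)
  S4Vectors::mcols(inst)$identity <- ident[idx]
  score <- sum(rowSums(match_mat[idx, span, drop = FALSE]) -
                 (len - rowSums(match_mat[idx, span, drop = FALSE]))) -
    c_penalty * len
  structure(list(family_id = NA_character_, consensus = consensus,
                 instances = inst, objective_score = score),
            class = "repeat_family")
}

#' @export
print.repeat_family <- function(x, ...) {
  cat(sprintf("repeat_family %s: %d bp consensus, %d instances, score %.0f\n",
              x$family_id, nchar(x$consensus), length(x$instances),
              x$objective_score))
  invisible(x)
}

#' Discover repeat families de novo
#'
#' Seeds are processed in descending occurrence order; genome positions
#' claimed by an accepted family are tombstoned so later seeds cannot
#' re-discover the same element. With `refine_instances = TRUE` (the
#' default) an accepted consensus is immediately re-mapped genome-wide with
#' [map_consensus()] and all of its hits become the family's instances and
#' claims; this recovers copies whose seed k-mer was destroyed by divergence
#' and prevents fragment families. Families with fewer than two surviving
#' instances or a consensus shorter than `min_length` are discarded. Output
#' is deterministic given the input.
#'
#' @param masked A `masked_genome` (see [mask_te()]) or `DNAStringSet`.
#' @param k Seed k-mer length (default 16).
#' @param min_count Minimum seed occurrence count (default 3).
#' @param min_identity Per-copy identity floor (default 0.8).
#' @param x_drop X-drop threshold (default 20).
#' @param c_penalty Consensus length penalty (default 2).
#' @param mismatch_penalty Column-score weight of a disagreeing copy
#'   (default 3).
#' @param min_length Minimum consensus length kept (default 50).
#' @param max_extend Maximum extension per direction (default 2000).
#' @param refine_instances Re-map each accepted consensus genome-wide and
#'   use the mapped hits as the family's instances (default TRUE).
#' @return A list of `repeat_family` objects (`family_id` = `fam001`, ...).
#' @export
discover_repeats <- function(masked, k = 16L, min_count = 3L,
                             min_identity = 0.8, x_drop = 20, c_penalty = 2,
                             mismatch_penalty = 3, min_length = 50L,
                             max_extend = 2000L, refine_instances = TRUE) {
  assembly <- if (inherits(masked, "masked_genome")) masked$assembly else masked
  seeds <- find_seeds(masked, k = k, min_count = min_count)
  sl <- .seqlengths_of(assembly)
  tomb <- lapply(sl, function(n) logical(n))
  out <- list()
  for (sd in seeds) {
    free <- vapply(seq_along(sd$pos), function(i) {
      !any(tomb[[sd$chrom[i]]][sd$pos[i]:(sd$pos[i] + nchar(sd$kmer) - 1L)])
    }, logical(1))
    if (sum(free) < min_count) next
    sd2 <- list(kmer = sd$kmer, chrom = sd$chrom[free], pos = sd$pos[free],
                strand = sd$strand[free])
    fam <- extend_seed(masked, sd2, min_identity = min_identity,
                       x_drop = x_drop, c_penalty = c_penalty,
                       mismatch_penalty = mismatch_penalty,
                       max_extend = max_extend)
    if (is.null(fam)) next
    if (nchar(fam$consensus) < min_length || length(fam$instances) < 2L) next
    if (refine_instances) {
      hits <- map_consensus(assembly, fam$consensus,
                            min_identity = min_identity)
      if (length(hits) >= 2L) fam$instances <- hits
    }
    fam$family_id <- sprintf("fam%03d", length(out) + 1L)
    inst <- fam$instances
    for (i in seq_along(inst)) {
      ch <- as.character(GenomeInfoDb::seqnames(inst))[i]
      tomb[[ch]][GenomicRanges::start(inst)[i]:GenomicRanges::end(inst)[i]] <- TRUE
    }
    out[[length(out) + 1L]] <- fam
  }
  out
}

#' Write a repeat-family catalogue
#'
#' Consensi go to FASTA (headers = family ids); instances to BED6 with the
#' family id in the name column and identity in the score column on a 0-1000
#' scale.
#'
#' @param families List of `repeat_family` objects.
#' @param fasta_path,bed_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a `GRanges` of all instances.
#' @export
write_families <- function(families, fasta_path = NULL, bed_path = NULL) {
  if (!length(families)) {
    if (!is.null(fasta_path)) writeLines(character(0), fasta_path)
    if (!is.null(bed_path)) writeLines(character(0), bed_path)
    return(invisible(GenomicRanges::GRanges()))
  }
  cons <- Biostrings::DNAStringSet(vapply(families, `[[`, "", "consensus"))
  names(cons) <- vapply(families, `[[`, "", "family_id")
  if (!is.null(fasta_path)) write_fasta(cons, fasta_path)
  inst <- do.call(c, lapply(families, function(f) {
    g <- f$instances
    S4Vectors::mcols(g)$name <- rep(f$family_id, length(g))
    S4Vectors::mcols(g)$score <-
      as.integer(round(S4Vectors::mcols(g)$identity * 1000))
    g
  }))
  if (!is.null(bed_path)) write_bed(inst, bed_path)
  invisible(inst)
}
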