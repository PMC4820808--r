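# Repeat-ortholog phylogenetics: built-in progressive aligner (external MSAs
# can be ingested instead), identity/distance matrices, hand-implemented
# neighbor joining, and bootstrap supports with a >50% consensus report.

.MSA_ALPHA <- c("A", "C", "G", "T", "N", "-")

#' Multiple sequence alignment container
#'
#' @param seqs Named character vector of equal-length gapped sequences over
#'   `{A,C,G,T,N,-}`.
#' @return A `dna_msa` object.
#' @export
dna_msa <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop("duplicate labels", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows must have equal length", call. = FALSE)
  bad <- grepl(sprintf("[^%s]", paste(.MSA_ALPHA, collapse = "")), seqs)
  if (any(bad)) stop("alignment contains characters outside A/C/G/T/N/-",
                     call. = FALSE)
  structure(list(labels = names(seqs), seqs = seqs,
                 n_columns = nchar(seqs[[1]])), class = "dna_msa")
}

#' @export
print.dna_msa <- function(x, ...) {
  cat("dna_msa:", length(x$seqs), "sequences x", x$n_columns, "columns\n")
  invisible(x)
}

#' @export
as.matrix.dna_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$labels
  m
}

#' Read an externally computed MSA from aligned FASTA
#'
#' @param path Aligned FASTA path (gaps as `-`).
#' @return A `dna_msa`.
#' @export
read_msa <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(raw))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  seqs <- gsub("[^ACGTN-]", "N", seqs)
  names(seqs) <- sub("\\s.*$", "", names(raw))
  dna_msa(seqs)
}

#' Write an MSA as aligned FASTA
#'
#' @param msa A `dna_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", msa$labels, "\n", msa$seqs), con)
  invisible(path)
}

.profile_of <- function(rows) {
  # rows: character matrix; returns 6 x L frequency matrix
  L <- ncol(rows)
  pr <- matrix(0, 6, L, dimnames = list(.MSA_ALPHA, NULL))
  for (a in seq_along(.MSA_ALPHA))
    pr[a, ] <- colMeans(rows == .MSA_ALPHA[a])
  pr
}

#' Progressive multiple alignment
#'
#' Guide order from single-linkage clustering on shared 8-mer distance;
#' pairwise and profile-profile alignment by global dynamic programming with
#' match +1, mismatch -1, gap open -4, gap extend -1 (a length-k gap costs
#' `open + ext * (k - 1)`), deterministic tie-breaking (prefer diagonal,
#' then the gap consuming the first profile).
#'
#' @param sequences Named character vector of nucleotide strings (>= 2), or
#'   a `DNAStringSet`.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters.
#' @param k Guide-tree k-mer length (default 8).
#' @return A `dna_msa`.
#' @export
progressive_align <- function(sequences, match = 1, mismatch = -1,
                              gap_open = -4, gap_ext = -1, k = 8L) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (length(sequences) < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (any(nchar(sequences) == 0L)) stop("zero-length sequence", call. = FALSE)
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  n <- length(sequences)

  # shared k-mer distance for the guide order
  kmers <- lapply(sequences, function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  })
  D <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    den <- min(length(kmers[[i]]), length(kmers[[j]]))
    d <- if (den == 0) 1 else 1 - length(intersect(kmers[[i]], kmers[[j]])) / den
    D[i, j] <- d; D[j, i] <- d
  }
  diag(D) <- Inf

  # clusters hold aligned row matrices
  clus <- lapply(sequences, function(s) {
    m <- matrix(.chars(s), nrow = 1)
    m
  })
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  cdist <- D
  while (sum(active) > 1L) {
    ij <- which(cdist == min(cdist[active, active][is.finite(cdist[active, active])]),
                arr.ind = TRUE)
    ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
    i <- ij[1]; j <- ij[2]
    pa <- .profile_of(clus[[i]]); pb <- .profile_of(clus[[j]])
    path <- .gotoh_align(pa, pb, match, mismatch, gap_open, gap_ext)
    L <- ncol(path)
    expand <- function(rows, idx) {
      out <- matrix("-", nrow(rows), L)
      take <- idx > 0L
      out[, take] <- rows[, idx[take], drop = FALSE]
      out
    }
    merged <- rbind(expand(clus[[i]], path[1, ]),
                    expand(clus[[j]], path[2, ]))
    clus[[i]] <- merged
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    # single linkage: min distance to the merged cluster
    newd <- pmin(cdist[i, ], cdist[j, ])
    cdist[i, ] <- newd; cdist[, i] <- newd
    cdist[i, i] <- Inf
    cdist[j, ] <- Inf; cdist[, j] <- Inf
  }
  root <- which(active)
  rows <- clus[[root]]
  ord <- order(members[[root]])
  seqs <- apply(rows[ord, , drop = FALSE], 1, paste, collapse = "")
  names(seqs) <- names(sequences)[sort(members[[root]])]
  # keep original input order
  dna_msa(seqs[names(sequences)])
}

#' Pairwise identity matrix of an alignment
#'
#' Identity of a pair is matches over columns where neither row has a gap or
#' N; pairs with no comparable column are `NA`.
#'
#' @param msa A `dna_msa`.
#' @return Symmetric numeric matrix of identity fractions.
#' @export
pairwise_identity <- function(msa) {
  m <- as.matrix(msa)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  good <- m %in% c("A", "C", "G", "T")
  dim(good) <- dim(m)
  out <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    comp <- good[i, ] & good[j, ]
    v <- if (!any(comp)) NA_real_ else mean(m[i, comp] == m[j, comp])
    out[i, j] <- v; out[j, i] <- v
  }
  out
}

#' Distance matrix from an alignment
#'
#' p-distance is `1 - identity` on gap/N-excluded columns; the Jukes-Cantor
#' model applies `d = -3/4 log(1 - 4p/3)`. Saturated pairs (p >= 0.75) are
#' mapped to a ceiling distance of 10 with a warning.
#'
#' @param msa A `dna_msa`.
#' @param model `"jukes_cantor"` (default) or `"p_distance"`.
#' @return Symmetric distance matrix (zero diagonal).
#' @export
msa_distances <- function(msa, model = c("jukes_cantor", "p_distance")) {
  model <- match.arg(model)
  p <- 1 - pairwise_identity(msa)
  if (anyNA(p)) stop("pair(s) with no comparable columns", call. = FALSE)
  if (model == "p_distance") return(p)
  sat <- p >= 0.75
  if (any(sat)) {
    warning(sum(sat[upper.tri(sat)]),
            " saturated pair(s) set to ceiling distance 10", call. = FALSE)
  }
  d <- p
  d[!sat] <- -0.75 * log(1 - 4 * p[!sat] / 3)
  d[sat] <- 10
  diag(d) <- 0
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: iteratively joins the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch
#' lengths by the standard NJ formulas. Negative branch lengths are clamped
#' to zero with the deficit moved to the sister branch; ties are broken by
#' label order.
#'
#' @param dm Symmetric non-negative distance matrix with labelled rows.
#' @return An unrooted ape `phylo`.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (is.null(rownames(dm))) stop("distance matrix must be labelled", call. = FALSE)
  if (!isSymmetric(unname(dm), tol = 1e-8) || any(dm < 0))
    stop("distance matrix must be symmetric with non-negative entries",
         call. = FALSE)
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  labs <- rownames(dm)
  nwk <- labs           # growing newick fragment per active node
  rep_lab <- labs       # representative (smallest) tip label, for tie-breaks
  act <- seq_len(n)
  D <- dm
  clamp_pair <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }
  while (length(act) > 3L) {
    na <- length(act)
    Dsub <- D[act, act]
    r <- rowSums(Dsub)
    Q <- (na - 2) * Dsub - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(rep_lab[act][cand[, 1]], rep_lab[act][cand[, 2]]),
                 pmax(rep_lab[act][cand[, 1]], rep_lab[act][cand[, 2]]))
    pick <- cand[order(key)[1], ]
    i <- act[pick[1]]; j <- act[pick[2]]
    dij <- D[i, j]
    bi <- dij / 2 + (r[pick[1]] - r[pick[2]]) / (2 * (na - 2))
    bj <- dij - bi
    b <- clamp_pair(bi, bj)
    new_d <- (D[i, act] + D[j, act] - dij) / 2
    u <- nrow(D) + 1L
    D <- rbind(cbind(D, 0), 0)
    D[u, act] <- new_d; D[act, u] <- new_d
    D[u, u] <- 0
    nwk <- c(nwk, sprintf("(%s:%.10g,%s:%.10g)", nwk[i], b[1], nwk[j], b[2]))
    rep_lab <- c(rep_lab, min(rep_lab[i], rep_lab[j]))
    act <- c(setdiff(act, c(i, j)), u)
  }
  a <- act[order(rep_lab[act])]
  da <- D[a[1], a[2]]; db <- D[a[1], a[3]]; dc <- D[a[2], a[3]]
  ba <- (da + db - dc) / 2
  bb <- (da + dc - db) / 2
  bc <- (db + dc - da) / 2
  bs <- pmax(c(ba, bb, bc), 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nwk[a[1]], bs[1], nwk[a[2]], bs[2], nwk[a[3]], bs[3])
  ape::read.tree(text = txt)
}

#' Bootstrap supports on a neighbor-joining tree
#'
#' Columns are resampled with replacement `n_boot` times (replicate `i`
#' reseeded with `seed + i`); each replicate alignment yields distances and
#' an NJ tree. The support of an internal branch of the original tree is the
#' percentage of replicate trees containing the same bipartition; branches
#' at or below 50 are flagged unsupported, and the majority-rule (>50%)
#' consensus topology is reported alongside.
#'
#' @param msa A `dna_msa` with at least 4 rows.
#' @param n_boot Bootstrap replicates (default 100; must be >= 2).
#' @param seed Integer seed.
#' @param model Distance model for [msa_distances()].
#' @return An `lr_phylo`: `tree` (node labels = integer percent supports),
#'   `supports`, `consensus` (>50% majority-rule tree), `n_boot`.
#' @export
bootstrap_support <- function(msa, n_boot = 100L, seed = 1L,
                              model = "jukes_cantor") {
  if (length(msa$seqs) < 4L) stop("need at least 4 taxa", call. = FALSE)
  if (n_boot < 2L) stop("n_boot must be >= 2", call. = FALSE)
  m <- as.matrix(msa)
  tree <- nj_tree(msa_distances(msa, model))
  boots <- vector("list", n_boot)
  for (i in seq_len(n_boot)) {
    set.seed(seed + i)
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    bm <- m[, cols, drop = FALSE]
    bmsa <- dna_msa(stats::setNames(apply(bm, 1, paste, collapse = ""),
                                    rownames(m)))
    boots[[i]] <- suppressWarnings(nj_tree(msa_distances(bmsa, model)))
  }
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- as.integer(round(100 * counts / n_boot))
  # the basal node carries the trivial all-taxa bipartition, not a branch
  trivial <- vapply(ape::prop.part(tree), length, integer(1)) ==
    length(tree$tip.label)
  supports[trivial] <- NA_integer_
  tree$node.label <- supports
  cons <- ape::consensus(boots, p = 0.5)
  structure(list(tree = tree, supports = supports, consensus = cons,
                 n_boot = as.integer(n_boot)), class = "lr_phylo")
}

#' @export
print.lr_phylo <- function(x, ...) {
  cat("lr_phylo: NJ tree on", length(x$tree$tip.label), "taxa,",
      x$n_boot, "bootstrap replicates\n")
  internal <- x$supports
  cat("  internal branch supports:", paste(internal, collapse = " "), "\n")
  cat("  bipartitions >50%:", sum(internal > 50), "\n")
  invisible(x)
}

#' Bootstrap support of a given leaf bipartition
#'
#' Convenience accessor: the support (0-100) of the branch separating
#' `group` from the remaining taxa, or `NA` when the original tree does not
#' contain that bipartition.
#'
#' @param phy An `lr_phylo`.
#' @param group Character vector of tip labels on one side.
#' @return Integer support percentage or `NA`.
#' @export
bipartition_support <- function(phy, group) {
  tree <- phy$tree
  tips <- tree$tip.label
  stopifnot(all(group %in% tips))
  target <- sort(group)
  other <- sort(setdiff(tips, group))
  # prop.part lists one clade per internal node, in node order, matching
  # the layout of the node labels set by bootstrap_support()
  bp <- ape::prop.part(tree)
  for (k in seq_along(bp)) {
    clade <- sort(tips[bp[[k]]])
    if (identical(clade, target) || identical(clade, other))
      return(phy$supports[k])
  }
  NA_integer_
}
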