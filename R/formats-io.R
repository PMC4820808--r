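#' Read a genome assembly from FASTA
#'
#' Sequences are uppercased, `U` is converted to `T`, and any residual
#' character outside `A/C/G/T/N` is replaced by `N` with a warning giving the
#' replacement count. Duplicate headers and empty files are errors.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] over the alphabet `{A,C,G,T,N}`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  # keep only the first whitespace-delimited token of each header
  names(raw) <- sub("\\s.*$", "", names(raw))
  dup <- names(raw)[duplicated(names(raw))]
  if (length(dup))
    stop("duplicate FASTA header(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  seqs <- toupper(as.character(raw))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  n_bad <- sum(vapply(seqs, function(s)
    nchar(gsub("[ACGTN]", "", s)), integer(1)))
  if (n_bad > 0L) {
    warning(n_bad, " non-ACGTN character(s) replaced by N", call. = FALSE)
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(raw)
  out
}

#' Write sequences to FASTA
#'
#' @param x A named `DNAStringSet`, or a named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read genomic intervals from BED or GTF
#'
#' BED (0-based half-open) and GTF (1-based closed) coordinates are converted
#' to the in-memory `GRanges` convention by rtracklayer; on re-export each
#' dialect's native convention is restored, so round-trips are exact. A strand
#' of `.`/absent becomes `*`. For GTF input, `gene_id` and a `biotype` column
#' (from `gene_type` or `gene_biotype` attributes, mapped onto
#' `lncRNA`/`mRNA`/`other`) are carried along when present.
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed"` or `"gtf"`.
#' @return A [GenomicRanges::GRanges].
#' @export
read_intervals <- function(path, dialect = c("bed", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  body <- which(!grepl("^(#|track|browser)", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (dialect == "bed") {
      if (length(f) < 3L) stop("BED line ", i, ": fewer than 3 fields", call. = FALSE)
      s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
      if (is.na(s) || is.na(e) || s >= e)
        stop("BED line ", i, ": invalid interval [", f[2], ", ", f[3], ")", call. = FALSE)
    } else {
      if (length(f) < 8L) stop("GTF line ", i, ": fewer than 8 fields", call. = FALSE)
      s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
      if (is.na(s) || is.na(e) || s > e)
        stop("GTF line ", i, ": invalid interval ", f[4], "..", f[5], call. = FALSE)
    }
  }
  gr <- rtracklayer::import(path, format = dialect)
  if (dialect == "gtf") {
    mc <- S4Vectors::mcols(gr)
    bt <- if ("gene_type" %in% names(mc)) mc$gene_type
          else if ("gene_biotype" %in% names(mc)) mc$gene_biotype
          else NULL
    if (!is.null(bt)) {
      S4Vectors::mcols(gr)$biotype <-
        ifelse(bt %in% c("lncRNA", "lincRNA"), "lncRNA",
               ifelse(bt %in% c("protein_coding", "mRNA"), "mRNA", "other"))
    }
  }
  gr
}

#' Write intervals to BED6
#'
#' Tab-separated, no header, 0-based half-open, file terminated by a newline.
#' The `name` and `score` columns are taken from the `GRanges` metadata when
#' present (`name`, `score`), else filled with `.`/`0`.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- rep(".", length(gr))
  sc <- S4Vectors::mcols(gr)$score
  if (is.null(sc)) sc <- rep(0L, length(gr))
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = nm, score = sc, strand = st)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read position frequency matrices in JASPAR plain-text format
#'
#' Each motif is a `>`-header line followed by four labelled rows (A, C, G, T)
#' of non-negative counts, with or without brackets. Rows of unequal width
#' within one motif are an error. An empty file yields an empty list.
#'
#' @param path Path to the PFM file.
#' @param background Base composition of the background model (A, C, G, T);
#'   defaults to uniform.
#' @return A list of `pfm` objects: `motif_id`, a 4 x W `counts` matrix with
#'   rownames A/C/G/T, and `background`.
#' @export
read_pfm <- function(path, background = rep(0.25, 4)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  stopifnot(length(background) == 4, all(background > 0))
  background <- background / sum(background)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  heads <- grep("^>", lines)
  if (!length(heads)) stop("not a JASPAR PFM file (no '>' headers): ", path,
                           call. = FALSE)
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    block <- lines[seq(heads[i] + 1L, bounds[i + 1L] - 1L)]
    if (length(block) != 4L)
      stop("motif ", id, ": expected 4 count rows, got ", length(block),
           call. = FALSE)
    rows <- lapply(block, function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("\\[|\\]", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    w <- lengths(rows)
    if (length(unique(w)) != 1L)
      stop("motif ", id, ": rows of unequal width (", paste(w, collapse = ","),
           ")", call. = FALSE)
    counts <- do.call(rbind, rows)
    if (any(counts < 0) || anyNA(counts))
      stop("motif ", id, ": counts must be non-negative numbers", call. = FALSE)
    rownames(counts) <- c("A", "C", "G", "T")
    out[[i]] <- structure(
      list(motif_id = id, counts = counts, background = background),
      class = "pfm")
  }
  out
}

#' @export
print.pfm <- function(x, ...) {
  cat("PFM", x$motif_id, "width", ncol(x$counts), "\n")
  print(x$counts)
  invisible(x)
}

#' Read / write phylogenetic trees in newick format
#'
#' Thin wrappers over \pkg{ape} fixing the package conventions: branch lengths
#' kept, integer bootstrap supports stored as internal node labels (read side
#' accepts unlabelled internals).
#'
#' @param path File path.
#' @return `read_newick` returns an ape `phylo`; `write_newick` returns
#'   `path` invisibly.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree An ape `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
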