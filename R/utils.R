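# Internal helpers shared across modules.

# Split a sequence string into a character vector of single bases.
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA string at a given GC content.
.random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.seqlengths_of <- function(assembly) {
  stats::setNames(Biostrings::width(assembly), names(assembly))
}

# GRanges constructor with seqlengths taken from an assembly.
.gr <- function(chrom, start, end, strand = "*", assembly = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  if (!is.null(assembly)) {
    sl <- .seqlengths_of(assembly)
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
  }
  gr
}

.stopifnot_assembly <- function(assembly) {
  if (!methods::is(assembly, "DNAStringSet"))
    stop("`assembly` must be a DNAStringSet (see read_fasta())", call. = FALSE)
  if (is.null(names(assembly)) || anyDuplicated(names(assembly)))
    stop("assembly sequences must have unique names", call. = FALSE)
}

# Extract genome subsequence as a plain string, honouring strand.
.extract_seq <- function(assembly, chrom, start, end, strand = "+") {
  s <- as.character(Biostrings::subseq(assembly[[chrom]], start, end))
  if (identical(strand, "-")) s <- .revcomp(s)
  s
}
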