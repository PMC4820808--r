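# Genome-wide mapping of family consensi, LOCAL vs DISPERSED classification by
# the locality fraction, and per-gene length-normalized repeat burdens.

#' Map a consensus sequence genome-wide
#'
#' Seed-and-extend search on both strands: exact `k_map`-mer seeds from the
#' consensus locate candidate windows (grouped by diagonal), which are then
#' aligned locally against the consensus (match +1, mismatch -1, gap open 4,
#' gap extend 1). Hits are reported when identity is at least `min_identity`
#' and the aligned consensus length is at least `min_len_frac` of the
#' consensus; overlapping hits are merged keeping the best identity.
#'
#' @param assembly `DNAStringSet` genome.
#' @param consensus Nucleotide string (length >= `2 * k_map`).
#' @param k_map Seed length (default 12).
#' @param min_identity Identity threshold (default 0.7).
#' @param min_len_frac Minimum aligned fraction of the consensus
#'   (default 0.5).
#' @return `GRanges` of hits with `identity` metadata (strand-aware).
#' @export
map_consensus <- function(assembly, consensus, k_map = 12L,
                          min_identity = 0.7, min_len_frac = 0.5) {
  .stopifnot_assembly(assembly)
  L <- nchar(consensus)
  if (L < 2L * k_map)
    stop("consensus shorter than 2 * k_map", call. = FALSE)
  sl <- .seqlengths_of(assembly)
  # full IUPAC matrix: masked-N stretches in candidate windows score
  # fractionally instead of erroring out
  submat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = FALSE)

  kmers_of <- function(s) {
    km <- substring(s, 1:(nchar(s) - k_map + 1L), k_map:nchar(s))
    ok <- !grepl("N", km, fixed = TRUE)
    list(km = km[ok], off = which(ok))
  }
  strands <- list(`+` = consensus, `-` = .revcomp(consensus))
  hits <- list()
  for (st in names(strands)) {
    ks <- kmers_of(strands[[st]])
    if (!length(ks$km)) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(ks$km))
    for (nm in names(assembly)) {
      mp <- Biostrings::matchPDict(pd, assembly[[nm]])
      starts <- unlist(lapply(seq_along(mp), function(i)
        IRanges::start(mp[[i]]) - (ks$off[i] - 1L)))
      if (!length(starts)) next
      # project the full consensus span on each seed diagonal, then merge
      proj <- IRanges::reduce(
        IRanges::IRanges(pmax(starts, 1L),
                         pmin(starts + L - 1L, sl[[nm]])),
        min.gapwidth = 50L)
      for (i in seq_along(proj)) {
        rs <- max(IRanges::start(proj)[i] - 20L, 1L)
        re <- min(IRanges::end(proj)[i] + 20L, sl[[nm]])
        region <- as.character(Biostrings::subseq(assembly[[nm]], rs, re))
        # a candidate window can hold several adjacent copies: take the best
        # local alignment, mask it out, and realign until nothing qualifies
        for (iter in seq_len(20L)) {
          pa <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(strands[[st]]), region, type = "local",
            substitutionMatrix = submat, gapOpening = 4, gapExtension = 1)
          pat_span <- Biostrings::width(Biostrings::pattern(pa))
          ident <- Biostrings::pid(pa, type = "PID1") / 100
          if (pat_span < min_len_frac * L || ident < min_identity) break
          sj <- Biostrings::subject(pa)
          s1 <- Biostrings::start(sj); s2 <- Biostrings::end(sj)
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = nm, start = rs + s1 - 1L, end = rs + s2 - 1L,
            strand = st, identity = ident)
          substr(region, s1, s2) <- strrep("N", s2 - s1 + 1L)
        }
      }
    }
  }
  if (!length(hits)) return(GenomicRanges::GRanges())
  df <- do.call(rbind, hits)
  gr <- .gr(df$chrom, df$start, df$end, df$strand, assembly = assembly)
  S4Vectors::mcols(gr)$identity <- df$identity
  # merge overlapping hits, keep best identity
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(gr, red, ignore.strand = TRUE)
  best <- vapply(split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov)),
                 function(i) i[which.max(S4Vectors::mcols(gr)$identity[i])],
                 integer(1))
  sort(gr[best], ignore.strand = TRUE)
}

#' Classify a repeat family as LOCAL or DISPERSED
#'
#' An instance is counted inside a locus when at least half of its bases
#' overlap the locus span (introns included). The host candidate is the locus
#' containing the most instances; the family is LOCAL when the fraction of
#' instances inside the host is at least `locality_min` (default 0.8, the
#' operational form of "at least 80% within the locus"). Outside instances
#' are annotated with two dispersal diagnostics: whether they are shorter
#' than the median in-locus instance, and the distance to their nearest
#' outside neighbour (flagged when above `far_sep`, default 250 kb). The
#' diagnostics are descriptive and never veto a LOCAL call.
#'
#' @param instances `GRanges` of mapped family instances (>= 2).
#' @param loci `GRanges` of gene annotations with a `gene_id` column.
#' @param locality_min LOCAL threshold on the locality fraction.
#' @param inside_frac Base-overlap fraction counting an instance as inside.
#' @param far_sep Pairwise-separation flag threshold in bp.
#' @param family_id Label carried into the call.
#' @return A `locality_call`: `family_id`, `call`, `host_locus`,
#'   `locality_fraction`, `n_instances`, `n_inside`, `outside` (per-instance
#'   diagnostic data.frame).
#' @export
classify_locality <- function(instances, loci, locality_min = 0.8,
                              inside_frac = 0.5, far_sep = 250000,
                              family_id = "family") {
  if (length(instances) < 2L)
    stop("need at least 2 instances to classify", call. = FALSE)
  n <- length(instances)
  res <- list(family_id = family_id, call = "DISPERSED",
              host_locus = NA_character_, locality_fraction = 0,
              n_instances = n, n_inside = 0L,
              outside = data.frame())
  if (length(loci) == 0L) {
    warning("no loci supplied; calling DISPERSED", call. = FALSE)
    return(structure(res, class = "locality_call"))
  }
  ov <- GenomicRanges::findOverlaps(instances, loci, ignore.strand = TRUE)
  if (length(ov)) {
    pint <- GenomicRanges::pintersect(
      instances[S4Vectors::queryHits(ov)], loci[S4Vectors::subjectHits(ov)],
      ignore.strand = TRUE)
    frac <- GenomicRanges::width(pint) /
      GenomicRanges::width(instances[S4Vectors::queryHits(ov)])
    ok <- frac >= inside_frac
    qh <- S4Vectors::queryHits(ov)[ok]; sh <- S4Vectors::subjectHits(ov)[ok]
    if (length(sh)) {
      cnt <- table(sh)
      host_i <- as.integer(names(cnt)[which.max(cnt)])
      in_host <- qh[sh == host_i]
      res$locality_fraction <- length(in_host) / n
      res$n_inside <- length(in_host)
      if (res$locality_fraction >= locality_min) {
        res$call <- "LOCAL"
        res$host_locus <- S4Vectors::mcols(loci)$gene_id[host_i]
      }
      out_idx <- setdiff(seq_len(n), in_host)
      if (length(out_idx)) {
        med_in <- stats::median(GenomicRanges::width(instances[in_host]))
        outs <- instances[out_idx]
        o_ch <- as.character(GenomeInfoDb::seqnames(outs))
        o_st <- GenomicRanges::start(outs); o_en <- GenomicRanges::end(outs)
        nearest <- vapply(seq_along(outs), function(i) {
          j <- setdiff(which(o_ch == o_ch[i]), i)
          if (!length(j)) return(Inf)
          # gap between intervals; 0 when overlapping or adjacent
          min(pmax(pmax(o_st[i] - o_en[j], o_st[j] - o_en[i]) - 1L, 0L))
        }, numeric(1))
        res$outside <- data.frame(
          chrom = as.character(GenomeInfoDb::seqnames(outs)),
          start = GenomicRanges::start(outs), end = GenomicRanges::end(outs),
          shorter_than_locus_median =
            GenomicRanges::width(outs) < med_in,
          nearest_outside_neighbor_distance = nearest,
          farther_than_threshold = nearest > far_sep)
      }
    }
  }
  structure(res, class = "locality_call")
}

#' @export
print.locality_call <- function(x, ...) {
  cat(sprintf("%s: %s (%d/%d instances in %s, locality %.2f)\n",
              x$family_id, x$call, x$n_inside, x$n_instances,
              ifelse(is.na(x$host_locus), "-", x$host_locus),
              x$locality_fraction))
  invisible(x)
}

#' Map and classify a list of repeat families
#'
#' Runs [map_consensus()] and [classify_locality()] for every family and
#' collects one call per family.
#'
#' @param families List of `repeat_family` objects.
#' @param genes Gene `GRanges` with `gene_id` (and ideally `biotype`).
#' @param assembly `DNAStringSet` genome.
#' @param ... Passed to [map_consensus()] and [classify_locality()]
#'   (`k_map`, `min_identity`, `min_len_frac`, `locality_min`,
#'   `inside_frac`, `far_sep`).
#' @return List with `calls` (data.frame: one row per family) and
#'   `instance_maps` (named list of `GRanges`).
#' @export
classify_families <- function(families, genes, assembly, k_map = 12L,
                              min_identity = 0.7, min_len_frac = 0.5,
                              locality_min = 0.8, inside_frac = 0.5,
                              far_sep = 250000) {
  maps <- list(); rows <- list()
  for (f in families) {
    hits <- map_consensus(assembly, f$consensus, k_map = k_map,
                          min_identity = min_identity,
                          min_len_frac = min_len_frac)
    maps[[f$family_id]] <- hits
    if (length(hits) < 2L) {
      rows[[f$family_id]] <- data.frame(
        family_id = f$family_id, call = "DISPERSED",
        host_locus = NA_character_, locality_fraction = 0,
        n_instances = length(hits), n_inside = 0L)
      next
    }
    lc <- classify_locality(hits, genes, locality_min = locality_min,
                            inside_frac = inside_frac, far_sep = far_sep,
                            family_id = f$family_id)
    rows[[f$family_id]] <- data.frame(
      family_id = lc$family_id, call = lc$call, host_locus = lc$host_locus,
      locality_fraction = lc$locality_fraction,
      n_instances = lc$n_instances, n_inside = lc$n_inside)
  }
  list(calls = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       instance_maps = maps)
}

#' Per-gene length-normalized repeat burdens
#'
#' For every gene: `n_lr` counts instances of LOCAL families lying inside the
#' gene (by the `inside_frac` base-overlap rule; set `count = "families"` to
#' count each hosted family once), `n_tr` counts tandem arrays overlapping
#' the gene, and both are normalized per kb of gene span. Instance lengths
#' and GC content are summarized per gene when the assembly is supplied.
#'
#' @param classification Result of [classify_families()].
#' @param arrays Tandem array `GRanges` (may be empty).
#' @param genes Gene `GRanges` with `gene_id`, `biotype`.
#' @param assembly Optional `DNAStringSet` for GC summaries.
#' @param count `"instances"` (default) or `"families"`.
#' @param inside_frac Base-overlap fraction counting an instance as inside.
#' @return A data.frame (class `repeat_burden`): `gene_id`, `biotype`,
#'   `length`, `n_lr`, `n_tr`, `lr_per_kb`, `tr_per_kb`, `mean_lr_len`,
#'   `median_lr_len`, `mean_lr_gc`.
#' @export
compute_burden <- function(classification, arrays, genes, assembly = NULL,
                           count = c("instances", "families"),
                           inside_frac = 0.5) {
  count <- match.arg(count)
  if (any(GenomicRanges::width(genes) <= 0))
    stop("zero-length gene", call. = FALSE)
  calls <- classification$calls
  maps <- classification$instance_maps
  ng <- length(genes)
  n_lr <- integer(ng); n_tr <- integer(ng)
  lr_len <- vector("list", ng); lr_gc <- vector("list", ng)
  local_fams <- calls$family_id[calls$call == "LOCAL"]
  for (fid in local_fams) {
    inst <- maps[[fid]]
    ov <- GenomicRanges::findOverlaps(inst, genes, ignore.strand = TRUE)
    if (!length(ov)) next
    pint <- GenomicRanges::pintersect(
      inst[S4Vectors::queryHits(ov)], genes[S4Vectors::subjectHits(ov)],
      ignore.strand = TRUE)
    frac <- GenomicRanges::width(pint) /
      GenomicRanges::width(inst[S4Vectors::queryHits(ov)])
    ok <- frac >= inside_frac
    qh <- S4Vectors::queryHits(ov)[ok]; sh <- S4Vectors::subjectHits(ov)[ok]
    for (g in unique(sh)) {
      ii <- qh[sh == g]
      n_lr[g] <- n_lr[g] + if (count == "instances") length(ii) else 1L
      w <- GenomicRanges::width(inst[ii])
      lr_len[[g]] <- c(lr_len[[g]], w)
      if (!is.null(assembly)) {
        gc <- vapply(ii, function(i) {
          s <- .extract_seq(assembly,
                            as.character(GenomeInfoDb::seqnames(inst))[i],
                            GenomicRanges::start(inst)[i],
                            GenomicRanges::end(inst)[i])
          b <- .chars(s)
          mean(b %in% c("G", "C"))
        }, numeric(1))
        lr_gc[[g]] <- c(lr_gc[[g]], gc)
      }
    }
  }
  if (length(arrays)) {
    ov <- GenomicRanges::findOverlaps(arrays, genes, ignore.strand = TRUE)
    tt <- table(factor(S4Vectors::subjectHits(ov), levels = seq_len(ng)))
    n_tr <- as.integer(tt)
  }
  len <- GenomicRanges::width(genes)
  out <- data.frame(
    gene_id = S4Vectors::mcols(genes)$gene_id,
    biotype = if (!is.null(S4Vectors::mcols(genes)$biotype))
      S4Vectors::mcols(genes)$biotype else NA_character_,
    length = len, n_lr = n_lr, n_tr = n_tr,
    lr_per_kb = n_lr / (len / 1000), tr_per_kb = n_tr / (len / 1000),
    mean_lr_len = vapply(lr_len, function(v)
      if (length(v)) mean(v) else NA_real_, numeric(1)),
    median_lr_len = vapply(lr_len, function(v)
      if (length(v)) stats::median(v) else NA_real_, numeric(1)),
    mean_lr_gc = vapply(lr_gc, function(v)
      if (length(v)) mean(v) else NA_real_, numeric(1)))
  class(out) <- c("repeat_burden", "data.frame")
  out
}
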