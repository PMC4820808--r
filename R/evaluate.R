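# Comparison of pipeline output against the planted ground truth of a
# simulation: family recovery, consensus identity, instance recall, locality
# correctness and tandem routing.

.consensus_identity <- function(a, b) {
  # ends-free alignment, best of both orientations
  submat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
  score1 <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
    substitutionMatrix = submat, gapOpening = 4, gapExtension = 1)
  score2 <- Biostrings::pairwiseAlignment(a, .revcomp(b), type = "overlap",
    substitutionMatrix = submat, gapOpening = 4, gapExtension = 1)
  best <- if (Biostrings::score(score1) >= Biostrings::score(score2))
    score1 else score2
  # identity over the planted consensus: matched bases / planted length
  Biostrings::nmatch(best) / nchar(a)
}

#' Score pipeline output against planted truth
#'
#' Matches each planted repeat family to the discovered family whose
#' instances best overlap its planted instances, then reports per-family
#' consensus identity (matched bases over planted consensus length,
#' orientation-free), instance recall, and the locality call of the matched
#' family. Tandem routing is scored as the fraction of planted tandem-array
#' base pairs covered by discovered families that were routed to the TR
#' catalogue (among planted tandem bases covered by any discovered family).
#'
#' @param sim An `lr_simulation`.
#' @param split Result of [split_tandem()] on the discovered families.
#' @param classification Result of [classify_families()] on the LR
#'   candidates.
#' @return A list: `families` (per planted family data.frame),
#'   `lr_recovery_rate`, `median_consensus_identity`,
#'   `dispersed_false_local`, `tandem_routing_fraction`.
#' @export
evaluate_recovery <- function(sim, split, classification) {
  truth <- sim$truth[sim$truth$kind == "family", , drop = FALSE]
  fam_cfg <- sim$config$families
  all_fams <- c(split$tr_catalog, split$lr_candidates)
  fam_ids <- vapply(all_fams, `[[`, "", "family_id")
  calls <- classification$calls

  inst_of <- function(f) f$instances
  rows <- list()
  for (i in seq_len(nrow(fam_cfg))) {
    pid <- fam_cfg$family_id[i]
    tt <- truth[truth$family_id == pid, , drop = FALSE]
    t_gr <- .gr(tt$chrom, tt$start, tt$end)
    # matched discovered family: most planted bases covered
    cover <- vapply(all_fams, function(f) {
      ov <- GenomicRanges::intersect(
        GenomicRanges::reduce(inst_of(f), ignore.strand = TRUE),
        GenomicRanges::reduce(t_gr), ignore.strand = TRUE)
      sum(GenomicRanges::width(ov))
    }, numeric(1))
    if (!length(cover) || max(cover) == 0) {
      rows[[pid]] <- data.frame(
        family_id = pid, host = fam_cfg$host[i], matched = NA_character_,
        consensus_identity = 0, instance_recall = 0, call = NA_character_)
      next
    }
    m <- which.max(cover)
    mf <- all_fams[[m]]
    cid <- .consensus_identity(as.character(sim$consensi[[pid]]), mf$consensus)
    ov <- GenomicRanges::findOverlaps(t_gr, inst_of(mf), ignore.strand = TRUE)
    hit <- unique(S4Vectors::queryHits(ov)[
      GenomicRanges::width(GenomicRanges::pintersect(
        t_gr[S4Vectors::queryHits(ov)],
        inst_of(mf)[S4Vectors::subjectHits(ov)], ignore.strand = TRUE)) >=
        0.5 * GenomicRanges::width(t_gr[S4Vectors::queryHits(ov)])])
    recall <- length(hit) / length(t_gr)
    call <- if (fam_ids[m] %in% calls$family_id)
      calls$call[calls$family_id == fam_ids[m]]
    else "TR"
    rows[[pid]] <- data.frame(
      family_id = pid, host = fam_cfg$host[i], matched = fam_ids[m],
      consensus_identity = cid, instance_recall = recall, call = call)
  }
  fam_tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  loc <- fam_tab[fam_tab$host == "local", , drop = FALSE]
  disp <- fam_tab[fam_tab$host == "dispersed", , drop = FALSE]
  recovered <- loc$consensus_identity >= 0.9 & !is.na(loc$call) &
    loc$call == "LOCAL"

  # tandem routing by planted-array base pairs
  t_arr <- GenomicRanges::reduce(IRanges::ranges(sim$tandem))
  bp_in <- function(fams) {
    if (!length(fams)) return(0)
    gr <- do.call(c, lapply(fams, function(f)
      GenomicRanges::reduce(f$instances, ignore.strand = TRUE)))
    sum(IRanges::width(IRanges::intersect(
      IRanges::reduce(IRanges::ranges(gr)), t_arr)))
  }
  tr_bp <- bp_in(split$tr_catalog)
  lr_bp <- bp_in(split$lr_candidates)
  routing <- if (tr_bp + lr_bp > 0) tr_bp / (tr_bp + lr_bp) else NA_real_

  list(families = fam_tab,
       lr_recovery_rate = mean(recovered),
       median_consensus_identity = stats::median(loc$consensus_identity),
       median_instance_recall = stats::median(loc$instance_recall),
       dispersed_false_local = sum(!is.na(disp$call) & disp$call == "LOCAL"),
       tandem_routing_fraction = routing)
}
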