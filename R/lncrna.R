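#' Four-predictor consensus of noncoding calls
#'
#' A transcript is accepted as noncoding only when all four coding-potential
#' predictors label it noncoding (the Venn-diagram intersection of the four
#' tools' noncoding sets). A transcript absent from a table is treated as
#' coding by that tool (and counted in a message).
#'
#' @param tables List of exactly four [tool_call_table()] objects.
#' @return Character vector of transcript_ids called noncoding by all four
#'   tools.
#' @export
consensus_noncoding <- function(tables) {
  if (length(tables) != 4)
    stop("consensus requires exactly 4 tool call tables, got ",
         length(tables))
  if (!all(vapply(tables, inherits, logical(1), "ToolCallTable")))
    stop("all elements must be ToolCallTable objects")
  universe <- unique(unlist(lapply(tables, function(t) names(t$calls))))
  if (length(universe) == 0) return(character(0))
  nmiss <- 0L
  keep <- rep(TRUE, length(universe))
  for (t in tables) {
    lab <- t$calls[universe]
    nmiss <- nmiss + sum(is.na(lab))
    keep <- keep & !is.na(lab) & lab == "noncoding"
  }
  if (nmiss > 0)
    message(nmiss, " transcript-table entries missing; treated as coding")
  universe[keep]
}

#' Structural discard rules for candidate lncRNA transcripts
#'
#' Applies the structural filters that define retained lncRNA candidates:
#' \describe{
#'   \item{too_short}{transcript length < `min_length` nt (default 200);}
#'   \item{coding_overlap}{the candidate's gene span intersects a
#'     protein-coding gene span (same strand by default);}
#'   \item{too_close}{gap to the nearest gene of a whitelisted biotype is
#'     positive but < `min_distance` bp (default 1,000); candidates
#'     overlapping a gene (gap 0) are exempt here because overlap is
#'     already handled by `coding_overlap`.}
#' }
#'
#' @param candidates Character vector of transcript_ids (typically the
#'   output of [consensus_noncoding()]).
#' @param ann An [annotation_set()] containing every candidate transcript.
#' @param min_length Minimum transcript length in nt.
#' @param min_distance Minimum gap to the nearest neighbouring gene in bp.
#' @param neighbour_biotypes Biotype whitelist for the distance rule.
#' @param same_strand_overlap If `TRUE` (default) the coding-overlap rule
#'   only considers protein-coding genes on the candidate's strand.
#' @return data.frame with columns transcript_id, gene_id, length_nt,
#'   distance_bp, discard_reasons (comma-separated, "" when retained),
#'   retained.
#' @export
apply_structural_filters <- function(candidates, ann,
                                     min_length = 200,
                                     min_distance = 1000,
                                     neighbour_biotypes = "protein_coding",
                                     same_strand_overlap = TRUE) {
  stopifnot(inherits(ann, "AnnotationSet"))
  tx <- ann$transcripts
  miss <- setdiff(candidates, tx$transcript_id)
  if (length(miss))
    stop("candidate transcripts absent from annotation: ",
         paste(miss, collapse = ", "))
  rownames(tx) <- tx$transcript_id
  cand <- tx[candidates, ]
  g <- ann$genes[cand$gene_id, ]
  coding <- ann$genes[ann$genes$biotype == "protein_coding", , drop = FALSE]
  cod_gr <- GenomicRanges::GRanges(
    coding$chrom, IRanges::IRanges(coding$start, coding$end),
    strand = coding$strand)
  names(cod_gr) <- coding$gene_id
  res <- lapply(seq_len(nrow(cand)), function(i) {
    reasons <- character(0)
    if (cand$length_nt[i] < min_length) reasons <- c(reasons, "too_short")
    gi <- g[i, ]
    gr <- GenomicRanges::GRanges(
      gi$chrom, IRanges::IRanges(gi$start, gi$end), strand = gi$strand)
    ov <- GenomicRanges::countOverlaps(
      gr, cod_gr[names(cod_gr) != gi$gene_id],
      ignore.strand = !same_strand_overlap)
    if (ov > 0) reasons <- c(reasons, "coding_overlap")
    d <- distance_to_nearest_gene(ann, gi, biotypes = neighbour_biotypes)
    if (!is.na(d) && d > 0 && d < min_distance)
      reasons <- c(reasons, "too_close")
    list(reasons = reasons, d = d)
  })
  data.frame(
    transcript_id = cand$transcript_id,
    gene_id = cand$gene_id,
    length_nt = cand$length_nt,
    distance_bp = vapply(res, function(r) as.integer(r$d), integer(1)),
    discard_reasons = vapply(res, function(r)
      paste(r$reasons, collapse = ","), character(1)),
    retained = vapply(res, function(r) length(r$reasons) == 0, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Full candidate lncRNA screen
#'
#' Combines the four-tool consensus with the structural filters over the
#' whole transcript universe of the four tables, recording a
#' `not_consensus` reason for transcripts that fail the Venn intersection.
#' Transcripts of protein-coding genes are excluded from the universe.
#'
#' @param tables List of four [tool_call_table()] objects.
#' @param ann An [annotation_set()].
#' @param ... Passed to [apply_structural_filters()].
#' @return data.frame as for [apply_structural_filters()], with
#'   `not_consensus` added to `discard_reasons` where applicable.
#' @export
screen_lncrnas <- function(tables, ann, ...) {
  universe <- unique(unlist(lapply(tables, function(t) names(t$calls))))
  universe <- intersect(universe, ann$transcripts$transcript_id)
  tx <- ann$transcripts
  rownames(tx) <- tx$transcript_id
  bio <- ann$genes[tx[universe, "gene_id"], "biotype"]
  universe <- universe[bio != "protein_coding"]
  if (length(universe) == 0)
    return(data.frame(transcript_id = character(0), gene_id = character(0),
                      length_nt = integer(0), distance_bp = integer(0),
                      discard_reasons = character(0),
                      retained = logical(0)))
  cons <- consensus_noncoding(tables)
  out <- apply_structural_filters(universe, ann, ...)
  nc <- out$transcript_id %in% cons
  out$discard_reasons[!nc] <- ifelse(
    nzchar(out$discard_reasons[!nc]),
    paste(out$discard_reasons[!nc], "not_consensus", sep = ","),
    "not_consensus")
  out$retained <- out$retained & nc
  out
}

#' Counts of exclusive Venn regions for up to four sets
#'
#' @param sets Named list of 2-4 character vectors.
#' @return data.frame with columns `region` (set names joined by `&`) and
#'   `count`; the counts over all exclusive regions sum to the size of the
#'   union.
#' @export
venn_counts <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list")
  k <- length(sets)
  if (k < 2 || k > 4) stop("venn_counts supports 2-4 sets, got ", k)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  region <- apply(combos, 1, function(z)
    paste(names(sets)[as.logical(z)], collapse = "&"))
  count <- apply(combos, 1, function(z)
    sum(apply(member, 1, function(m) all(m == as.logical(z)))))
  data.frame(region = region, count = as.integer(count),
             row.names = NULL, stringsAsFactors = FALSE)
}
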