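#' Gene-model annotation sets
#'
#' An `AnnotationSet` holds one record per gene (span, strand, biotype,
#' exonic length) together with its transcripts and exon intervals, plus a
#' `GenomicRanges` index used for window and distance queries. Coordinates
#' are 1-based and inclusive (GTF convention); BED input is converted on
#' read. The exonic length of a gene is the length of the union of its exon
#' intervals, so overlapping exons are not double-counted; a transcript's
#' length is the sum of its own exon lengths.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`, `exon_length`.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `length_nt`.
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @return An object of class `AnnotationSet`.
#' @export
annotation_set <- function(genes, transcripts, exons) {
  stopifnot(is.data.frame(genes), is.data.frame(transcripts),
            is.data.frame(exons))
  need <- c("gene_id", "chrom", "start", "end", "strand", "biotype",
            "exon_length")
  if (!all(need %in% names(genes)))
    stop("genes is missing columns: ",
         paste(setdiff(need, names(genes)), collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "))
  bad <- genes$end < genes$start
  if (any(bad))
    stop("gene span with end < start: ",
         paste(genes$gene_id[bad], collapse = ", "))
  if (any(genes$exon_length < 1))
    stop("gene with exonic length < 1 bp: ",
         paste(genes$gene_id[genes$exon_length < 1], collapse = ", "))
  known <- c("protein_coding", "lncRNA", "candidate", "other")
  if (!all(genes$biotype %in% known)) {
    odd <- unique(genes$biotype[!genes$biotype %in% known])
    warning("unknown biotype(s) mapped to 'other': ",
            paste(odd, collapse = ", "))
    genes$biotype[!genes$biotype %in% known] <- "other"
  }
  rownames(genes) <- genes$gene_id
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  names(gr) <- genes$gene_id
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 gr = gr),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  tab <- table(x$genes$biotype)
  cat("AnnotationSet:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  cat("  biotypes:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of genes in an annotation set
#' @param x An `AnnotationSet`.
#' @export
length.AnnotationSet <- function(x) nrow(x$genes)

# Ensembl-style GTF attribute extraction: key "value";
gtf_attr <- function(attrs, key) {
  pat <- paste0('(^|; ?)', key, ' "([^"]*)"')
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(g) if (length(g) >= 3) g[3] else NA_character_,
         character(1))
}

#' Read genome annotation from GTF or BED12
#'
#' Parses an Ensembl-dialect GTF (attributes `gene_id`, `transcript_id` and
#' a biotype key, default `gene_biotype`) or a BED12 file into an
#' [annotation_set()]. For GTF, exon records define transcripts and the
#' per-gene exon union; gene spans are the min/max over transcripts. For
#' BED12 each line is one transcript treated as its own gene (`name` column
#' = identifier), with `blockSizes` giving the exon lengths; biotypes are
#' supplied through `biotype_map` since BED carries none.
#'
#' @param path File to read.
#' @param format `"gtf"` or `"bed12"`.
#' @param biotype_attr GTF attribute key carrying the gene biotype.
#' @param biotype_map Optional named character vector mapping gene_id to
#'   biotype (used for BED12, or to override GTF biotypes).
#' @return An `AnnotationSet`.
#' @export
read_annotation <- function(path, format = c("gtf", "bed12"),
                            biotype_attr = "gene_biotype",
                            biotype_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "gtf") {
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(lines)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 9)) {
      lineno <- which(keep)[which(nf != 9)[1]]
      stop("malformed GTF record (", nf[which(nf != 9)[1]],
           " fields, expected 9) at line ", lineno)
    }
    st <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
    en <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
    bad <- is.na(st) | is.na(en) | en < st
    if (any(bad))
      stop("malformed GTF coordinates (end < start or non-numeric) at line ",
           which(keep)[which(bad)[1]])
    feat <- vapply(fields, `[[`, "", 3L)
    ex <- which(feat == "exon")
    if (length(ex) == 0) stop("GTF contains no exon records: ", path)
    attrs <- vapply(fields[ex], `[[`, "", 9L)
    exons <- data.frame(
      transcript_id = gtf_attr(attrs, "transcript_id"),
      gene_id = gtf_attr(attrs, "gene_id"),
      chrom = vapply(fields[ex], `[[`, "", 1L),
      start = st[ex], end = en[ex],
      strand = vapply(fields[ex], `[[`, "", 7L),
      stringsAsFactors = FALSE)
    if (anyNA(exons$gene_id) || anyNA(exons$transcript_id))
      stop("exon record without gene_id/transcript_id attribute in ", path)
    bio <- gtf_attr(attrs, biotype_attr)
    gene_bio <- tapply(bio, exons$gene_id, function(b) {
      b <- b[!is.na(b)]
      if (length(b)) b[1] else "other"
    })
  } else {
    bed <- rtracklayer::import(path, format = "bed")
    if (is.null(bed$blocks))
      stop("BED input lacks block (exon) structure; BED12 required: ", path)
    ids <- bed$name
    if (is.null(ids) || anyNA(ids)) stop("BED12 lines must carry a name")
    blk <- bed$blocks  # IRangesList, relative to each line's start
    exl <- as.data.frame(blk)
    off <- GenomicRanges::start(bed)[exl$group] - 1L
    exons <- data.frame(
      transcript_id = ids[exl$group],
      gene_id = ids[exl$group],
      chrom = as.character(GenomicRanges::seqnames(bed))[exl$group],
      start = exl$start + off, end = exl$end + off,
      strand = as.character(GenomicRanges::strand(bed))[exl$group],
      stringsAsFactors = FALSE)
    gene_bio <- setNames(rep("other", length(ids)), ids)
  }
  if (!is.null(biotype_map)) {
    hit <- intersect(names(biotype_map), names(gene_bio))
    gene_bio[hit] <- biotype_map[hit]
  }
  build_annotation_from_exons(exons, unlist(gene_bio))
}

# Assemble an AnnotationSet from an exon table + per-gene biotypes.
build_annotation_from_exons <- function(exons, gene_bio) {
  exons$strand[!exons$strand %in% c("+", "-")] <- "+"
  tx_len <- tapply(exons$end - exons$start + 1L, exons$transcript_id, sum)
  tx_gene <- exons$gene_id[!duplicated(exons$transcript_id)]
  names(tx_gene) <- exons$transcript_id[!duplicated(exons$transcript_id)]
  transcripts <- data.frame(
    transcript_id = names(tx_len),
    gene_id = unname(tx_gene[names(tx_len)]),
    length_nt = as.integer(tx_len),
    stringsAsFactors = FALSE)
  egr <- GenomicRanges::GRanges(exons$chrom,
                                IRanges::IRanges(exons$start, exons$end))
  union_len <- sum(GenomicRanges::width(GenomicRanges::reduce(
    S4Vectors::split(egr, exons$gene_id))))
  gid <- names(union_len)
  first <- !duplicated(exons$gene_id)
  meta <- exons[first, c("gene_id", "chrom", "strand")]
  rownames(meta) <- meta$gene_id
  genes <- data.frame(
    gene_id = gid,
    chrom = meta[gid, "chrom"],
    start = as.integer(tapply(exons$start, exons$gene_id, min)[gid]),
    end = as.integer(tapply(exons$end, exons$gene_id, max)[gid]),
    strand = meta[gid, "strand"],
    biotype = ifelse(is.na(gene_bio[gid]), "other",
                     unname(gene_bio[gid])),
    exon_length = as.integer(union_len),
    stringsAsFactors = FALSE)
  annotation_set(genes, transcripts, exons)
}

#' Write an annotation set as GTF
#'
#' Emits gene, transcript and exon records with `gene_id`,
#' `transcript_id` and `gene_biotype` attributes; [read_annotation()]
#' round-trips gene identifiers, coordinates, strand and biotype.
#'
#' @param ann An `AnnotationSet`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "AnnotationSet"))
  g <- ann$genes
  tx <- ann$transcripts
  ex <- ann$exons
  gl <- sprintf(
    '%s\tlncTFnet\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
    g$chrom, g$start, g$end, g$strand, g$gene_id, g$biotype)
  tg <- g[tx$gene_id, ]
  txs <- tapply(ex$start, ex$transcript_id, min)[tx$transcript_id]
  txe <- tapply(ex$end, ex$transcript_id, max)[tx$transcript_id]
  tl <- sprintf(
    paste0('%s\tlncTFnet\ttranscript\t%d\t%d\t.\t%s\t.\t',
           'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";'),
    tg$chrom, as.integer(txs), as.integer(txe), tg$strand, tx$gene_id,
    tx$transcript_id, tg$biotype)
  eg <- g[ex$gene_id, ]
  el <- sprintf(
    paste0('%s\tlncTFnet\texon\t%d\t%d\t.\t%s\t.\t',
           'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";'),
    ex$chrom, ex$start, ex$end, ex$strand, ex$gene_id, ex$transcript_id,
    eg$biotype)
  writeLines(c(gl, tl, el), path)
  invisible(path)
}

resolve_anchor <- function(ann, anchor) {
  if (is.character(anchor) && length(anchor) == 1) {
    if (!anchor %in% ann$genes$gene_id)
      stop("anchor gene not in annotation: ", anchor)
    return(ann$genes[anchor, ])
  }
  if (is.data.frame(anchor) && nrow(anchor) == 1) return(anchor)
  stop("anchor must be a gene_id or a one-row gene data.frame")
}

#' Genes within a symmetric window around an anchor gene
#'
#' Returns every other gene on the anchor's chromosome whose span
#' intersects `[start - window_bp, end + window_bp]` of the anchor span.
#' Strand is ignored: the window extends both upstream and downstream.
#' This is the co-location primitive behind cis-target calling (default
#' window in the pipeline: 100 kb).
#'
#' @param ann An `AnnotationSet`.
#' @param anchor A gene_id present in `ann`, or a one-row gene data.frame.
#' @param window_bp Non-negative window size in bp.
#' @return The `genes` rows of the co-located genes (possibly 0 rows).
#' @export
genes_within_window <- function(ann, anchor, window_bp) {
  stopifnot(inherits(ann, "AnnotationSet"),
            is.numeric(window_bp), window_bp >= 0)
  a <- resolve_anchor(ann, anchor)
  if (!a$chrom %in% ann$genes$chrom)
    stop("anchor chromosome absent from annotation: ", a$chrom)
  win <- GenomicRanges::GRanges(
    a$chrom,
    IRanges::IRanges(max(1L, a$start - as.integer(window_bp)),
                     a$end + as.integer(window_bp)))
  hits <- GenomicRanges::findOverlaps(win, ann$gr, ignore.strand = TRUE)
  idx <- S4Vectors::subjectHits(hits)
  out <- ann$genes[idx, , drop = FALSE]
  out[out$gene_id != a$gene_id, , drop = FALSE]
}

#' Distance to the nearest other gene
#'
#' Gap in bp between the anchor gene's span and the closest other gene on
#' the same chromosome: the number of bases strictly between the two spans
#' (0 when they overlap or are book-ended). Returns `NA` when the anchor is
#' alone on its chromosome ("no neighbour").
#'
#' @param ann An `AnnotationSet`.
#' @param anchor A gene_id or one-row gene data.frame.
#' @param biotypes Optional character vector restricting which neighbour
#'   biotypes count (default: all genes).
#' @return Integer gap in bp, or `NA_integer_` if no neighbour exists.
#' @export
distance_to_nearest_gene <- function(ann, anchor, biotypes = NULL) {
  stopifnot(inherits(ann, "AnnotationSet"))
  a <- resolve_anchor(ann, anchor)
  g <- ann$genes
  sel <- g$chrom == a$chrom & g$gene_id != a$gene_id
  if (!is.null(biotypes)) sel <- sel & g$biotype %in% biotypes
  if (!any(sel)) return(NA_integer_)
  agr <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end))
  d <- GenomicRanges::distance(agr, ann$gr[sel], ignore.strand = TRUE)
  as.integer(min(d))
}
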