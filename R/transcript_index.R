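#' Build a transcript index from a GTF annotation
#'
#' Parses a GENCODE-dialect GTF (gene/transcript/exon/CDS features with
#' \code{transcript_id} attributes) into an index mapping genomic coordinates
#' to transcript/CDS space. Coordinates are 1-based inclusive on input (GTF
#' convention); internal arithmetic is 0-based half-open with conversions
#' only at parse/write boundaries.
#'
#' Transcripts without CDS features are kept but flagged \code{coding =
#' FALSE} and excluded from peptide generation. A coding transcript whose
#' total CDS length is not a multiple of three (annotation artifact) is kept
#' with \code{cds_mod3_ok = FALSE}; the trailing partial codon is trimmed at
#' translation time.
#'
#' @param gtf_path Path to a GTF file.
#' @param genome Optional \code{genome_sequence}; when supplied, annotated
#'   coordinates are checked against contig bounds.
#' @return An object of class \code{transcript_index}.
#' @export
load_annotation <- function(gtf_path, genome = NULL) {
  if (!file.exists(gtf_path)) stop("GTF not found: ", gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (!"transcript_id" %in% names(md)) stop("GTF lacks transcript_id attributes")
  type <- as.character(md$type)

  tx_rows <- which(type == "transcript")
  if (length(tx_rows) == 0) stop("GTF has no transcript features")
  tx_ids <- as.character(md$transcript_id[tx_rows])

  transcripts <- list()
  for (i in seq_along(tx_rows)) {
    r <- tx_rows[i]
    tid <- tx_ids[i]
    gid <- as.character(md$gene_id[r])
    sym <- if ("gene_name" %in% names(md) && !is.na(md$gene_name[r])) {
      as.character(md$gene_name[r])
    } else gid  # gene_symbol falls back to gene_id
    transcripts[[tid]] <- list(
      transcript_id = tid, gene_id = gid, gene_symbol = sym,
      contig = as.character(GenomicRanges::seqnames(gr)[r]),
      strand = as.character(GenomicRanges::strand(gr)[r]),
      exons = data.frame(start = integer(0), end = integer(0)),
      cds = data.frame(start = integer(0), end = integer(0), phase = integer(0)),
      coding = FALSE, cds_len = 0L, cds_mod3_ok = TRUE
    )
  }

  add_feature <- function(kind) {
    rows <- which(type == kind)
    for (r in rows) {
      tid <- as.character(md$transcript_id[r])
      if (is.null(transcripts[[tid]])) {
        stop(kind, " feature references unknown transcript: ", tid)
      }
      ph <- if (kind == "CDS" && "phase" %in% names(md)) {
        p <- md$phase[r]
        if (is.na(p)) 0L else as.integer(p)
      } else 0L
      row <- data.frame(start = GenomicRanges::start(gr)[r],
                        end = GenomicRanges::end(gr)[r])
      if (kind == "CDS") row$phase <- ph
      fld <- if (kind == "CDS") "cds" else "exons"
      transcripts[[tid]][[fld]] <<- rbind(transcripts[[tid]][[fld]], row)
    }
  }
  add_feature("exon")
  add_feature("CDS")

  for (tid in names(transcripts)) {
    tx <- transcripts[[tid]]
    if (nrow(tx$exons) > 0) tx$exons <- tx$exons[order(tx$exons$start), , drop = FALSE]
    if (nrow(tx$cds) > 0) {
      # order 5'->3' in transcript direction
      ord <- order(tx$cds$start, decreasing = (tx$strand == "-"))
      tx$cds <- tx$cds[ord, , drop = FALSE]
      rownames(tx$cds) <- NULL
      # every CDS segment must lie inside some exon
      for (k in seq_len(nrow(tx$cds))) {
        inside <- any(tx$exons$start <= tx$cds$start[k] & tx$exons$end >= tx$cds$end[k])
        if (!inside) stop("CDS segment outside exons for transcript ", tid)
      }
      if (!all(tx$cds$phase %in% 0:2)) stop("invalid CDS phase for transcript ", tid)
      tx$cds_len <- sum(tx$cds$end - tx$cds$start + 1L)
      tx$coding <- TRUE
      tx$cds_mod3_ok <- (tx$cds_len %% 3L == 0L)
      if (tx$cds_len < 3L) stop("coding transcript with CDS length < 3: ", tid)
    }
    if (!is.null(genome)) {
      if (!tx$contig %in% names(genome$lengths)) {
        stop("transcript ", tid, " on contig absent from genome: ", tx$contig)
      }
      if (nrow(tx$exons) > 0 && max(tx$exons$end) > genome$lengths[[tx$contig]]) {
        stop("transcript ", tid, " extends beyond contig ", tx$contig)
      }
    }
    class(tx) <- "transcript_model"
    transcripts[[tid]] <- tx
  }

  coding_ids <- names(transcripts)[vapply(transcripts, function(t) t$coding, logical(1))]
  if (length(coding_ids) > 0) {
    segs <- do.call(rbind, lapply(coding_ids, function(tid) {
      tx <- transcripts[[tid]]
      data.frame(contig = tx$contig, start = tx$cds$start, end = tx$cds$end,
                 transcript_id = tid, stringsAsFactors = FALSE)
    }))
    cds_gr <- GenomicRanges::GRanges(
      seqnames = segs$contig,
      ranges = IRanges::IRanges(start = segs$start, end = segs$end),
      transcript_id = segs$transcript_id)
  } else {
    cds_gr <- GenomicRanges::GRanges()
  }

  idx <- list(transcripts = transcripts, cds_gr = cds_gr,
              contigs = unique(vapply(transcripts, function(t) t$contig, character(1))))
  class(idx) <- "transcript_index"
  idx
}

#' Genomic coordinate of every CDS base, in transcript order
#'
#' Returns the 1-based genomic coordinate of each spliced CDS position
#' (offsets \code{0..L-1}, 5' to 3'). The workhorse for breakpoint mapping.
#'
#' @param transcript A \code{transcript_model}.
#' @return Integer vector of length \code{cds_len}.
#' @export
cds_genomic_coords <- function(transcript) {
  stopifnot(inherits(transcript, "transcript_model"), transcript$coding)
  segs <- transcript$cds
  coords <- unlist(lapply(seq_len(nrow(segs)), function(k) {
    if (transcript$strand == "+") segs$start[k]:segs$end[k] else segs$end[k]:segs$start[k]
  }))
  as.integer(coords)
}

#' Map a genomic position into spliced CDS space
#'
#' @param transcript A coding \code{transcript_model}.
#' @param pos 1-based genomic coordinate.
#' @return 0-based offset into the spliced CDS, or \code{NA_integer_} when
#'   \code{pos} falls in an intron, UTR or outside the transcript.
#' @export
map_genomic_to_cds <- function(transcript, pos) {
  coords <- cds_genomic_coords(transcript)
  m <- match(pos, coords)
  if (is.na(m)) NA_integer_ else m - 1L
}

#' Extract the spliced wild-type CDS of a transcript
#'
#' Concatenates CDS segments 5' to 3' and reverse-complements on the minus
#' strand. When the annotated CDS length is not a multiple of three, a
#' warning is emitted and the sequence returned untrimmed (the transcript
#' carries \code{cds_mod3_ok = FALSE}).
#'
#' @param transcript A coding \code{transcript_model}.
#' @param genome A \code{genome_sequence}.
#' @return Uppercase DNA string.
#' @export
extract_cds <- function(transcript, genome) {
  stopifnot(inherits(transcript, "transcript_model"))
  if (!transcript$coding) stop("transcript is non-coding: ", transcript$transcript_id)
  segs <- transcript$cds[order(transcript$cds$start), , drop = FALSE]
  parts <- vapply(seq_len(nrow(segs)), function(k) {
    genome_subseq(genome, transcript$contig, segs$start[k] - 1L, segs$end[k])
  }, character(1))
  s <- paste0(parts, collapse = "")
  if (transcript$strand == "-") s <- revcomp(s)
  if (!transcript$cds_mod3_ok) {
    warning("CDS length of ", transcript$transcript_id,
            " is not a multiple of 3 (", nchar(s), " nt)")
  }
  s
}

#' Coding transcripts whose CDS intersects a genomic interval
#'
#' @param index A \code{transcript_index}.
#' @param contig Contig name (must be known to the index).
#' @param start,end 1-based inclusive genomic interval.
#' @return List of \code{transcript_model}, sorted by transcript_id.
#' @export
overlapping_transcripts <- function(index, contig, start, end) {
  stopifnot(inherits(index, "transcript_index"))
  if (!contig %in% index$contigs) stop("unknown contig: ", contig)
  if (length(index$cds_gr) == 0) return(list())
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, index$cds_gr)
  ids <- sort(unique(S4Vectors::mcols(index$cds_gr)$transcript_id[S4Vectors::subjectHits(hits)]))
  lapply(ids, function(tid) index$transcripts[[tid]])
}

#' @export
print.transcript_index <- function(x, ...) {
  n_coding <- sum(vapply(x$transcripts, function(t) t$coding, logical(1)))
  cat(sprintf("transcript_index: %d transcript(s), %d coding, contigs: %s\n",
              length(x$transcripts), n_coding, paste(x$contigs, collapse = ", ")))
  invisible(x)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s, %s strand, %s): %d exon(s), CDS %d nt%s\n",
              x$transcript_id, x$gene_symbol, x$strand, x$contig,
              nrow(x$exons), x$cds_len,
              if (x$coding) "" else " [non-coding]"))
  invisible(x)
}
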