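#' Classify an SV as frameshift or in-frame
#'
#' A gene-level frameshift annotation (AnnotSV-style), when available, takes
#' priority. Otherwise, single-event SVs are frameshift iff the net
#' coding-length change is not a multiple of three (\code{length_rule});
#' fusion events are frameshift iff the nucleotide length of the 5' (head)
#' segment is not divisible by three (\code{head_rule}).
#'
#' @param nt_value Net coding-length change in nt (single events) or head
#'   segment length in nt (fusions).
#' @param fusion Logical; is this a fusion (BND) event?
#' @param annotation Optional annotation string; values matching
#'   "frameshift"/"yes" or "in-frame"/"no" are honored, anything else falls
#'   through to the arithmetic rule.
#' @return List with \code{value} ("in_frame"/"frameshift") and
#'   \code{source} ("annotation"/"length_rule"/"head_rule").
#' @export
classify_frame <- function(nt_value, fusion = FALSE, annotation = NULL) {
  if (!is.null(annotation) && length(annotation) == 1 && !is.na(annotation)) {
    a <- tolower(annotation)
    if (grepl("frameshift|^yes$", a) && !grepl("no[_ -]?frameshift", a)) {
      return(list(value = "frameshift", source = "annotation"))
    }
    if (grepl("in[_ -]?frame|^no$", a)) {
      return(list(value = "in_frame", source = "annotation"))
    }
  }
  shifted <- (as.integer(nt_value) %% 3L) != 0L
  list(value = if (shifted) "frameshift" else "in_frame",
       source = if (fusion) "head_rule" else "length_rule")
}

#' @keywords internal
#' 0-based count of head-transcript CDS bases retained by a breakend.
retained_head_len <- function(transcript, pos, orientation) {
  coords <- cds_genomic_coords(transcript)
  need <- if (transcript$strand == "+") "left_of_join" else "right_of_join"
  if (orientation != need) {
    stop("breakend orientation does not retain the 5' end of ",
         transcript$transcript_id)
  }
  if (transcript$strand == "+") sum(coords <= pos) else sum(coords >= pos)
}

#' Reconstruct the mutant coding sequence for an (event, transcript) pair
#'
#' Applies the event to the spliced wild-type CDS of the head transcript in
#' transcript space:
#' \itemize{
#'   \item DEL: deleted span excised (clipped to CDS bases; a spanning
#'     deletion removes whole contained exon bases).
#'   \item DUP: tandem duplication, duplicated CDS bases repeated in place.
#'   \item INS: inserted sequence spliced at the CDS offset of the anchor
#'     (reverse-complemented on minus-strand transcripts).
#'   \item INV: CDS bases within the inverted span replaced by their reverse
#'     complement in transcript space; inversions that also cover intronic
#'     sequence reuse the wild-type splice structure and are flagged
#'     \code{simplified_splice}.
#'   \item BND: 5' head segment from the start codon to the head breakend,
#'     concatenated (in join orientation, via any micro-inserted bases) with
#'     the tail read in the frame implied by the head when the tail breakend
#'     lies in a coding transcript, else with genomic sequence downstream of
#'     the join up to \code{fusion_horizon} nt.
#' }
#' Junction offsets (0-based, into the mutant sequence) are recorded at
#' every novel adjacency. Breakends falling in intron/UTR of the head are
#' reconstructed with the junction at the nearest CDS boundary and a
#' \code{truncated} flag.
#'
#' @param event An \code{sv_event}.
#' @param head Head (5') coding \code{transcript_model}.
#' @param tail Optional tail \code{transcript_model} for fusions.
#' @param genome \code{genome_sequence}.
#' @param annotation Optional AnnotSV-style frameshift annotation string for
#'   this (event, gene); takes priority in frame classification.
#' @param fusion_horizon Max nt of genomic sequence appended when a fusion
#'   runs into non-coding territory (default 600 = 3 x 200 codons).
#' @return Object of class \code{mutant_cds}.
#' @export
reconstruct_mutant_cds <- function(event, head, tail = NULL, genome,
                                   annotation = NULL, fusion_horizon = 600L) {
  stopifnot(inherits(event, "sv_event"), inherits(head, "transcript_model"))
  wt <- suppressWarnings(extract_cds(head, genome))
  coords <- cds_genomic_coords(head)
  L <- nchar(wt)
  flags <- character(0)
  partner <- NA_character_

  substr0 <- function(s, from0, to0) {  # 0-based half-open
    if (to0 <= from0) "" else substr(s, from0 + 1L, to0)
  }

  if (event$sv_type %in% c("DEL", "DUP", "INV")) {
    a <- min(event$pos1, event$pos2) + 1L   # POS is the padding base
    b <- max(event$pos1, event$pos2)
    idx <- which(coords >= a & coords <= b)  # 1-based indices, transcript order
    if (length(idx) == 0) stop("event ", event$event_id, " touches no CDS base of ",
                               head$transcript_id)
    i1 <- min(idx); i2 <- max(idx)
    in1 <- !is.na(map_genomic_to_cds(head, event$pos1))
    in2 <- !is.na(map_genomic_to_cds(head, event$pos2))
    if (!(in1 && in2)) flags <- c(flags, "truncated")
    if ((b - a + 1L) != length(idx)) flags <- c(flags, "simplified_splice")
  }

  if (event$sv_type == "DEL") {
    seq <- paste0(substr0(wt, 0L, i1 - 1L), substr0(wt, i2, L))
    junctions <- i1 - 1L
    novel <- c(i1 - 1L, i1 - 1L)           # pure junction, no novel bases
    net <- -(i2 - i1 + 1L)
    if (i1 == 1L) flags <- c(flags, "no_start")
    fc <- classify_frame(net, fusion = FALSE, annotation = annotation)
  } else if (event$sv_type == "DUP") {
    ndup <- i2 - i1 + 1L
    dupseq <- substr0(wt, i1 - 1L, i2)
    seq <- paste0(substr0(wt, 0L, i2), dupseq, substr0(wt, i2, L))
    junctions <- c(i2, i2 + ndup)
    novel <- c(i2, i2 + ndup)              # the second copy
    net <- ndup
    fc <- classify_frame(net, fusion = FALSE, annotation = annotation)
  } else if (event$sv_type == "INV") {
    invseq <- revcomp(substr0(wt, i1 - 1L, i2))
    seq <- paste0(substr0(wt, 0L, i1 - 1L), invseq, substr0(wt, i2, L))
    junctions <- c(i1 - 1L, i2)
    novel <- c(i1 - 1L, i2)
    net <- 0L
    fc <- classify_frame(net, fusion = FALSE, annotation = annotation)
  } else if (event$sv_type == "INS") {
    o1 <- map_genomic_to_cds(head, event$pos1)
    if (is.na(o1)) stop("INS anchor of ", event$event_id, " outside CDS of ",
                        head$transcript_id)
    ins <- if (head$strand == "+") event$inserted_seq else revcomp(event$inserted_seq)
    p <- if (head$strand == "+") o1 + 1L else o1
    seq <- paste0(substr0(wt, 0L, p), ins, substr0(wt, p, L))
    junctions <- c(p, p + nchar(ins))
    novel <- c(p, p + nchar(ins))
    net <- nchar(ins)
    fc <- classify_frame(net, fusion = FALSE, annotation = annotation)
  } else if (event$sv_type == "BND") {
    if (isTRUE(event$unpaired)) stop("cannot reconstruct fusion from unpaired breakend ",
                                     event$event_id)
    ends <- list(list(contig = event$contig1, pos = event$pos1, orient = event$orient1),
                 list(contig = event$contig2, pos = event$pos2, orient = event$orient2))
    need <- if (head$strand == "+") "left_of_join" else "right_of_join"
    head_i <- which(vapply(ends, function(e) e$contig == head$contig &&
                             e$orient == need, logical(1)))
    if (length(head_i) == 0) stop("no breakend of ", event$event_id,
                                  " retains the 5' end of ", head$transcript_id)
    head_i <- head_i[1]
    hend <- ends[[head_i]]; tend <- ends[[3L - head_i]]
    head_len <- retained_head_len(head, hend$pos, hend$orient)
    if (is.na(map_genomic_to_cds(head, hend$pos))) flags <- c(flags, "truncated")
    if (head_len == 0L) flags <- c(flags, "no_start")
    head_seq <- substr0(wt, 0L, head_len)
    ins <- if (head$strand == "+") event$inserted_seq else revcomp(event$inserted_seq)

    tail_seq <- NULL
    if (!is.null(tail) && inherits(tail, "transcript_model") && tail$coding &&
        tail$contig == tend$contig) {
      tneed <- if (tail$strand == "+") "right_of_join" else "left_of_join"
      if (tend$orient == tneed) {
        tcoords <- cds_genomic_coords(tail)
        nret <- if (tail$strand == "+") sum(tcoords >= tend$pos) else sum(tcoords <= tend$pos)
        wt_tail <- suppressWarnings(extract_cds(tail, genome))
        tail_seq <- substr0(wt_tail, nchar(wt_tail) - nret, nchar(wt_tail))
        partner <- tail$transcript_id
      }
    }
    if (is.null(tail_seq)) {
      # genomic continuation downstream of the join, bounded horizon
      clen <- genome$lengths[[tend$contig]]
      if (tend$orient == "right_of_join") {
        tail_seq <- genome_subseq(genome, tend$contig, tend$pos - 1L,
                                  min(clen, tend$pos - 1L + fusion_horizon))
      } else {
        tail_seq <- revcomp(genome_subseq(genome, tend$contig,
                                          max(0L, tend$pos - fusion_horizon), tend$pos))
      }
      flags <- c(flags, "genomic_tail")
      partner <- NA_character_
    }
    seq <- paste0(head_seq, ins, tail_seq)
    junctions <- unique(c(head_len, head_len + nchar(ins)))
    novel <- c(head_len, head_len + nchar(ins))
    fc <- classify_frame(head_len, fusion = TRUE, annotation = annotation)
  } else {
    stop("unsupported SV type: ", event$sv_type)
  }

  len_mut <- nchar(seq)
  if (fc$value == "frameshift") novel <- c(min(junctions), len_mut)
  junctions <- sort(unique(junctions[junctions < len_mut & junctions >= 0]))

  out <- list(event_id = event$event_id, transcript_id = head$transcript_id,
              partner_transcript_id = partner, sv_type = event$sv_type,
              sequence = seq, wt_sequence = wt,
              junction_nt_offsets = as.integer(junctions),
              novel_region = as.integer(novel),
              frame_class = fc, flags = unique(flags))
  class(out) <- "mutant_cds"
  out
}

#' @export
print.mutant_cds <- function(x, ...) {
  cat(sprintf("mutant_cds %s/%s [%s, %s via %s]: %d nt (wt %d), junctions at %s%s\n",
              x$event_id, x$transcript_id, x$sv_type, x$frame_class$value,
              x$frame_class$source, nchar(x$sequence), nchar(x$wt_sequence),
              paste(x$junction_nt_offsets, collapse = ","),
              if (length(x$flags)) paste0(" flags=", paste(x$flags, collapse = "+")) else ""))
  invisible(x)
}

#' Translate a mutant CDS into protein with junction tracking
#'
#' Standard genetic code from position 0; translation halts at the first
#' stop codon. Frameshift sequences with no stop before the sequence end are
#' translated to the last full codon with \code{stopped = FALSE}. Junction
#' residues are \code{floor(o/3)} for each junction nt offset \code{o}
#' surviving before the stop; the trailing partial codon is dropped. An
#' internal stop upstream of the first junction yields a protein flagged
#' \code{junction_lost} (empty junction set).
#'
#' @param mutant A \code{mutant_cds}.
#' @return Object of class \code{mutant_protein}.
#' @export
translate_mutant <- function(mutant) {
  stopifnot(inherits(mutant, "mutant_cds"))
  if ("no_start" %in% mutant$flags) {
    stop("mutant CDS of ", mutant$event_id, " lost the start codon; not translated")
  }
  seq <- mutant$sequence
  if (nchar(seq) < 3) stop("mutant CDS shorter than one codon")
  ncod <- nchar(seq) %/% 3L
  trimmed <- substr(seq, 1L, ncod * 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(trimmed),
                                           no.init.codon = TRUE,
                                           if.fuzzy.codon = "solve"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  stopped <- stop_at > 0
  protein <- if (stopped) substr(aa, 1L, stop_at - 1L) else aa
  plen <- nchar(protein)

  jres <- unique(vapply(mutant$junction_nt_offsets, function(o) o %/% 3L, integer(1)))
  jres <- jres[jres < plen & jres >= 0]
  junction_lost <- length(mutant$junction_nt_offsets) > 0 && length(jres) == 0

  nr <- mutant$novel_region
  novel_res <- if (!is.null(nr) && nr[2] > nr[1]) {
    lo <- nr[1] %/% 3L
    hi <- (nr[2] - 1L) %/% 3L
    r <- lo:hi
    r[r < plen & r >= 0]
  } else integer(0)

  out <- list(sequence = protein,
              junction_residues = as.integer(sort(jres)),
              novel_residues = as.integer(novel_res),
              stopped = stopped, junction_lost = junction_lost,
              event_id = mutant$event_id, transcript_id = mutant$transcript_id,
              frame_class = mutant$frame_class, flags = mutant$flags)
  class(out) <- "mutant_protein"
  out
}

#' @export
print.mutant_protein <- function(x, ...) {
  cat(sprintf("mutant_protein %s/%s: %d aa, junction residues {%s}, stopped=%s%s\n",
              x$event_id, x$transcript_id, nchar(x$sequence),
              paste(x$junction_residues, collapse = ","), x$stopped,
              if (x$junction_lost) " [junction lost to upstream stop]" else ""))
  invisible(x)
}

#' Write a per-event reconstruction audit trail
#'
#' Traceability TSV: one row per reconstructed (event, transcript) with
#' frame class and its source, junction offsets and sequence lengths.
#'
#' @param mutants List of \code{mutant_cds}.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_audit_trail <- function(mutants, path) {
  df <- do.call(rbind, lapply(mutants, function(m) {
    data.frame(event_id = m$event_id, transcript_id = m$transcript_id,
               partner_transcript_id = m$partner_transcript_id,
               sv_type = m$sv_type,
               frame_class = m$frame_class$value, frame_source = m$frame_class$source,
               junction_nt_offsets = paste(m$junction_nt_offsets, collapse = ","),
               wt_len = nchar(m$wt_sequence), mutant_len = nchar(m$sequence),
               flags = paste(m$flags, collapse = "+"),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
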