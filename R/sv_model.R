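#' @keywords internal
info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1]]
  if (length(m) < 2) NA_character_ else m[2]
}

#' Decode a VCF breakend ALT string
#'
#' Decodes the four bracket forms of VCF breakend notation
#' (\code{t[p[}, \code{t]p]}, \code{]p]t}, \code{[p[t}) into the local join
#' orientation, the mate locus and orientation, and any micro-inserted bases
#' carried in the ALT beyond the REF base.
#'
#' Orientations are expressed as which side of the breakpoint is retained in
#' the derived allele: \code{left_of_join} (sequence up to and including the
#' position) or \code{right_of_join} (sequence from the position onward).
#'
#' @param alt Breakend ALT string.
#' @param ref REF allele (anchor base(s)).
#' @return A list with \code{local_orientation}, \code{mate_contig},
#'   \code{mate_pos}, \code{mate_orientation}, \code{inserted_seq}; or
#'   \code{NULL} if the ALT does not parse as breakend notation.
#' @export
decode_breakend_alt <- function(alt, ref) {
  m <- regmatches(alt, regexec("^([ACGTNacgtn]*)([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])([ACGTNacgtn]*)$",
                               alt, perl = TRUE))[[1]]
  if (length(m) == 0) return(NULL)
  seq_before <- m[2]; br1 <- m[3]; mate_contig <- m[4]
  mate_pos <- as.integer(m[5]); br2 <- m[6]; seq_after <- m[7]
  if (br1 != br2) return(NULL)
  has_before <- nzchar(seq_before); has_after <- nzchar(seq_after)
  if (has_before == has_after) return(NULL)  # exactly one side carries bases
  if (has_before) {
    # t[p[ or t]p] : local sequence extends leftward from here
    local_orientation <- "left_of_join"
    if (!startsWith(toupper(seq_before), toupper(ref))) return(NULL)
    inserted <- substring(seq_before, nchar(ref) + 1L)
    mate_orientation <- if (br1 == "[") "right_of_join" else "left_of_join"
  } else {
    # ]p]t or [p[t : local sequence extends rightward from here
    local_orientation <- "right_of_join"
    if (!endsWith(toupper(seq_after), toupper(ref))) return(NULL)
    inserted <- substring(seq_after, 1L, nchar(seq_after) - nchar(ref))
    mate_orientation <- if (br1 == "]") "left_of_join" else "right_of_join"
  }
  list(local_orientation = local_orientation, mate_contig = mate_contig,
       mate_pos = mate_pos, mate_orientation = mate_orientation,
       inserted_seq = toupper(inserted))
}

new_sv_event <- function(event_id, sv_type, contig1, pos1, orient1,
                         contig2 = NA_character_, pos2 = NA_integer_,
                         orient2 = NA_character_, inserted_seq = "",
                         filter_status = "PASS", mate_id = NA_character_,
                         unpaired = FALSE) {
  ev <- list(event_id = event_id, sv_type = sv_type,
             contig1 = contig1, pos1 = as.integer(pos1), orient1 = orient1,
             contig2 = contig2, pos2 = as.integer(pos2), orient2 = orient2,
             inserted_seq = inserted_seq, filter_status = filter_status,
             mate_id = mate_id, unpaired = unpaired,
             annotsv_frameshift = NULL)
  class(ev) <- "sv_event"
  ev
}

#' @export
print.sv_event <- function(x, ...) {
  loc2 <- if (is.na(x$pos2)) "" else sprintf(" -> %s:%d", x$contig2, x$pos2)
  cat(sprintf("sv_event %s [%s] %s:%d%s filter=%s%s\n", x$event_id, x$sv_type,
              x$contig1, x$pos1, loc2, x$filter_status,
              if (x$unpaired) " (unpaired breakend)" else ""))
  invisible(x)
}

#' Pair breakend records into fusion events
#'
#' Matches reciprocal \code{MATEID} pairs, derives the join orientation of
#' each side from the bracket direction and flanking-base side, and captures
#' micro-inserted bases between the breakends.
#'
#' @param records data.frame with columns \code{id, mate_id, contig, pos,
#'   alt, ref, filter}.
#' @return List of \code{sv_event} (paired BND events first, then unpaired
#'   singles flagged \code{unpaired = TRUE} with a warning).
#' @export
pair_breakends <- function(records) {
  if (nrow(records) == 0) return(list())
  if (any(records$id == records$mate_id, na.rm = TRUE)) {
    bad <- records$id[which(records$id == records$mate_id)]
    stop("self-mated breakend record(s): ", paste(bad, collapse = ", "))
  }
  key <- vapply(seq_len(nrow(records)), function(i) {
    paste(sort(c(records$id[i], records$mate_id[i])), collapse = "|")
  }, character(1))
  counts <- table(key)
  if (any(counts > 2)) {
    stop("breakend mate group with >2 records: ",
         paste(names(counts)[counts > 2], collapse = ", "))
  }
  events <- list()
  for (k in unique(key)) {
    rows <- records[key == k, , drop = FALSE]
    dec <- lapply(seq_len(nrow(rows)), function(i) decode_breakend_alt(rows$alt[i], rows$ref[i]))
    keep <- !vapply(dec, is.null, logical(1))
    rows <- rows[keep, , drop = FALSE]; dec <- dec[keep]
    if (nrow(rows) == 0) next
    if (nrow(rows) == 1) {
      warning("breakend ", rows$id[1], " has no mate record; retained unpaired")
      d <- dec[[1]]
      events[[length(events) + 1L]] <- new_sv_event(
        event_id = rows$id[1], sv_type = "BND",
        contig1 = rows$contig[1], pos1 = rows$pos[1], orient1 = d$local_orientation,
        contig2 = d$mate_contig, pos2 = d$mate_pos, orient2 = d$mate_orientation,
        inserted_seq = d$inserted_seq, filter_status = rows$filter[1],
        mate_id = rows$mate_id[1], unpaired = TRUE)
      next
    }
    # deterministic end order: lower (contig, pos) first
    ord <- order(rows$contig, rows$pos)
    rows <- rows[ord, , drop = FALSE]; dec <- dec[ord]
    events[[length(events) + 1L]] <- new_sv_event(
      event_id = paste(rows$id[1], rows$id[2], sep = "__"), sv_type = "BND",
      contig1 = rows$contig[1], pos1 = rows$pos[1], orient1 = dec[[1]]$local_orientation,
      contig2 = rows$contig[2], pos2 = rows$pos[2], orient2 = dec[[2]]$local_orientation,
      inserted_seq = dec[[1]]$inserted_seq, filter_status = rows$filter[1],
      mate_id = rows$id[2], unpaired = FALSE)
  }
  ord <- order(vapply(events, function(e) sprintf("%s:%010d", e$contig1, e$pos1), character(1)))
  events[ord]
}

#' Parse somatic SV calls from a VCF
#'
#' Reads a VCF (plain or bgzipped) of structural-variant calls: symbolic
#' ALTs (\code{<DEL>/<DUP>/<INS>/<INV>}) with \code{END} (or \code{SVLEN})
#' in INFO, explicit-sequence insertions, and paired breakend (BND) records
#' in bracket notation with \code{MATEID}. Breakend mates are merged into
#' one event. Only records with \code{FILTER = PASS} are retained by
#' default.
#'
#' Deletion semantics follow the VCF convention for symbolic ALTs: POS is
#' the last retained base and the affected interval is \code{POS+1 .. END}
#' (the same padding-base convention is applied to DUP and INV).
#'
#' @param vcf_path Path to the VCF.
#' @param pass_only Keep only FILTER=PASS records (default TRUE).
#' @return List of \code{sv_event}.
#' @export
parse_sv_vcf <- function(vcf_path, pass_only = TRUE) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- vcfR::getINFO(v)
  if (nrow(fx) == 0) return(list())
  fx$POS <- as.integer(fx$POS)
  fx$FILTER[is.na(fx$FILTER)] <- "."
  keep <- if (pass_only) fx$FILTER == "PASS" else rep(TRUE, nrow(fx))

  events <- list()
  bnd <- data.frame(id = character(0), mate_id = character(0), contig = character(0),
                    pos = integer(0), alt = character(0), ref = character(0),
                    filter = character(0), stringsAsFactors = FALSE)
  for (i in which(keep)) {
    alt <- fx$ALT[i]; ref <- fx$REF[i]
    rid <- if (!is.na(fx$ID[i]) && fx$ID[i] != ".") fx$ID[i] else {
      sprintf("sv_%s_%d", fx$CHROM[i], fx$POS[i])
    }
    if (grepl("\\[|\\]", alt)) {
      mate <- info_field(info[i], "MATEID")
      bnd <- rbind(bnd, data.frame(id = rid, mate_id = mate, contig = fx$CHROM[i],
                                   pos = fx$POS[i], alt = alt, ref = ref,
                                   filter = fx$FILTER[i], stringsAsFactors = FALSE))
      next
    }
    sym <- regmatches(alt, regexec("^<(DEL|DUP|INS|INV)>?", alt))[[1]]
    if (length(sym) >= 2) {
      type <- sym[2]
      end <- suppressWarnings(as.integer(info_field(info[i], "END")))
      if (is.na(end)) {
        svlen <- suppressWarnings(as.integer(info_field(info[i], "SVLEN")))
        if (!is.na(svlen) && type != "INS") end <- fx$POS[i] + abs(svlen)
      }
      if (type == "INS") {
        ins <- info_field(info[i], "SVINSSEQ")
        if (is.na(ins)) ins <- info_field(info[i], "SEQ")
        if (is.na(ins)) {
          warning("INS record ", rid, " lacks inserted sequence; skipped")
          next
        }
        events[[length(events) + 1L]] <- new_sv_event(
          rid, "INS", fx$CHROM[i], fx$POS[i], "left_of_join",
          inserted_seq = toupper(ins), filter_status = fx$FILTER[i])
      } else {
        if (is.na(end)) { warning("record ", rid, " lacks END/SVLEN; skipped"); next }
        events[[length(events) + 1L]] <- new_sv_event(
          rid, type, fx$CHROM[i], fx$POS[i], "left_of_join",
          contig2 = fx$CHROM[i], pos2 = end, orient2 = "right_of_join",
          filter_status = fx$FILTER[i])
      }
      next
    }
    if (grepl("^<", alt)) {
      warning("unsupported symbolic ALT ", alt, " at record ", rid, "; skipped")
      next
    }
    if (grepl("^[ACGTNacgtn]+$", alt) && nchar(alt) > nchar(ref) &&
        startsWith(toupper(alt), toupper(ref))) {
      # explicit-sequence insertion
      events[[length(events) + 1L]] <- new_sv_event(
        rid, "INS", fx$CHROM[i], fx$POS[i] + nchar(ref) - 1L, "left_of_join",
        inserted_seq = toupper(substring(alt, nchar(ref) + 1L)),
        filter_status = fx$FILTER[i])
      next
    }
    warning("malformed or unsupported ALT '", alt, "' at record ", rid, "; skipped")
  }
  events <- c(events, pair_breakends(bnd))
  ord <- order(vapply(events, function(e) sprintf("%s:%010d:%s", e$contig1, e$pos1, e$event_id),
                      character(1)))
  events[ord]
}

#' Read an AnnotSV-style split-mode gene annotation table
#'
#' Minimal split-mode shape: one row per (SV, gene) with columns
#' \code{SV_chrom, SV_start, SV_end, Gene_name, Frameshift} (values like
#' "yes"/"no" or "frameshift"/"in-frame").
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_annotsv_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("SV_chrom", "SV_start", "SV_end", "Gene_name", "Frameshift")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("AnnotSV table missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Attach AnnotSV frameshift annotations to events
#'
#' Rows are joined on SV coordinates plus gene symbol; a matching annotation
#' is attached to the event (per gene) and takes priority in
#' [classify_frame()].
#'
#' @param events List of \code{sv_event}.
#' @param annot data.frame from [read_annotsv_table()].
#' @return The events, with \code{annotsv_frameshift} set to a named
#'   character vector (gene symbol -> annotation) where rows matched.
#' @export
attach_annotsv <- function(events, annot) {
  lapply(events, function(ev) {
    hit <- annot$SV_chrom == ev$contig1 & annot$SV_start == ev$pos1 &
      (is.na(ev$pos2) | annot$SV_end == ev$pos2)
    if (any(hit)) {
      ev$annotsv_frameshift <- stats::setNames(as.character(annot$Frameshift[hit]),
                                               annot$Gene_name[hit])
    }
    ev
  })
}

#' Classify an SV event's relationship to a transcript's CDS
#'
#' Retention rules: \code{both_in_cds} when both breakpoints map into the
#' spliced CDS; \code{one_in_cds} when exactly one does; \code{spans_cds}
#' when neither does but the event interval (interval-based SVs: DEL, DUP,
#' INV) fully contains at least one CDS segment; \code{no_overlap}
#' otherwise. Events classed \code{no_overlap} are dropped from peptide
#' generation. For BND events with breakends on different contigs each
#' breakend is evaluated on its own contig and \code{spans_cds} cannot
#' apply.
#'
#' @param event An \code{sv_event}.
#' @param transcript A coding \code{transcript_model}.
#' @param spanning_types SV types for which the interval-spanning rule is
#'   applied (configurable; default all interval-based types).
#' @return One of \code{"both_in_cds"}, \code{"one_in_cds"},
#'   \code{"spans_cds"}, \code{"no_overlap"}.
#' @export
classify_cds_overlap <- function(event, transcript,
                                 spanning_types = c("DEL", "DUP", "INV")) {
  stopifnot(inherits(event, "sv_event"), inherits(transcript, "transcript_model"))
  if (!transcript$coding) stop("transcript is non-coding")
  in1 <- event$contig1 == transcript$contig &&
    !is.na(map_genomic_to_cds(transcript, event$pos1))
  in2 <- !is.na(event$pos2) && !is.na(event$contig2) &&
    event$contig2 == transcript$contig &&
    !is.na(map_genomic_to_cds(transcript, event$pos2))
  if (in1 && in2) return("both_in_cds")
  if (in1 || in2) return("one_in_cds")
  if (event$sv_type %in% spanning_types && !is.na(event$pos2) &&
      identical(event$contig1, event$contig2) &&
      event$contig1 == transcript$contig) {
    lo <- min(event$pos1, event$pos2); hi <- max(event$pos1, event$pos2)
    contained <- any(transcript$cds$start >= lo & transcript$cds$end <= hi)
    if (contained) return("spans_cds")
  }
  "no_overlap"
}
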