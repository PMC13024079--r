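empty_peptides <- function() {
  data.frame(sequence = character(0), event_id = character(0),
             transcript_id = character(0), start_residue = integer(0),
             length = integer(0), spans_junction = logical(0),
             in_novel_region = logical(0), stringsAsFactors = FALSE)
}

#' Slide 8-11-mer windows over a mutant protein
#'
#' Emits every window of lengths \code{min_len..max_len} (pre-filter count
#' is \eqn{\sum_k \max(0, L - k + 1)}), annotated with whether the window
#' spans a junction residue and whether it overlaps the novel residue span.
#'
#' @param protein A \code{mutant_protein}.
#' @param min_len,max_len Window lengths (defaults 8 and 11).
#' @return data.frame of candidate windows (possibly empty).
#' @export
window_peptides <- function(protein, min_len = 8L, max_len = 11L) {
  stopifnot(inherits(protein, "mutant_protein"))
  L <- nchar(protein$sequence)
  if (L < min_len) return(empty_peptides())
  rows <- list()
  for (k in min_len:max_len) {
    n <- L - k + 1L
    if (n < 1L) next
    starts <- 0:(n - 1L)
    overlaps <- function(res) {
      # window [s, s+k) intersects the residue set
      hit <- rep(FALSE, n)
      for (r in res) {
        lo <- max(0L, r - k + 1L)
        if (lo <= min(r, n - 1L)) hit[(lo:min(r, n - 1L)) + 1L] <- TRUE
      }
      hit
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = substring(protein$sequence, starts + 1L, starts + k),
      event_id = protein$event_id, transcript_id = protein$transcript_id,
      start_residue = starts, length = k,
      spans_junction = overlaps(protein$junction_residues),
      in_novel_region = overlaps(protein$novel_residues),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Retain only junction-spanning or novel-region windows
#'
#' @param windows data.frame from [window_peptides()].
#' @return Subset with \code{spans_junction | in_novel_region}.
#' @export
retain_variant_windows <- function(windows) {
  if (nrow(windows) == 0) return(windows)
  windows[windows$spans_junction | windows$in_novel_region, , drop = FALSE]
}

#' Build the wild-type k-mer set used for self-peptide removal
#'
#' @param proteins Character vector of wild-type protein sequences.
#' @param k_range K-mer lengths (default 8:11).
#' @return Character vector of unique k-mers.
#' @export
wt_kmer_set <- function(proteins, k_range = 8:11) {
  kmers <- character(0)
  for (p in proteins) {
    L <- nchar(p)
    for (k in k_range) {
      if (L < k) next
      kmers <- c(kmers, vapply(1:(L - k + 1L), function(i) substr(p, i, i + k - 1L),
                               character(1)))
    }
  }
  unique(kmers)
}

#' Remove peptides identical to the wild-type sequence
#'
#' Windows whose sequence occurs in the wild-type k-mer set are dropped;
#' survivors are deduplicated on sequence with lineage lists merged
#' (semicolon-joined; the first lineage, by event then transcript then
#' start, names the FASTA record).
#'
#' @param windows data.frame of candidate windows.
#' @param wt Character vector from [wt_kmer_set()].
#' @return Deduplicated data.frame with merged \code{lineages} column.
#' @export
filter_self_peptides <- function(windows, wt) {
  if (nrow(windows) == 0) {
    out <- empty_peptides(); out$lineages <- character(0); return(out)
  }
  keep <- windows[!(windows$sequence %in% wt), , drop = FALSE]
  if (nrow(keep) == 0) {
    out <- empty_peptides(); out$lineages <- character(0); return(out)
  }
  keep <- keep[order(keep$sequence, keep$event_id, keep$transcript_id,
                     keep$start_residue), , drop = FALSE]
  parts <- split(keep, keep$sequence)
  out <- do.call(rbind, lapply(parts, function(g) {
    data.frame(sequence = g$sequence[1], event_id = g$event_id[1],
               transcript_id = g$transcript_id[1], start_residue = g$start_residue[1],
               length = g$length[1],
               gene_symbol = if ("gene_symbol" %in% names(g)) g$gene_symbol[1] else NA_character_,
               spans_junction = any(g$spans_junction),
               in_novel_region = any(g$in_novel_region),
               lineages = paste(unique(sprintf("%s:%s:%d", g$event_id, g$transcript_id,
                                               g$start_residue)), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$sequence), , drop = FALSE]
}

#' Write the neo_-prefixed candidate FASTA and CSV manifest
#'
#' One FASTA record per unique peptide sequence with a stable, parseable
#' header \code{neo_<event_id>_<transcript_id>_<start>}; the CSV manifest
#' lists every lineage and flag.
#'
#' @param peptides data.frame from [filter_self_peptides()].
#' @param fasta_path Output FASTA path.
#' @param manifest_path Optional output CSV path.
#' @return \code{fasta_path}, invisibly.
#' @export
write_neo_fasta <- function(peptides, fasta_path, manifest_path = NULL) {
  headers <- sprintf("neo_%s_%s_%d", peptides$event_id, peptides$transcript_id,
                     peptides$start_residue)
  con <- try(file(fasta_path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write FASTA: ", fasta_path)
  on.exit(close(con))
  if (nrow(peptides) > 0) {
    writeLines(paste0(">", headers, "\n", peptides$sequence), con, sep = "\n")
  }
  if (!is.null(manifest_path)) {
    man <- peptides
    man$fasta_header <- if (nrow(man) > 0) headers else character(0)
    utils::write.csv(man, manifest_path, row.names = FALSE, quote = FALSE)
  }
  invisible(fasta_path)
}

#' Read peptides back from a neo_ FASTA
#'
#' @param fasta_path FASTA path.
#' @return data.frame with \code{header} and \code{sequence}.
#' @export
read_neo_fasta <- function(fasta_path) {
  ss <- Biostrings::readAAStringSet(fasta_path)
  data.frame(header = names(ss), sequence = as.character(ss),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @keywords internal
#' Coding transcripts whose CDS genomic span covers a position (introns
#' included), used to admit intronic breakends of one_in_cds events.
transcripts_spanning <- function(index, contig, pos) {
  ids <- sort(names(index$transcripts))
  out <- list()
  for (tid in ids) {
    tx <- index$transcripts[[tid]]
    if (!tx$coding || tx$contig != contig) next
    if (pos >= min(tx$cds$start) && pos <= max(tx$cds$end)) out[[length(out) + 1L]] <- tx
  }
  out
}

#' Generate candidate neoantigen peptides from SV events
#'
#' End-to-end generation: for every retained (event, overlapping coding
#' transcript) pair, reconstruct the mutant CDS, translate, slide 8-11-mer
#' windows, keep junction-spanning/novel windows, and remove wild-type
#' self peptides. Peptides are generated per overlapping coding transcript
#' (isoform-aware); the final table is deduplicated on peptide sequence
#' with lineages preserved.
#'
#' @param events List of \code{sv_event} (already PASS-filtered).
#' @param index \code{transcript_index}.
#' @param genome \code{genome_sequence}.
#' @param min_len,max_len Window lengths.
#' @param self_filter Wild-type scope for self-peptide removal:
#'   \code{"transcript"} (k-mers of the source transcript's wild-type
#'   protein, plus the fusion partner's; default) or \code{"proteome"}
#'   (additionally all k-mers of \code{proteome_fasta}).
#' @param proteome_fasta Optional reference proteome FASTA for
#'   \code{self_filter = "proteome"}.
#' @param fusion_horizon See [reconstruct_mutant_cds()].
#' @return List with \code{peptides} (deduplicated data.frame),
#'   \code{mutants} (list of \code{mutant_cds}) and \code{proteins}.
#' @export
generate_candidate_peptides <- function(events, index, genome,
                                        min_len = 8L, max_len = 11L,
                                        self_filter = c("transcript", "proteome"),
                                        proteome_fasta = NULL,
                                        fusion_horizon = 600L) {
  self_filter <- match.arg(self_filter)
  proteome_kmers <- character(0)
  if (self_filter == "proteome") {
    if (is.null(proteome_fasta)) stop("proteome self-filter requires proteome_fasta")
    prot <- Biostrings::readAAStringSet(proteome_fasta)
    proteome_kmers <- wt_kmer_set(as.character(prot), min_len:max_len)
  }

  all_windows <- list()
  mutants <- list()
  proteins <- list()

  handle_pair <- function(event, head, tail = NULL) {
    ann <- if (!is.null(event$annotsv_frameshift)) {
      unname(event$annotsv_frameshift[head$gene_symbol])
    } else NULL
    if (length(ann) == 0 || is.na(ann)) ann <- NULL
    m <- tryCatch(reconstruct_mutant_cds(event, head, tail, genome,
                                         annotation = ann,
                                         fusion_horizon = fusion_horizon),
                  error = function(e) { warning(conditionMessage(e)); NULL })
    if (is.null(m)) return()
    mutants[[length(mutants) + 1L]] <<- m
    p <- tryCatch(translate_mutant(m),
                  error = function(e) { warning(conditionMessage(e)); NULL })
    if (is.null(p)) return()
    proteins[[length(proteins) + 1L]] <<- p
    win <- retain_variant_windows(window_peptides(p, min_len, max_len))
    if (nrow(win) == 0) return()
    win$gene_symbol <- head$gene_symbol
    # transcript-local wild-type scope (head + fusion partner)
    scope <- suppressWarnings(extract_cds(head, genome))
    wt_prots <- translate_wt(scope)
    if (!is.na(m$partner_transcript_id)) {
      pt <- index$transcripts[[m$partner_transcript_id]]
      wt_prots <- c(wt_prots, translate_wt(suppressWarnings(extract_cds(pt, genome))))
    }
    wt <- unique(c(wt_kmer_set(wt_prots, min_len:max_len), proteome_kmers))
    win <- win[!(win$sequence %in% wt), , drop = FALSE]
    if (nrow(win) > 0) all_windows[[length(all_windows) + 1L]] <<- win
  }

  for (event in events) {
    if (event$filter_status != "PASS") next
    if (event$sv_type == "BND") {
      if (isTRUE(event$unpaired)) {
        warning("skipping unpaired breakend ", event$event_id)
        next
      }
      ends <- list(list(contig = event$contig1, pos = event$pos1, orient = event$orient1),
                   list(contig = event$contig2, pos = event$pos2, orient = event$orient2))
      for (i in 1:2) {
        e <- ends[[i]]; other <- ends[[3L - i]]
        for (head in transcripts_spanning(index, e$contig, e$pos)) {
          need <- if (head$strand == "+") "left_of_join" else "right_of_join"
          if (e$orient != need) next
          tails <- transcripts_spanning(index, other$contig, other$pos)
          tail <- if (length(tails) > 0) tails[[1]] else NULL
          handle_pair(event, head, tail)
        }
      }
    } else {
      hi <- if (is.na(event$pos2)) event$pos1 else max(event$pos1, event$pos2)
      lo <- min(event$pos1, if (is.na(event$pos2)) event$pos1 else event$pos2)
      cands <- tryCatch(overlapping_transcripts(index, event$contig1, lo, hi),
                        error = function(e) list())
      # admit transcripts whose CDS span covers a breakend in an intron
      extra <- c(transcripts_spanning(index, event$contig1, lo),
                 transcripts_spanning(index, event$contig1, hi))
      ids <- unique(vapply(c(cands, extra), function(t) t$transcript_id, character(1)))
      for (tid in sort(ids)) {
        head <- index$transcripts[[tid]]
        cls <- classify_cds_overlap(event, head)
        if (cls == "no_overlap") next
        handle_pair(event, head)
      }
    }
  }

  windows <- if (length(all_windows) > 0) do.call(rbind, all_windows) else empty_peptides()
  peptides <- filter_self_peptides(windows, character(0))  # dedup + lineage merge
  list(peptides = peptides, mutants = mutants, proteins = proteins)
}

#' @keywords internal
#' Translate a wild-type CDS, dropping the trailing stop and partial codon.
translate_wt <- function(cds) {
  ncod <- nchar(cds) %/% 3L
  if (ncod == 0) return("")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(substr(cds, 1, ncod * 3L)),
                                           no.init.codon = TRUE,
                                           if.fuzzy.codon = "solve"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) substr(aa, 1, stop_at - 1L) else aa
}
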