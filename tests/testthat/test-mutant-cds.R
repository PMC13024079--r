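# 12-nt toy gene: ATG GCA TTT TGA at positions 11-22 of a padded contig
toy_gene <- function() {
  genome <- mini_genome(c(c1 = paste0(strrep("C", 10), "ATGGCATTTTGA", strrep("C", 10))))
  gtf <- mini_gtf(list(list(id = "T1", gene = "G1", symbol = "G1", contig = "c1",
                            strand = "+",
                            exons = data.frame(start = 11, end = 22),
                            cds = data.frame(start = 11, end = 22))))
  list(genome = genome, index = load_annotation(gtf, genome))
}

mk_mut <- function(seq, junctions, novel = NULL, frame = "in_frame") {
  structure(list(event_id = "e", transcript_id = "t",
                 partner_transcript_id = NA_character_, sv_type = "DEL",
                 sequence = seq, wt_sequence = seq,
                 junction_nt_offsets = as.integer(junctions),
                 novel_region = if (is.null(novel)) c(0L, 0L) else as.integer(novel),
                 frame_class = list(value = frame, source = "length_rule"),
                 flags = character(0)),
            class = "mutant_cds")
}

test_that("deletion splices out the affected CDS bases with one junction", {
  tg <- toy_gene()
  tx <- tg$index$transcripts[["T1"]]
  # remove "GCA" (genomic 14-16): POS is the last retained base
  m <- reconstruct_mutant_cds(mk_event("DEL", "c1", 13, 16), tx, NULL, tg$genome)
  expect_equal(m$sequence, "ATGTTTTGA")
  expect_equal(m$junction_nt_offsets, 3L)
  expect_equal(nchar(m$sequence) - nchar(m$wt_sequence), -3L)
  expect_equal(m$frame_class$value, "in_frame")
})

test_that("tandem duplication repeats the span in place, junction at copy end", {
  tg <- toy_gene()
  tx <- tg$index$transcripts[["T1"]]
  m <- reconstruct_mutant_cds(mk_event("DUP", "c1", 13, 17), tx, NULL, tg$genome)
  expect_equal(m$sequence, paste0("ATGGCAT", "GCAT", "TTTGA"))
  expect_equal(nchar(m$sequence), nchar(m$wt_sequence) + 4L)
  expect_true(11L %in% m$junction_nt_offsets)  # end of the duplicated copy
  expect_equal(m$frame_class$value, "frameshift")
})

test_that("insertion splices the inserted sequence at the anchor offset", {
  tg <- toy_gene()
  tx <- tg$index$transcripts[["T1"]]
  m <- reconstruct_mutant_cds(mk_event("INS", "c1", 16, inserted = "AAA"), tx,
                              NULL, tg$genome)
  expect_equal(m$sequence, "ATGGCAAAATTTTGA")
  expect_equal(m$junction_nt_offsets, c(6L, 9L))
  expect_equal(m$frame_class$value, "in_frame")
})

test_that("inversion reverse-complements the covered CDS bases in transcript space", {
  tg <- toy_gene()
  tx <- tg$index$transcripts[["T1"]]
  m <- reconstruct_mutant_cds(mk_event("INV", "c1", 13, 19), tx, NULL, tg$genome)
  expect_equal(m$sequence, paste0("ATG", revcomp("GCATTT"), "TGA"))
  expect_equal(nchar(m$sequence), nchar(m$wt_sequence))
})

test_that("fusion joins the head CDS prefix to the tail read in head frame", {
  genome <- mini_genome(c(
    cA = paste0(strrep("T", 10), "ATGGCATTTCCCGGGTGA", strrep("T", 10)),
    cB = paste0(strrep("A", 10), "ATGAAACTGGATTAA", strrep("A", 10))))
  gtf <- mini_gtf(list(
    list(id = "TA", gene = "GA", symbol = "GA", contig = "cA", strand = "+",
         exons = data.frame(start = 11, end = 28), cds = data.frame(start = 11, end = 28)),
    list(id = "TB", gene = "GB", symbol = "GB", contig = "cB", strand = "+",
         exons = data.frame(start = 11, end = 25), cds = data.frame(start = 11, end = 25))))
  idx <- load_annotation(gtf, genome)
  # head = 9 nt of TA (breakend at genomic 19, left retained);
  # tail = TB from CDS offset 3 (genomic 14, right retained)
  ev <- svpepgen:::new_sv_event("f", "BND", "cA", 19L, "left_of_join",
                                "cB", 14L, "right_of_join")
  m <- reconstruct_mutant_cds(ev, idx$transcripts[["TA"]], idx$transcripts[["TB"]],
                              genome)
  expect_equal(m$sequence, paste0("ATGGCATTT", "AAACTGGATTAA"))
  expect_equal(m$junction_nt_offsets, 9L)
  expect_equal(m$frame_class, list(value = "in_frame", source = "head_rule"))
  expect_equal(m$partner_transcript_id, "TB")
  # fusion from an unpaired breakend cannot be reconstructed
  ev_un <- ev; ev_un$unpaired <- TRUE
  expect_error(reconstruct_mutant_cds(ev_un, idx$transcripts[["TA"]], NULL, genome),
               "unpaired")
})

test_that("frame classification follows net-change, head-divisibility and annotation priority", {
  expect_equal(classify_frame(-3), list(value = "in_frame", source = "length_rule"))
  expect_equal(classify_frame(4)$value, "frameshift")
  expect_equal(classify_frame(10, fusion = TRUE),
               list(value = "frameshift", source = "head_rule"))
  expect_equal(classify_frame(9, fusion = TRUE)$value, "in_frame")
  # a gene-level annotation overrides the arithmetic in either direction
  expect_equal(classify_frame(-3, annotation = "yes"),
               list(value = "frameshift", source = "annotation"))
  expect_equal(classify_frame(4, annotation = "in-frame"),
               list(value = "in_frame", source = "annotation"))
})

test_that("translation stops at the first stop codon and maps junctions to residues", {
  p <- translate_mutant(mk_mut("ATGGCATGA", 3))
  expect_equal(p$sequence, "MA")
  expect_true(p$stopped)
  expect_equal(translate_mutant(mk_mut("ATGGCAAAATTTGCA", 7))$junction_residues, 2L)
  # trailing partial codon dropped; no stop -> stopped FALSE
  p2 <- translate_mutant(mk_mut("ATGGCAAAATT", 4, frame = "frameshift"))
  expect_equal(nchar(p2$sequence), 3L)
  expect_false(p2$stopped)
  # internal stop upstream of the junction: protein emitted, junction lost
  p3 <- translate_mutant(mk_mut("ATGTGAGCAGCA", 9))
  expect_equal(p3$sequence, "M")
  expect_true(p3$junction_lost)
  expect_length(p3$junction_residues, 0)
})

test_that("length bookkeeping and the frame rule agree on every fixture event", {
  ctx <- fixture_ctx()
  for (m in ctx$gen$mutants) {
    net <- nchar(m$sequence) - nchar(m$wt_sequence)
    if (m$sv_type %in% c("DEL", "DUP", "INS")) {
      expect_equal(m$frame_class$value == "frameshift", net %% 3L != 0L,
                   info = m$event_id)
    }
    if (m$sv_type == "INV") expect_equal(net, 0L, info = m$event_id)
  }
})

test_that("in-frame events restore the wild-type suffix downstream of the junction", {
  ctx <- fixture_ctx()
  for (m in ctx$gen$mutants) {
    if (m$frame_class$value != "in_frame" || m$sv_type == "BND") next
    p <- translate_mutant(m)
    wt_prot <- svpepgen:::translate_wt(m$wt_sequence)
    jmax <- max(c(p$junction_residues, p$novel_residues))
    n_tail <- nchar(p$sequence) - jmax - 1L
    if (n_tail <= 0) next
    expect_equal(substr(p$sequence, nchar(p$sequence) - n_tail + 1L, nchar(p$sequence)),
                 substr(wt_prot, nchar(wt_prot) - n_tail + 1L, nchar(wt_prot)),
                 info = m$event_id)
  }
})

test_that("audit trail records frame provenance and junction offsets per event", {
  ctx <- fixture_ctx()
  path <- tempfile(fileext = ".tsv")
  write_audit_trail(ctx$gen$mutants, path)
  audit <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(audit), length(ctx$gen$mutants))
  expect_true(all(c("event_id", "frame_class", "frame_source",
                    "junction_nt_offsets", "wt_len", "mutant_len") %in% names(audit)))
  expect_setequal(unique(audit$frame_class), c("in_frame", "frameshift"))
})
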