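write_test_vcf <- function(rows) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="t">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="t">',
    '##FILTER=<ID=LOWQUAL,Description="t">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", rows), path)
  path
}

test_that("symbolic ALT records parse and only PASS records become events", {
  vcf <- write_test_vcf(c(
    "chr1\t100\td1\tA\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=200",
    "chr1\t300\td2\tC\t<DEL>\t.\tLOWQUAL\tSVTYPE=DEL;END=400",
    "chr1\t500\tu1\tG\t<DUP>\t.\tPASS\tSVTYPE=DUP;END=560"))
  ev <- parse_sv_vcf(vcf)
  expect_length(ev, 2)                       # < number of records (one non-PASS)
  ids <- vapply(ev, `[[`, character(1), "event_id")
  expect_setequal(ids, c("d1", "u1"))
  d1 <- ev[[which(ids == "d1")]]
  expect_equal(d1$sv_type, "DEL")
  expect_equal(c(d1$pos1, d1$pos2), c(100L, 200L))
  # equality with record count iff all records PASS
  ev_all <- parse_sv_vcf(vcf, pass_only = FALSE)
  expect_length(ev_all, 3)
})

test_that("parsing the same VCF twice yields identical event content", {
  vcf <- fixture_bundle()$paths$vcf
  e1 <- suppressWarnings(parse_sv_vcf(vcf))
  e2 <- suppressWarnings(parse_sv_vcf(vcf))
  expect_identical(e1, e2)
})

test_that("all four breakend bracket forms decode to the orientation truth table", {
  # VCF breakend grammar: the side of the bracket carrying local sequence is
  # the retained side; bracket direction gives the mate's retained side.
  cases <- list(
    list(alt = "A[chr2:500[", local = "left_of_join",  mate = "right_of_join"),
    list(alt = "A]chr2:500]", local = "left_of_join",  mate = "left_of_join"),
    list(alt = "]chr2:500]A", local = "right_of_join", mate = "left_of_join"),
    list(alt = "[chr2:500[A", local = "right_of_join", mate = "right_of_join"))
  for (cs in cases) {
    d <- decode_breakend_alt(cs$alt, "A")
    expect_equal(d$local_orientation, cs$local, info = cs$alt)
    expect_equal(d$mate_orientation, cs$mate, info = cs$alt)
    expect_equal(d$mate_contig, "chr2")
    expect_equal(d$mate_pos, 500L)
    expect_equal(d$inserted_seq, "")
  }
  # micro-insertion between the breakends
  d <- decode_breakend_alt("AGGT[chr2:500[", "A")
  expect_equal(d$inserted_seq, "GGT")
  d <- decode_breakend_alt("]chr2:500]TTCA", "A")
  expect_equal(d$inserted_seq, "TTC")
  expect_null(decode_breakend_alt("<DEL>", "A"))
})

test_that("breakend mates merge into one paired event with deterministic order", {
  vcf <- write_test_vcf(c(
    "chr1\t100\tb1\tA\tA[chr2:500[\t.\tPASS\tSVTYPE=BND;MATEID=b2",
    "chr2\t500\tb2\tT\t]chr1:100]T\t.\tPASS\tSVTYPE=BND;MATEID=b1",
    "chr1\t900\tb3\tG\tG[chr2:700[\t.\tPASS\tSVTYPE=BND;MATEID=b4",
    "chr2\t700\tb4\tC\t]chr1:900]C\t.\tPASS\tSVTYPE=BND;MATEID=b3"))
  ev <- parse_sv_vcf(vcf)
  expect_length(ev, 2)
  ids <- vapply(ev, `[[`, character(1), "event_id")
  expect_equal(sort(ids), c("b1__b2", "b3__b4"))
  e <- ev[[which(ids == "b1__b2")]]
  expect_equal(e$orient1, "left_of_join")   # chr1:100 left side retained
  expect_equal(e$orient2, "right_of_join")  # chr2:500 right side retained
  expect_false(e$unpaired)
})

test_that("degenerate mate topologies error and lone breakends warn", {
  self <- data.frame(id = "x", mate_id = "x", contig = "chr1", pos = 1L,
                     alt = "A[chr2:5[", ref = "A", filter = "PASS",
                     stringsAsFactors = FALSE)
  expect_error(pair_breakends(self), "self-mated")
  triple <- data.frame(id = c("a", "b", "a"), mate_id = c("b", "a", "b"),
                       contig = "chr1", pos = c(1L, 2L, 3L),
                       alt = c("A[chr2:5[", "]chr1:1]T", "A[chr2:5["),
                       ref = c("A", "T", "A"), filter = "PASS",
                       stringsAsFactors = FALSE)
  # the a|b mate group holds three records
  expect_error(pair_breakends(triple), ">2 records")
  lone <- data.frame(id = "a", mate_id = "zz", contig = "chr1", pos = 10L,
                     alt = "A[chr2:5[", ref = "A", filter = "PASS",
                     stringsAsFactors = FALSE)
  expect_warning(ev <- pair_breakends(lone), "no mate")
  expect_true(ev[[1]]$unpaired)
})

test_that("CDS-overlap classes partition events and match a base-membership oracle", {
  ctx <- fixture_ctx()
  txa <- ctx$index$transcripts[["TXA"]]
  # case (1): both breakpoints inside a CDS exon
  expect_equal(classify_cds_overlap(mk_event("DEL", "chr1", 1030, 1033), txa),
               "both_in_cds")
  # case (2): one breakpoint in CDS, the other in an intron
  expect_equal(classify_cds_overlap(mk_event("DEL", "chr1", 1080, 1150), txa),
               "one_in_cds")
  # case (3): both outside, interval spans a whole coding exon
  expect_equal(classify_cds_overlap(mk_event("DEL", "chr1", 1095, 1300), txa),
               "spans_cds")
  expect_equal(classify_cds_overlap(mk_event("DEL", "chr1", 5000, 5100), txa),
               "no_overlap")

  # partition property + brute-force oracle over random intervals
  set.seed(11)
  coords <- cds_genomic_coords(txa)
  for (i in 1:60) {
    p <- sort(sample(900:1600, 2))
    ev <- mk_event("DEL", "chr1", p[1], p[2])
    cls <- classify_cds_overlap(ev, txa)
    in1 <- p[1] %in% coords; in2 <- p[2] %in% coords
    oracle <- if (in1 && in2) "both_in_cds" else if (in1 || in2) "one_in_cds"
    else if (any(txa$cds$start >= p[1] & txa$cds$end <= p[2])) "spans_cds"
    else "no_overlap"
    expect_equal(cls, oracle, info = paste(p, collapse = "-"))
  }
})

test_that("AnnotSV rows join on coordinates plus gene symbol", {
  tab_path <- tempfile(fileext = ".tsv")
  writeLines(c("SV_chrom\tSV_start\tSV_end\tGene_name\tFrameshift",
               "chr1\t1030\t1033\tGENEA\tyes"), tab_path)
  annot <- read_annotsv_table(tab_path)
  ev <- attach_annotsv(list(mk_event("DEL", "chr1", 1030, 1033),
                            mk_event("DEL", "chr1", 1210, 1214)), annot)
  expect_equal(unname(ev[[1]]$annotsv_frameshift["GENEA"]), "yes")
  expect_null(ev[[2]]$annotsv_frameshift)
  expect_error(read_annotsv_table({
    p <- tempfile(); writeLines("a\tb", p); p
  }), "missing column")
})
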