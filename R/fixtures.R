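## Deterministic toy dataset: 2 contigs, 3 coding genes (both strands,
## multi-exon CDS), one SV of each type plus a non-PASS record, predictor
## tables consistent with the generated candidate set, and a truth manifest
## whose mutant CDS strings are derived by direct string surgery on the
## designed coding sequences -- an oracle independent of the genomic
## reconstruction path.

STOP_CODONS <- c("TAA", "TAG", "TGA")

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rand_codons <- function(n) {
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste, collapse = "")
  pool <- setdiff(all_codons, STOP_CODONS)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

#' @keywords internal
#' Hand-splice oracle: translate a CDS, stopping at the first stop codon.
truth_translate <- function(cds) {
  ncod <- nchar(cds) %/% 3L
  aa <- character(0)
  for (i in seq_len(ncod)) {
    codon <- substr(cds, 3 * i - 2, 3 * i)
    a <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                            no.init.codon = TRUE))
    if (a == "*") return(list(protein = paste(aa, collapse = ""), stopped = TRUE))
    aa <- c(aa, a)
  }
  list(protein = paste(aa, collapse = ""), stopped = FALSE)
}

#' @keywords internal
#' Brute-force enumeration of the retained candidate peptide set of one
#' mutant CDS: all 8-11-mer windows overlapping a junction residue or the
#' novel residue span, minus wild-type k-mers.
truth_peptides <- function(mut_cds, junctions, novel, frameshift, wt_proteins,
                           k_range = 8:11) {
  tr <- truth_translate(mut_cds)
  prot <- tr$protein
  plen <- nchar(prot)
  if (frameshift) novel <- c(min(junctions), nchar(mut_cds))
  jres <- unique(floor(junctions / 3))
  jres <- jres[jres < plen]
  nres <- if (novel[2] > novel[1]) {
    r <- (novel[1] %/% 3):((novel[2] - 1) %/% 3)
    r[r < plen]
  } else integer(0)
  hot <- union(jres, nres)
  wt_kmers <- wt_kmer_set(wt_proteins, k_range)
  peps <- character(0)
  for (k in k_range) {
    if (plen < k) next
    for (s in 0:(plen - k)) {
      if (!any(hot %in% s:(s + k - 1))) next
      pep <- substr(prot, s + 1, s + k)
      if (!(pep %in% wt_kmers)) peps <- c(peps, pep)
    }
  }
  sort(unique(peps))
}

gtf_line <- function(contig, feature, start, end, strand, frame, attrs) {
  sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t%s\t%s", contig, feature, start, end,
          strand, frame, attrs)
}

#' Generate the self-contained toy fixture bundle
#'
#' Writes, under \code{out_dir}: a 2-contig genome FASTA, a GTF with three
#' coding genes (both strands, multi-exon CDS), an SV VCF containing an
#' in-frame deletion, a frameshift deletion, a tandem duplication (on the
#' minus-strand gene), an insertion, an inversion, a reciprocal breakend
#' pair forming an in-frame fusion, and one non-PASS record; a truth
#' manifest (expected mutant CDS, frame class and peptide set per event,
#' derived by direct string surgery); the generated candidate FASTA +
#' manifest; and schema-consistent predictor tables for every
#' prioritization parser. Byte-identical output for identical seeds.
#'
#' @param seed Integer seed driving all randomness.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with file \code{paths}, the \code{truth}
#'   manifest data.frame, the generated \code{peptides} table and the
#'   designed gene table.
#' @export
make_fixture <- function(seed, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  set.seed(seed)

  ## ---- designed coding sequences -----------------------------------------
  cdsA <- paste0("ATG", rand_codons(65), "TAA")   # 201 nt, chr1 + strand
  cdsB <- paste0("ATG", rand_codons(48), "TGA")   # 150 nt, chr1 - strand
  cdsC <- paste0("ATG", rand_codons(38), "TAA")   # 120 nt, chr2 + strand

  chr1 <- rand_dna(10000)
  chr2 <- rand_dna(8000)
  place <- function(contig, start, s) {
    substr(contig, start, start + nchar(s) - 1L) <- s
    contig
  }
  # gene A: CDS exons 1001-1090 (90), 1201-1260 (60), 1401-1451 (51)
  chr1 <- place(chr1, 1001, substr(cdsA, 1, 90))
  chr1 <- place(chr1, 1201, substr(cdsA, 91, 150))
  chr1 <- place(chr1, 1401, substr(cdsA, 151, 201))
  # gene B (minus): transcript exon1 (80 nt) at 3201-3280, exon2 (70 nt) at 3001-3070
  chr1 <- place(chr1, 3201, revcomp(substr(cdsB, 1, 80)))
  chr1 <- place(chr1, 3001, revcomp(substr(cdsB, 81, 150)))
  # gene C: CDS exons 501-560, 701-760
  chr2 <- place(chr2, 501, substr(cdsC, 1, 60))
  chr2 <- place(chr2, 701, substr(cdsC, 61, 120))

  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    gtf = file.path(out_dir, "annotation.gtf"),
    vcf = file.path(out_dir, "svs.vcf"),
    truth = file.path(out_dir, "truth_manifest.tsv"),
    neo_fasta = file.path(out_dir, "neo_peptides.fa"),
    manifest = file.path(out_dir, "peptide_manifest.csv"),
    cleavage = file.path(out_dir, "cleavage.tsv"),
    netmhcpan = file.path(out_dir, "netmhcpan.tsv"),
    mhcflurry = file.path(out_dir, "mhcflurry.tsv"),
    tpm = file.path(out_dir, "tpm.tsv"),
    ms = file.path(out_dir, "ms_combined_peptide.tsv"),
    immuno = file.path(out_dir, "immunogenicity.tsv"),
    similarity = file.path(out_dir, "similarity.tsv"))

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = chr2)), paths$genome)

  ## ---- GTF ----------------------------------------------------------------
  attrs <- function(gid, gname, tid = NULL) {
    a <- sprintf('gene_id "%s"; gene_name "%s";', gid, gname)
    if (!is.null(tid)) a <- paste0(a, sprintf(' transcript_id "%s";', tid))
    a
  }
  g <- c(
    gtf_line("chr1", "gene", 1001, 1451, "+", ".", attrs("GA", "GENEA")),
    gtf_line("chr1", "transcript", 1001, 1451, "+", ".", attrs("GA", "GENEA", "TXA")),
    gtf_line("chr1", "exon", 1001, 1090, "+", ".", attrs("GA", "GENEA", "TXA")),
    gtf_line("chr1", "exon", 1201, 1260, "+", ".", attrs("GA", "GENEA", "TXA")),
    gtf_line("chr1", "exon", 1401, 1451, "+", ".", attrs("GA", "GENEA", "TXA")),
    gtf_line("chr1", "CDS", 1001, 1090, "+", "0", attrs("GA", "GENEA", "TXA")),
    gtf_line("chr1", "CDS", 1201, 1260, "+", "0", attrs("GA", "GENEA", "TXA")),
    gtf_line("chr1", "CDS", 1401, 1451, "+", "0", attrs("GA", "GENEA", "TXA")),
    gtf_line("chr1", "gene", 3001, 3280, "-", ".", attrs("GB", "GENEB")),
    gtf_line("chr1", "transcript", 3001, 3280, "-", ".", attrs("GB", "GENEB", "TXB")),
    gtf_line("chr1", "exon", 3001, 3070, "-", ".", attrs("GB", "GENEB", "TXB")),
    gtf_line("chr1", "exon", 3201, 3280, "-", ".", attrs("GB", "GENEB", "TXB")),
    gtf_line("chr1", "CDS", 3001, 3070, "-", "1", attrs("GB", "GENEB", "TXB")),
    gtf_line("chr1", "CDS", 3201, 3280, "-", "0", attrs("GB", "GENEB", "TXB")),
    gtf_line("chr2", "gene", 501, 760, "+", ".", attrs("GC", "GENEC")),
    gtf_line("chr2", "transcript", 501, 760, "+", ".", attrs("GC", "GENEC", "TXC")),
    gtf_line("chr2", "exon", 501, 560, "+", ".", attrs("GC", "GENEC", "TXC")),
    gtf_line("chr2", "exon", 701, 760, "+", ".", attrs("GC", "GENEC", "TXC")),
    gtf_line("chr2", "CDS", 501, 560, "+", "0", attrs("GC", "GENEC", "TXC")),
    gtf_line("chr2", "CDS", 701, 760, "+", "0", attrs("GC", "GENEC", "TXC")))
  writeLines(g, paths$gtf)

  ## ---- VCF ----------------------------------------------------------------
  base_at <- function(contig, pos) {
    substr(if (contig == "chr1") chr1 else chr2, pos, pos)
  }
  ins_seq <- "CATCA"  # 5 nt -> frameshift
  vcf_header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="Breakend mate">',
    '##FILTER=<ID=LOWQUAL,Description="Low quality">',
    '##ALT=<ID=DEL,Description="Deletion">',
    '##ALT=<ID=DUP,Description="Duplication">',
    '##ALT=<ID=INV,Description="Inversion">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  vrow <- function(chrom, pos, id, ref, alt, filter, info) {
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\t%s", chrom, pos, id, ref, alt, filter, info)
  }
  vcf <- c(vcf_header,
    # in-frame DEL: removes CDS offsets 30..32 of TXA (genomic 1031-1033)
    vrow("chr1", 1030, "del_if", base_at("chr1", 1030), "<DEL>", "PASS",
         "SVTYPE=DEL;END=1033"),
    # frameshift DEL: removes CDS offsets 100..103 (genomic 1211-1214)
    vrow("chr1", 1210, "del_fs", base_at("chr1", 1210), "<DEL>", "PASS",
         "SVTYPE=DEL;END=1214"),
    # in-frame tandem DUP on minus-strand gene B (genomic 3241-3246)
    vrow("chr1", 3240, "dup_if", base_at("chr1", 3240), "<DUP>", "PASS",
         "SVTYPE=DUP;END=3246"),
    # frameshift INS after genomic 1420 (CDS offset 169 of TXA)
    vrow("chr1", 1420, "ins_fs", base_at("chr1", 1420),
         paste0(base_at("chr1", 1420), ins_seq), "PASS", "SVTYPE=INS"),
    # in-frame INV of genomic 1051-1062 (CDS offsets 50..61 of TXA)
    vrow("chr1", 1050, "inv_if", base_at("chr1", 1050), "<INV>", "PASS",
         "SVTYPE=INV;END=1062"),
    # reciprocal breakend pair: TXA head (60 nt) fused to TXC tail (offset 81)
    vrow("chr1", 1060, "bnd_1", base_at("chr1", 1060),
         paste0(base_at("chr1", 1060), "[chr2:722["), "PASS",
         "SVTYPE=BND;MATEID=bnd_2"),
    vrow("chr2", 722, "bnd_2", base_at("chr2", 722),
         paste0("]chr1:1060]", base_at("chr2", 722)), "PASS",
         "SVTYPE=BND;MATEID=bnd_1"),
    # non-PASS record: must not become an event
    vrow("chr1", 1035, "del_lowq", base_at("chr1", 1035), "<DEL>", "LOWQUAL",
         "SVTYPE=DEL;END=1040"))
  writeLines(vcf, paths$vcf)

  ## ---- truth manifest (hand-splice oracle) --------------------------------
  protA <- truth_translate(cdsA)$protein
  protB <- truth_translate(cdsB)$protein
  protC <- truth_translate(cdsC)$protein
  s0 <- function(s, from1, to1) if (to1 < from1) "" else substr(s, from1, to1)
  truth_rows <- list(
    list(event_id = "del_if", transcript_id = "TXA",
         mutant_cds = paste0(s0(cdsA, 1, 30), s0(cdsA, 34, 201)),
         junctions = 30, novel = c(30, 30), frameshift = FALSE, wt = protA),
    list(event_id = "del_fs", transcript_id = "TXA",
         mutant_cds = paste0(s0(cdsA, 1, 100), s0(cdsA, 105, 201)),
         junctions = 100, novel = c(100, 100), frameshift = TRUE, wt = protA),
    list(event_id = "dup_if", transcript_id = "TXB",
         mutant_cds = paste0(s0(cdsB, 1, 40), s0(cdsB, 35, 40), s0(cdsB, 41, 150)),
         junctions = c(40, 46), novel = c(40, 46), frameshift = FALSE, wt = protB),
    list(event_id = "ins_fs", transcript_id = "TXA",
         mutant_cds = paste0(s0(cdsA, 1, 170), ins_seq, s0(cdsA, 171, 201)),
         junctions = c(170, 175), novel = c(170, 175), frameshift = TRUE, wt = protA),
    list(event_id = "inv_if", transcript_id = "TXA",
         mutant_cds = paste0(s0(cdsA, 1, 50), revcomp(s0(cdsA, 51, 62)),
                             s0(cdsA, 63, 201)),
         junctions = c(50, 62), novel = c(50, 62), frameshift = FALSE, wt = protA),
    list(event_id = "bnd_1__bnd_2", transcript_id = "TXA",
         mutant_cds = paste0(s0(cdsA, 1, 60), s0(cdsC, 82, 120)),
         junctions = 60, novel = c(60, 60), frameshift = FALSE,
         wt = c(protA, protC)))
  truth <- do.call(rbind, lapply(truth_rows, function(r) {
    peps <- truth_peptides(r$mutant_cds, r$junctions, r$novel, r$frameshift, r$wt)
    data.frame(event_id = r$event_id, transcript_id = r$transcript_id,
               mutant_cds = r$mutant_cds,
               frame_class = if (r$frameshift) "frameshift" else "in_frame",
               junction_nt_offsets = paste(r$junctions, collapse = ","),
               peptides = paste(peps, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- run the generation pipeline, then derive predictor tables ----------
  genome <- read_genome(paths$genome)
  index <- load_annotation(paths$gtf, genome)
  events <- parse_sv_vcf(paths$vcf)
  gen <- generate_candidate_peptides(events, index, genome)
  write_neo_fasta(gen$peptides, paths$neo_fasta, paths$manifest)

  genes <- data.frame(gene = c("GENEA", "GENEB", "GENEC"),
                      tpm = c(12.5, 0, 3.2), stringsAsFactors = FALSE)
  tables <- make_predictor_tables(gen$peptides, seed, genes)
  utils::write.table(tables$cleavage, paths$cleavage, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tables$netmhcpan, paths$netmhcpan, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tables$mhcflurry, paths$mhcflurry, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tables$tpm, paths$tpm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tables$ms, paths$ms, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tables$immuno, paths$immuno, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tables$similarity, paths$similarity, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(paths = paths, truth = truth, peptides = gen$peptides,
                 genes = genes, tables = tables))
}

#' Build schema-consistent predictor tables for a candidate peptide set
#'
#' Deterministically assigns each peptide a scenario cycling through
#' clean passes, prescreen failures, binding failures, every MS detection
#' pattern, and exact-boundary rows for every cutoff of
#' [scoring_params()] (NetChop_Score exactly 0.5; affinity 500 nM;
#' percentile rank 2.0; immunogenicity 0.7; identity 79/80/85 percent;
#' E-value 200). 8- and 11-mers carry no immunogenicity score.
#'
#' @param peptides Candidate table with \code{sequence} and
#'   \code{gene_symbol} columns (e.g. from
#'   [generate_candidate_peptides()]).
#' @param seed Integer seed.
#' @param genes data.frame with \code{gene} and \code{tpm} (defaults to
#'   the fixture genes).
#' @return List of data.frames: \code{cleavage}, \code{netmhcpan},
#'   \code{mhcflurry}, \code{tpm}, \code{ms}, \code{immuno},
#'   \code{similarity}.
#' @export
make_predictor_tables <- function(peptides, seed,
                                  genes = data.frame(
                                    gene = c("GENEA", "GENEB", "GENEC"),
                                    tpm = c(12.5, 0, 3.2))) {
  set.seed(seed + 1L)
  seqs <- sort(unique(peptides$sequence))
  alleles <- c("HLA-A*02:01", "HLA-B*15:01")
  roles <- c("good", "prescreen_fail", "binding_fail", "normal_only",
             "tumor_and_normal", "no_ms", "low_immuno", "netchop_boundary",
             "flurry_boundary", "sim79", "sim80_boundary", "wb_rescue",
             "ref_mapped", "multi_neo")
  empty <- function(...) {
    cols <- list(...)
    as.data.frame(cols, stringsAsFactors = FALSE)[0, , drop = FALSE]
  }
  if (length(seqs) == 0) {
    return(list(
      cleavage = empty(peptide = "", position = 0L, residue = "", score = 0),
      netmhcpan = empty(peptide = "", allele = "", bind_level = "", el_rank = 0),
      mhcflurry = empty(peptide = "", allele = "", affinity_nm = 0,
                        flurry_rank = 0, presentation_score = 0),
      tpm = genes,
      ms = empty(peptide = "", proteins = "", tumor_spectral_count = 0L,
                 normal_spectral_count = 0L),
      immuno = empty(peptide = "", allele = "", immuno_score = 0),
      similarity = empty(qseqid = "", sseqid = "", pident = 0, length = 0L,
                         mismatch = 0L, gapopen = 0L, qstart = 0L, qend = 0L,
                         sstart = 0L, send = 0L, evalue = 0, bitscore = 0)))
  }

  cleav <- list(); net <- list(); flu <- list(); ms <- list(); imm <- list()
  sim <- list()
  for (i in seq_along(seqs)) {
    p <- seqs[i]
    L <- nchar(p)
    role <- roles[((i - 1L) %% length(roles)) + 1L]

    ## cleavage profile
    sc <- if (role == "prescreen_fail") {
      c(0.2, 0.9, 0.6, round(stats::runif(L - 5, 0, 0.45), 4), 0.1, 0.2)
    } else if (role == "netchop_boundary") {
      c(0.25, round(stats::runif(L - 2, 0, 0.45), 4), 0.25)  # score exactly 0.5
    } else {
      c(0.9, round(stats::runif(L - 2, 0, 0.45), 4), 0.85)
    }
    cleav[[i]] <- data.frame(peptide = p, position = seq_len(L),
                             residue = strsplit(p, "")[[1]], score = sc,
                             stringsAsFactors = FALSE)

    ## binding records
    if (role == "binding_fail") {
      net[[i]] <- data.frame(peptide = p, allele = alleles,
                             bind_level = c("", ""), el_rank = c(15, 22))
      flu[[i]] <- data.frame(peptide = p, allele = alleles,
                             affinity_nm = c(2000, 5000), flurry_rank = c(8, 12),
                             presentation_score = c(0.2, 0.1))
    } else if (role == "flurry_boundary") {
      # both records sit exactly on a failing boundary (strict <)
      net[[i]] <- data.frame(peptide = p, allele = alleles,
                             bind_level = c("", ""), el_rank = c(5, 6))
      flu[[i]] <- data.frame(peptide = p, allele = alleles,
                             affinity_nm = c(500, 499), flurry_rank = c(1.5, 2.0),
                             presentation_score = c(0.5, 0.5))
    } else if (role == "wb_rescue") {
      net[[i]] <- data.frame(peptide = p, allele = alleles,
                             bind_level = c("WB", ""), el_rank = c(1.8, 9))
      flu[[i]] <- data.frame(peptide = p, allele = alleles,
                             affinity_nm = c(900, 1200), flurry_rank = c(4, 6),
                             presentation_score = c(0.4, 0.3))
    } else {
      net[[i]] <- data.frame(peptide = p, allele = alleles,
                             bind_level = c("SB", ""), el_rank = c(0.2, 7))
      flu[[i]] <- data.frame(peptide = p, allele = alleles,
                             affinity_nm = c(150, 1500), flurry_rank = c(0.8, 5),
                             presentation_score = c(0.95, 0.3))
    }

    ## MS detection pattern
    neo_id <- sprintf("neo_%s", p)
    if (role == "normal_only") {
      ms[[i]] <- data.frame(peptide = p, proteins = neo_id,
                            tumor_spectral_count = 0L, normal_spectral_count = 4L)
    } else if (role == "tumor_and_normal") {
      ms[[i]] <- data.frame(peptide = p, proteins = neo_id,
                            tumor_spectral_count = 3L, normal_spectral_count = 2L)
    } else if (role == "ref_mapped") {
      ms[[i]] <- data.frame(peptide = p,
                            proteins = paste(neo_id, "sp|P00001|REF_HUMAN", sep = ";"),
                            tumor_spectral_count = 5L, normal_spectral_count = 0L)
    } else if (role == "multi_neo") {
      ms[[i]] <- data.frame(peptide = p,
                            proteins = paste(neo_id, paste0(neo_id, "_alt"), sep = ";"),
                            tumor_spectral_count = 6L, normal_spectral_count = 0L)
    } else if (role != "no_ms") {
      ms[[i]] <- data.frame(peptide = p, proteins = neo_id,
                            tumor_spectral_count = 5L, normal_spectral_count = 0L)
    }

    ## immunogenicity (9/10-mers only; 8/11-mers bypass with NA)
    score <- if (L %in% c(9L, 10L)) {
      if (role == "low_immuno") 0.7 else if (role %in% c("good", "wb_rescue",
                                                         "multi_neo", "sim80_boundary"))
        round(stats::runif(1, 0.75, 0.98), 4) else round(stats::runif(1, 0.1, 0.5), 4)
    } else NA_real_
    imm[[i]] <- data.frame(peptide = p, allele = alleles[1], immuno_score = score)
    if (L %in% c(9L, 10L) && i %% 7 == 0) {  # duplicate pair with a lower score
      imm[[length(seqs) + i]] <- data.frame(peptide = p, allele = alleles[1],
                                            immuno_score = max(0, score - 0.3))
    }

    ## similarity best hits
    if (role %in% c("good", "wb_rescue", "multi_neo", "tumor_and_normal")) {
      sim[[i]] <- data.frame(qseqid = p, sseqid = sprintf("dbpep_%04d", i),
                             pident = 85.0, length = L, mismatch = 1L, gapopen = 0L,
                             qstart = 1L, qend = L, sstart = 1L, send = L,
                             evalue = 1.5, bitscore = 24.6)
    } else if (role == "sim80_boundary") {
      sim[[i]] <- data.frame(qseqid = p, sseqid = sprintf("dbpep_%04d", i),
                             pident = 80.0, length = L, mismatch = 2L, gapopen = 0L,
                             qstart = 1L, qend = L, sstart = 1L, send = L,
                             evalue = 200, bitscore = 19.2)
    } else if (role == "sim79") {
      sim[[i]] <- data.frame(qseqid = p, sseqid = sprintf("dbpep_%04d", i),
                             pident = 79.0, length = L, mismatch = 2L, gapopen = 0L,
                             qstart = 1L, qend = L, sstart = 1L, send = L,
                             evalue = 50, bitscore = 18.0)
    }
  }
  bind <- function(lst) {
    lst <- lst[!vapply(lst, is.null, logical(1))]
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  }
  list(cleavage = bind(cleav), netmhcpan = bind(net), mhcflurry = bind(flu),
       tpm = genes, ms = bind(ms), immuno = bind(imm), similarity = bind(sim))
}

#' Read the fixture predictor tables back from disk
#'
#' @param paths Named list of paths as produced by [make_fixture()].
#' @return List of parsed inputs ready for [prioritize_candidates()].
#' @export
read_fixture_tables <- function(paths) {
  list(cleavage = parse_cleavage_table(utils::read.delim(paths$cleavage,
                                                         stringsAsFactors = FALSE)),
       binding = binding_records(
         utils::read.delim(paths$netmhcpan, stringsAsFactors = FALSE),
         utils::read.delim(paths$mhcflurry, stringsAsFactors = FALSE)),
       tpm = utils::read.delim(paths$tpm, stringsAsFactors = FALSE),
       ms = utils::read.delim(paths$ms, stringsAsFactors = FALSE),
       immuno = utils::read.delim(paths$immuno, stringsAsFactors = FALSE),
       similarity = parse_blast_table(utils::read.delim(paths$similarity,
                                                        stringsAsFactors = FALSE)))
}
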