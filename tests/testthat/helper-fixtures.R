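# Shared fixture machinery: a cached full toy bundle plus ad-hoc builders
# for small hand-verifiable genomes, transcripts and events.

.fx_cache <- new.env(parent = emptyenv())

# One full fixture bundle per seed, generated once per test run.
fixture_bundle <- function(seed = 42) {
  key <- paste0("fx", seed)
  if (!exists(key, envir = .fx_cache)) {
    dir <- file.path(tempdir(), paste0("svpg_fx_", seed))
    assign(key, suppressWarnings(make_fixture(seed, dir)), envir = .fx_cache)
  }
  get(key, envir = .fx_cache)
}

# Parsed pipeline context (genome, index, events, generated peptides) for the
# cached bundle.
fixture_ctx <- function(seed = 42) {
  key <- paste0("ctx", seed)
  if (!exists(key, envir = .fx_cache)) {
    fx <- fixture_bundle(seed)
    genome <- read_genome(fx$paths$genome)
    index <- load_annotation(fx$paths$gtf, genome)
    events <- suppressWarnings(parse_sv_vcf(fx$paths$vcf))
    gen <- suppressWarnings(generate_candidate_peptides(events, index, genome))
    assign(key, list(fx = fx, genome = genome, index = index, events = events,
                     gen = gen), envir = .fx_cache)
  }
  get(key, envir = .fx_cache)
}

# Write a named character vector of contig sequences as a FASTA and load it.
mini_genome <- function(contigs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(contigs), function(n) c(paste0(">", n), contigs[[n]]))),
             path)
  read_genome(path)
}

# Write a minimal GENCODE-style GTF for a list of transcripts, each a list
# with id, gene, symbol, contig, strand, exons (data.frame start/end) and
# cds (data.frame start/end, genomic order).
mini_gtf <- function(transcripts) {
  path <- tempfile(fileext = ".gtf")
  lines <- character(0)
  for (tx in transcripts) {
    at <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";',
                  tx$gene, tx$symbol, tx$id)
    rng <- range(c(tx$exons$start, tx$exons$end))
    lines <- c(lines,
               sprintf("%s\ttest\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       tx$contig, rng[1], rng[2], tx$strand, at))
    for (i in seq_len(nrow(tx$exons))) {
      lines <- c(lines, sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\t%s",
                                tx$contig, tx$exons$start[i], tx$exons$end[i],
                                tx$strand, at))
    }
    if (!is.null(tx$cds)) {
      for (i in seq_len(nrow(tx$cds))) {
        lines <- c(lines, sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                  tx$contig, tx$cds$start[i], tx$cds$end[i],
                                  tx$strand, at))
      }
    }
  }
  writeLines(lines, path)
  path
}

# Build an sv_event directly (bypassing VCF) for reconstruction tests.
mk_event <- function(sv_type, contig, pos1, pos2 = NA, inserted = "",
                     id = sv_type) {
  svpepgen:::new_sv_event(
    event_id = id, sv_type = sv_type, contig1 = contig, pos1 = pos1,
    orient1 = "left_of_join",
    contig2 = if (is.na(pos2)) NA_character_ else contig, pos2 = pos2,
    orient2 = if (is.na(pos2)) NA_character_ else "right_of_join",
    inserted_seq = inserted)
}

# A single-exon plus-strand test case and its exact minus-strand mirror:
# the mirrored contig is the reverse complement, the gene sits at the
# flipped coordinates on the minus strand, and the event coordinates are
# flipped accordingly. Used for strand-invariance checks.
mirror_case <- function(cds, pad5 = 100, pad3 = 80, event_maker) {
  set.seed(nchar(cds))
  flank5 <- paste(sample(c("A", "C", "G", "T"), pad5, replace = TRUE), collapse = "")
  flank3 <- paste(sample(c("A", "C", "G", "T"), pad3, replace = TRUE), collapse = "")
  plus_contig <- paste0(flank5, cds, flank3)
  N <- nchar(plus_contig)
  s <- pad5 + 1L; e <- pad5 + nchar(cds)

  plus <- list(
    genome = mini_genome(c(ctg = plus_contig)),
    gtf = mini_gtf(list(list(id = "TP", gene = "GP", symbol = "GP", contig = "ctg",
                             strand = "+",
                             exons = data.frame(start = s, end = e),
                             cds = data.frame(start = s, end = e)))))
  minus <- list(
    genome = mini_genome(c(ctg = revcomp(plus_contig))),
    gtf = mini_gtf(list(list(id = "TP", gene = "GP", symbol = "GP", contig = "ctg",
                             strand = "-",
                             exons = data.frame(start = N - e + 1L, end = N - s + 1L),
                             cds = data.frame(start = N - e + 1L, end = N - s + 1L)))))
  plus$index <- load_annotation(plus$gtf, plus$genome)
  minus$index <- load_annotation(minus$gtf, minus$genome)
  plus$event <- event_maker$plus(s, e)
  minus$event <- event_maker$minus(N, s, e)
  list(plus = plus, minus = minus)
}

# Mirrored event constructors: an interval SV affecting [a, b] on the plus
# contig (POS = a-1, END = b) affects [N-b+1, N-a+1] on the mirror
# (POS = N-b, END = N-a+1 ... inclusive right edge N-a+1 means POS' = N-b,
# END' = N - (a - 1)). Insertions after p map to after N-p with the
# sequence reverse-complemented.
mirror_interval_event <- function(sv_type, a, b, N) {
  list(pos1 = N - b, pos2 = N - (a - 1L))
}

# Protein + retained-peptide set for one (event, transcript) context.
run_one_event <- function(event, index, genome) {
  tx <- index$transcripts[[sort(names(index$transcripts))[1]]]
  m <- reconstruct_mutant_cds(event, tx, NULL, genome)
  p <- translate_mutant(m)
  win <- retain_variant_windows(window_peptides(p))
  wt <- wt_kmer_set(svpepgen:::translate_wt(suppressWarnings(extract_cds(tx, genome))))
  peps <- sort(unique(win$sequence[!(win$sequence %in% wt)]))
  list(mutant = m, protein = p, peptides = peps)
}
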