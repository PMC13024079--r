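test_that("internal cleavage risk matches direct arithmetic with natural log", {
  p <- scoring_params()
  # no qualifying internal site
  expect_equal(internal_risk(c(0.9, 0.1, 0.2, 0.3, 0.1, 0.2, 0.1, 0.8), p)$internal_risk, 0)
  # one site at 0.6: alpha*0.6 + beta*ln(2)
  r1 <- internal_risk(c(0.9, 0.1, 0.6, 0.1, 0.1, 0.1, 0.1, 0.8), p)
  expect_equal(r1$internal_risk, 1.0 * 0.6 + 0.3 * log(2), tolerance = 1e-12)
  expect_equal(r1$internal_cleavage_count, 1L)
  # two sites {0.6, 0.9}: alpha*0.9 + beta*ln(3)
  r2 <- internal_risk(c(0.9, 0.6, 0.1, 0.9, 0.1, 0.1, 0.1, 0.8), p)
  expect_equal(r2$internal_risk, 0.9 + 0.3 * log(3), tolerance = 1e-12)
  # peptides too short for internal positions carry zero risk
  expect_equal(internal_risk(c(0.9, 0.8), p)$internal_risk, 0)
})

test_that("the combined score reduces to N+C at zero risk and decays with risk", {
  p <- scoring_params()
  s <- netchop_score(c(0.9, rep(0.1, 6), 0.8), p)
  expect_identical(s$netchop_score, 0.9 + 0.8)   # exact in the risk-free limit
  expect_true(s$pass)
  s2 <- netchop_score(c(0.2, 0.7, rep(0.1, 5), 0.2), p)  # risk = 0.7 + 0.3 ln 2
  expect_equal(s2$netchop_score, 0.4 / (1 + 0.7 + 0.3 * log(2)), tolerance = 1e-12)
  expect_false(s2$pass)
  # strictly decreasing in risk for fixed termini
  risks <- seq(0, 2, by = 0.25)
  scores <- (0.9 + 0.8) / (1 + risks)
  expect_true(all(diff(scores) < 0))
})

test_that("min-max normalization maps endpoints to 0/1 and preserves order", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(5), 0)
  expect_equal(minmax_normalize(c(3, 3, 3)), c(0, 0, 0))
  set.seed(9)
  for (i in 1:100) {
    x <- rnorm(sample(2:50, 1))
    y <- minmax_normalize(x)
    expect_true(all(y >= 0 & y <= 1))
    if (max(x) > min(x)) {
      expect_equal(min(y), 0); expect_equal(max(y), 1)
      expect_equal(rank(x), rank(y))
    }
  }
})

test_that("cleavage tables require complete positions and scores in [0,1]", {
  good <- data.frame(peptide = "AAAAAAAK", position = 1:8,
                     residue = strsplit("AAAAAAAK", "")[[1]],
                     score = seq(0.1, 0.8, by = 0.1))
  prof <- parse_cleavage_table(good)
  expect_length(prof, 1)
  expect_equal(prof[[1]]$n_score, 0.1)
  expect_equal(prof[[1]]$c_score, 0.8)
  expect_error(parse_cleavage_table(good[-3, ]), "AAAAAAAK")
  bad <- good; bad$score[2] <- 1.4
  expect_error(parse_cleavage_table(bad), "0, 1")
  # interleaved peptides parse order-independently
  two <- rbind(good, data.frame(peptide = "CCCCCCCK", position = 1:8,
                                residue = strsplit("CCCCCCCK", "")[[1]],
                                score = rep(0.5, 8)))
  shuffled <- two[sample(nrow(two)), ]
  expect_identical(parse_cleavage_table(two), parse_cleavage_table(shuffled))
})

test_that("binding pass rules follow SB/WB and strict affinity/rank bounds", {
  p <- scoring_params()
  rec <- binding_records(
    net_table = data.frame(peptide = "PEP", allele = c("A1", "A2", "A3"),
                           bind_level = c("", "WB", ""), el_rank = c(9, 1.9, 12)),
    flurry_table = data.frame(peptide = "PEP", allele = c("A1", "A2", "A3"),
                              affinity_nm = c(300, 900, 2000),
                              flurry_rank = c(1.5, 4, 9),
                              presentation_score = c(0.9, 0.4, 0.1)))
  expect_true(rec$flurry_pass[rec$allele == "A1"])   # 300 nM & 1.5 rank
  expect_true(rec$net_pass[rec$allele == "A2"])      # WB counts
  expect_true(binding_pass(rec, params = p))
  # one WB among three alleles suffices even when flurry fails everywhere
  rec_wb <- binding_records(
    net_table = data.frame(peptide = "P2", allele = c("A1", "A2", "A3"),
                           bind_level = c("", "WB", ""), el_rank = c(9, 3, 12)))
  expect_true(binding_pass(rec_wb, params = p))
  # fails: affinity ok but rank too high, no bind level
  rec_fail <- binding_records(
    flurry_table = data.frame(peptide = "P3", allele = "A1", affinity_nm = 300,
                              flurry_rank = 2.5, presentation_score = 0.3))
  expect_false(binding_pass(rec_fail, params = p))
  # untyped alleles are ignored with a warning
  expect_warning(ok <- binding_pass(rec, typed_alleles = "A9", params = p),
                 "untyped")
  expect_false(ok)
})

test_that("evidence gates apply the printed boundary semantics", {
  p <- scoring_params()
  expect_false(expression_gate(0))
  expect_true(expression_gate(0.013))
  expect_warning(miss <- expression_gate(NA_real_))
  expect_false(miss)
  expect_equal(immunogenicity_gate("AAAAAAAKL", 0.8, p), "high")
  expect_equal(immunogenicity_gate("AAAAAAAKLV", 0.7, p), "low")  # strict >
  expect_equal(immunogenicity_gate("AAAAAAAK", NA, p), "NA-retained")
  expect_equal(immunogenicity_gate("AAAAAAAKLVM", NA, p), "NA-retained")
  expect_error(immunogenicity_gate("AAAAAAAKL", NA, p), "missing immunogenicity")
  hit <- function(pid, ev) data.frame(qseqid = "q", sseqid = "s", pident = pid,
                                      length = 9L, evalue = ev, bitscore = 20)
  expect_true(similarity_gate(hit(85, 50), p))
  expect_true(similarity_gate(hit(80.0, 200), p))   # inclusive boundaries
  expect_false(similarity_gate(hit(79, 50), p))
  expect_false(similarity_gate(hit(90, 201), p))
  expect_false(similarity_gate(NULL, p))
})

test_that("MS evidence selection follows neo_ prefix, reference removal and patterns", {
  g <- ms_evidence_gate("neo_a", tumor_sc = 3, normal_sc = 0)
  expect_equal(g$ms_pattern, "tumor_only")
  expect_true(g$retained); expect_equal(g$tier, "primary")
  g2 <- ms_evidence_gate("neo_a", 2, 1)
  expect_equal(g2$tier, "secondary")
  expect_false(ms_evidence_gate("neo_a", 0, 4)$retained)       # normal-only removed
  # reference-proteome mapping dominates even with multiple neo_ entries
  g3 <- ms_evidence_gate(c("neo_a", "neo_b", "sp|P1|X_HUMAN"), 5, 0)
  expect_false(g3$retained)
  expect_true(g3$maps_to_reference_proteome)
  g4 <- ms_evidence_gate(c("neo_a", "neo_b"), 5, 0)
  expect_true(g4$retained); expect_true(g4$multi_mapped_neo)
  expect_false(ms_evidence_gate("neo_a", 0, 0)$retained)       # needs a spectrum
})

test_that("best-hit selection ranks by bitscore, then E-value, then length", {
  blast <- data.frame(qseqid = "P", sseqid = c("s1", "s2", "s3"),
                      pident = c(85, 90, 88), length = c(9, 9, 10),
                      evalue = c(10, 5, 5), bitscore = c(20, 20, 18))
  best <- best_similarity_hit(blast, "P")
  expect_equal(best$sseqid, "s2")  # same bitscore as s1, lower evalue
  expect_null(best_similarity_hit(blast, "ZZZ"))
})

test_that("pair-score deduplication keeps the maximum score deterministically", {
  rec <- data.frame(peptide = c("P", "P", "Q"), allele = c("A1", "A1", "A1"),
                    immuno_score = c(0.6, 0.9, NA))
  out <- deduplicate_pair_scores(rec)
  expect_equal(out$immuno_score[out$peptide == "P"], 0.9)
  expect_true(is.na(out$immuno_score[out$peptide == "Q"]))
  expect_equal(out$peptide, c("P", "Q"))
})

test_that("a hand-built cascade yields the enumerated tier counts 10/6/4/3/1", {
  aa <- c("ACDEFGHKL", "CDEFGHKLM", "DEFGHKLMN", "EFGHKLMNP", "FGHKLMNPQ",
          "GHKLMNPQR", "HKLMNPQRS", "KLMNPQRST", "LMNPQRSTV", "MNPQRSTVW")
  # roles: 1-4 fail prescreen; 5-6 fail binding; 7 fails TPM; 8-9 fail MS; 10 passes all
  peptides <- data.frame(sequence = aa, event_id = "e", transcript_id = "t",
                         start_residue = 0L, length = 9L,
                         gene_symbol = c(rep("GEXP", 6), "GZERO", rep("GEXP", 3)),
                         spans_junction = TRUE, in_novel_region = FALSE,
                         lineages = "e:t:0", stringsAsFactors = FALSE)
  cleav <- do.call(rbind, lapply(seq_along(aa), function(i) {
    sc <- if (i <= 4) c(0.1, 0.9, rep(0.1, 6), 0.1) else c(0.9, rep(0.1, 7), 0.9)
    data.frame(peptide = aa[i], position = 1:9, residue = strsplit(aa[i], "")[[1]],
               score = sc)
  }))
  net <- data.frame(peptide = aa, allele = "A1",
                    bind_level = ifelse(seq_along(aa) %in% 5:6, "", "SB"),
                    el_rank = 0.3)
  tpm <- data.frame(gene = c("GEXP", "GZERO"), tpm = c(7.5, 0))
  ms <- data.frame(peptide = aa[c(8, 9, 10)],
                   proteins = "neo_x",
                   tumor_spectral_count = c(0L, 0L, 4L),
                   normal_spectral_count = c(5L, 0L, 0L))
  immuno <- data.frame(peptide = aa, allele = "A1", immuno_score = 0.9)
  blast <- data.frame(qseqid = aa[10], sseqid = "db1", pident = 85, length = 9L,
                      evalue = 2, bitscore = 22)
  res <- prioritize_candidates(peptides, parse_cleavage_table(cleav),
                               binding_records(net_table = net), tpm, ms, immuno,
                               blast)
  expect_equal(res$funnel$n_unique_peptides, c(10L, 6L, 4L, 3L, 1L, 1L))
  expect_true(all(diff(res$funnel$n_unique_peptides) <= 0))
  # gates are idempotent: re-running on the same inputs reproduces the table
  res2 <- prioritize_candidates(peptides, parse_cleavage_table(cleav),
                                binding_records(net_table = net), tpm, ms, immuno,
                                blast)
  expect_identical(res$table, res2$table)
})

test_that("YAML configuration overrides defaults and rejects bad weights", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("alpha: 0.8", "beta: 0.5", "immuno_cutoff: 0.6"), cfg)
  p <- read_scoring_config(cfg)
  expect_equal(p$alpha, 0.8)
  expect_equal(p$beta, 0.5)
  expect_equal(p$immuno_cutoff, 0.6)
  expect_equal(p$rank_cutoff, 2.0)  # untouched default
  expect_error(scoring_params(alpha = -1), "alpha")
  writeLines(c("alpha: 1.0", "bogus_key: 3"), cfg)
  expect_warning(read_scoring_config(cfg), "bogus_key")
})
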