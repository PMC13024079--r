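#' Scoring and filtering parameters
#'
#' Bundles the weights of the internal-cleavage risk model and every
#' threshold of the filter cascade. All are user-adjustable, also via a
#' YAML configuration file ([read_scoring_config()]).
#'
#' Boundary semantics (frozen by tests): prescreen NetChop_Score >= 0.5
#' (inclusive); MHCflurry affinity < 500 nM and percentile rank < 2.0
#' (strict); TPM > 0 (strict); immunogenicity > 0.7 (strict); similarity
#' identity >= 80 percent and E-value <= 200 (inclusive).
#'
#' @param alpha Weight of the maximum internal cleavage score (default 1.0).
#' @param beta Weight of the log site-count penalty (default 0.3; the
#'   logarithm is natural).
#' @param internal_site_cutoff Internal positions with cleavage score at or
#'   above this are counted as cleavage sites (default 0.5).
#' @param netchop_pass_cutoff Prescreen threshold on NetChop_Score (0.5).
#' @param affinity_cutoff nM affinity bound for flurry_pass (500).
#' @param rank_cutoff Percentile-rank bound for flurry_pass (2.0).
#' @param tpm_cutoff Expression bound, strict greater-than (0).
#' @param immuno_cutoff Immunogenicity bound, strict greater-than (0.7).
#' @param identity_cutoff Percent-identity bound, inclusive (80).
#' @param evalue_cutoff E-value bound, inclusive (200).
#' @param max_over_all_internal Sensitivity option: take
#'   \code{max_internal_score} over all internal positions instead of only
#'   qualifying sites (default FALSE).
#' @return Object of class \code{scoring_params}.
#' @export
scoring_params <- function(alpha = 1.0, beta = 0.3,
                           internal_site_cutoff = 0.5,
                           netchop_pass_cutoff = 0.5,
                           affinity_cutoff = 500,
                           rank_cutoff = 2.0,
                           tpm_cutoff = 0,
                           immuno_cutoff = 0.7,
                           identity_cutoff = 80,
                           evalue_cutoff = 200,
                           max_over_all_internal = FALSE) {
  p <- list(alpha = alpha, beta = beta,
            internal_site_cutoff = internal_site_cutoff,
            netchop_pass_cutoff = netchop_pass_cutoff,
            affinity_cutoff = affinity_cutoff, rank_cutoff = rank_cutoff,
            tpm_cutoff = tpm_cutoff, immuno_cutoff = immuno_cutoff,
            identity_cutoff = identity_cutoff, evalue_cutoff = evalue_cutoff,
            max_over_all_internal = isTRUE(max_over_all_internal))
  num <- p[setdiff(names(p), "max_over_all_internal")]
  if (!all(vapply(num, function(v) is.numeric(v) && is.finite(v), logical(1)))) {
    stop("all scoring parameters must be finite numbers")
  }
  if (alpha < 0 || beta < 0) stop("weights alpha and beta must be >= 0")
  class(p) <- "scoring_params"
  p
}

#' Read scoring parameters from a YAML config file
#'
#' Keys mirror the arguments of [scoring_params()]; absent keys keep their
#' defaults.
#'
#' @param path YAML path.
#' @return \code{scoring_params}.
#' @export
read_scoring_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(scoring_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) warning("ignoring unknown config key(s): ",
                                   paste(unknown, collapse = ", "))
  do.call(scoring_params, cfg[intersect(names(cfg), known)])
}

#' @export
print.scoring_params <- function(x, ...) {
  cat("scoring_params:\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Parse a per-position cleavage score table
#'
#' NetChop-style long form with columns \code{peptide}, \code{position}
#' (1-based), \code{residue} (optional) and \code{score}. Every position of
#' every peptide must be present exactly once; scores must lie in [0, 1].
#'
#' @param source Path to a TSV/CSV or a data.frame.
#' @return Named list of cleavage profiles (\code{peptide},
#'   \code{scores}, \code{n_score}, \code{c_score}).
#' @export
parse_cleavage_table <- function(source) {
  tab <- if (is.data.frame(source)) source else {
    utils::read.delim(source, sep = "", stringsAsFactors = FALSE)
  }
  need <- c("peptide", "position", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("cleavage table missing column(s): ",
                             paste(miss, collapse = ", "))
  if (any(tab$score < 0 | tab$score > 1, na.rm = TRUE) || any(is.na(tab$score))) {
    stop("cleavage scores must lie in [0, 1]")
  }
  profiles <- lapply(split(tab, tab$peptide), function(g) {
    g <- g[order(g$position), , drop = FALSE]
    L <- nchar(g$peptide[1])
    if (!identical(as.integer(g$position), seq_len(L))) {
      stop("cleavage table has missing or duplicated positions for peptide ",
           g$peptide[1])
    }
    list(peptide = g$peptide[1], scores = as.numeric(g$score),
         n_score = g$score[1], c_score = g$score[L])
  })
  profiles[order(names(profiles))]
}

#' Internal proteasomal cleavage risk of a peptide
#'
#' Internal positions (excluding both termini) with cleavage score at or
#' above \code{internal_site_cutoff} are potential internal cleavage sites.
#' The risk is
#' \deqn{\alpha \cdot max\_internal\_score + \beta \cdot \ln(1 + internal\_cleavage\_count)}
#' with \code{max_internal_score = 0} when no site qualifies. Peptides with
#' fewer than 3 positions have no internal positions and risk 0.
#'
#' @param profile A cleavage profile (from [parse_cleavage_table()]) or a
#'   numeric vector of per-position scores.
#' @param params \code{scoring_params}.
#' @return List with \code{max_internal_score},
#'   \code{internal_cleavage_count} and \code{internal_risk}.
#' @export
internal_risk <- function(profile, params = scoring_params()) {
  scores <- if (is.list(profile)) profile$scores else profile
  L <- length(scores)
  if (L < 3) {
    return(list(max_internal_score = 0, internal_cleavage_count = 0L,
                internal_risk = 0))
  }
  internal <- scores[2:(L - 1L)]
  sites <- internal[internal >= params$internal_site_cutoff]
  max_int <- if (params$max_over_all_internal) max(internal) else {
    if (length(sites) > 0) max(sites) else 0
  }
  n_sites <- length(sites)
  list(max_internal_score = max_int, internal_cleavage_count = n_sites,
       internal_risk = params$alpha * max_int + params$beta * log1p(n_sites))
}

#' Min-max normalize a vector of risks
#'
#' \code{(x - min)/(max - min)} elementwise; when all values are equal the
#' output is all zeros. The cohort is whatever is passed in one call
#' (per-run normalization).
#'
#' @param risks Non-empty numeric vector.
#' @return Numeric vector in [0, 1].
#' @export
minmax_normalize <- function(risks) {
  stopifnot(length(risks) > 0, is.numeric(risks))
  rng <- range(risks)
  if (rng[1] == rng[2]) return(rep(0, length(risks)))
  (risks - rng[1]) / (rng[2] - rng[1])
}

#' Combined terminal-cleavage score with internal-risk penalty
#'
#' \deqn{NetChop\_Score = (N\_score + C\_score)/(1 + Internal\_Risk)}
#' with prescreen pass at \code{NetChop_Score >= netchop_pass_cutoff}
#' (inclusive). As the internal risk goes to zero the score approaches
#' \code{N_score + C_score} exactly.
#'
#' @param profile Cleavage profile or numeric score vector.
#' @param params \code{scoring_params}.
#' @return List with \code{netchop_score}, \code{pass}, and the
#'   internal-risk components.
#' @export
netchop_score <- function(profile, params = scoring_params()) {
  scores <- if (is.list(profile)) profile$scores else profile
  r <- internal_risk(scores, params)
  n_score <- scores[1]
  c_score <- scores[length(scores)]
  sc <- (n_score + c_score) / (1 + r$internal_risk)
  c(list(netchop_score = sc, pass = sc >= params$netchop_pass_cutoff,
         n_score = n_score, c_score = c_score), r)
}

#' Score a cohort of cleavage profiles
#'
#' Applies [internal_risk()] and [netchop_score()] to every profile and
#' min-max normalizes the risks over the cohort (all profiles of one
#' invocation).
#'
#' @param profiles List from [parse_cleavage_table()].
#' @param params \code{scoring_params}.
#' @return data.frame with one row per peptide.
#' @export
score_cleavage_profiles <- function(profiles, params = scoring_params()) {
  if (length(profiles) == 0) {
    return(data.frame(peptide = character(0), n_score = numeric(0),
                      c_score = numeric(0), max_internal_score = numeric(0),
                      internal_cleavage_count = integer(0),
                      internal_risk = numeric(0), internal_risk_norm = numeric(0),
                      netchop_score = numeric(0), prescreen_pass = logical(0)))
  }
  rows <- lapply(profiles, function(p) {
    s <- netchop_score(p, params)
    data.frame(peptide = p$peptide, n_score = s$n_score, c_score = s$c_score,
               max_internal_score = s$max_internal_score,
               internal_cleavage_count = s$internal_cleavage_count,
               internal_risk = s$internal_risk,
               netchop_score = s$netchop_score, prescreen_pass = s$pass,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df$internal_risk_norm <- minmax_normalize(df$internal_risk)
  df[, c("peptide", "n_score", "c_score", "max_internal_score",
         "internal_cleavage_count", "internal_risk", "internal_risk_norm",
         "netchop_score", "prescreen_pass")]
}

#' Merge NetMHCpan-style and MHCflurry-style binding tables
#'
#' Builds one record per (peptide, allele) with per-tool pass flags:
#' \code{net_pass} iff BindLevel is SB or WB; \code{flurry_pass} iff
#' affinity < 500 nM and percentile rank < 2.0 (strict). A missing tool's
#' columns default that tool's pass to FALSE, so partial runs remain
#' usable.
#'
#' @param net_table data.frame with \code{peptide, allele, bind_level,
#'   el_rank} (or NULL).
#' @param flurry_table data.frame with \code{peptide, allele, affinity_nm,
#'   flurry_rank, presentation_score} (or NULL).
#' @param params \code{scoring_params}.
#' @return data.frame of binding records.
#' @export
binding_records <- function(net_table = NULL, flurry_table = NULL,
                            params = scoring_params()) {
  if (is.null(net_table) && is.null(flurry_table)) {
    stop("at least one binding table is required")
  }
  if (!is.null(net_table)) {
    stopifnot(all(c("peptide", "allele", "bind_level") %in% names(net_table)))
    if (!"el_rank" %in% names(net_table)) net_table$el_rank <- NA_real_
    net_table <- net_table[, c("peptide", "allele", "bind_level", "el_rank")]
  } else {
    net_table <- data.frame(peptide = character(0), allele = character(0),
                            bind_level = character(0), el_rank = numeric(0))
  }
  if (!is.null(flurry_table)) {
    stopifnot(all(c("peptide", "allele", "affinity_nm", "flurry_rank") %in%
                    names(flurry_table)))
    if (!"presentation_score" %in% names(flurry_table)) {
      flurry_table$presentation_score <- NA_real_
    }
    flurry_table <- flurry_table[, c("peptide", "allele", "affinity_nm",
                                     "flurry_rank", "presentation_score")]
  } else {
    flurry_table <- data.frame(peptide = character(0), allele = character(0),
                               affinity_nm = numeric(0), flurry_rank = numeric(0),
                               presentation_score = numeric(0))
  }
  rec <- merge(net_table, flurry_table, by = c("peptide", "allele"), all = TRUE)
  rec$bind_level[is.na(rec$bind_level)] <- "none"
  rec$net_pass <- rec$bind_level %in% c("SB", "WB")
  rec$flurry_pass <- !is.na(rec$affinity_nm) & !is.na(rec$flurry_rank) &
    rec$affinity_nm < params$affinity_cutoff & rec$flurry_rank < params$rank_cutoff
  rec <- rec[order(rec$peptide, rec$allele), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Candidate binding pass over a sample's HLA alleles
#'
#' A peptide is included in the candidate set if it satisfies
#' \code{net_pass} or \code{flurry_pass} for at least one HLA allele of the
#' sample. Records for alleles outside the sample's typed set are ignored
#' with a warning.
#'
#' @param records Binding records for one peptide (from
#'   [binding_records()]).
#' @param typed_alleles Optional character vector of the sample's typed
#'   alleles.
#' @param params \code{scoring_params}.
#' @return Logical scalar.
#' @export
binding_pass <- function(records, typed_alleles = NULL, params = scoring_params()) {
  if (nrow(records) == 0) return(FALSE)
  if (!is.null(typed_alleles)) {
    bad <- !(records$allele %in% typed_alleles)
    if (any(bad)) {
      warning("ignoring record(s) for untyped allele(s): ",
              paste(unique(records$allele[bad]), collapse = ", "))
      records <- records[!bad, , drop = FALSE]
    }
  }
  any(records$net_pass | records$flurry_pass)
}

#' Gene-expression gate (TPM > 0, strict)
#'
#' @param gene_tpm Numeric TPM value(s); NA (gene absent from the TPM
#'   table) fails with a warning.
#' @return Logical vector.
#' @export
expression_gate <- function(gene_tpm) {
  if (any(is.na(gene_tpm))) warning("gene(s) absent from TPM table fail the expression gate")
  !is.na(gene_tpm) & gene_tpm > 0
}

#' Mass-spectrometry evidence gate
#'
#' Consumes combined_peptide-style rows for one peptide across tumor and
#' normal searches. The peptide is selected when its Protein field contains
#' a "neo_"-prefixed entry, removed when it also maps to the reference
#' proteome, retained when multi-mapped across several neo_ entries, and
#' requires a spectral count > 0 in at least one sample. The detection
#' pattern is \code{tumor_only} (retained, tier primary),
#' \code{tumor_and_normal} (retained, tier secondary), \code{normal_only}
#' (removed) or \code{not_detected}.
#'
#' @param proteins Character vector of protein accessions the peptide maps
#'   to (the Protein field plus any mapped proteins).
#' @param tumor_sc,normal_sc Spectral counts in the tumor and normal runs.
#' @return List with \code{ms_pattern}, \code{retained}, \code{tier},
#'   \code{maps_to_reference_proteome}, \code{multi_mapped_neo},
#'   \code{spectral_count}.
#' @export
ms_evidence_gate <- function(proteins, tumor_sc, normal_sc) {
  neo <- grepl("^neo_", proteins)
  is_neo <- any(neo)
  maps_ref <- any(!neo)
  multi_neo <- sum(neo) > 1
  tumor_sc <- sum(tumor_sc, na.rm = TRUE)
  normal_sc <- sum(normal_sc, na.rm = TRUE)
  pattern <- if (tumor_sc > 0 && normal_sc > 0) "tumor_and_normal"
  else if (tumor_sc > 0) "tumor_only"
  else if (normal_sc > 0) "normal_only"
  else "not_detected"
  retained <- is_neo && !maps_ref && (tumor_sc + normal_sc) > 0 &&
    pattern %in% c("tumor_only", "tumor_and_normal")
  tier <- if (!retained) NA_character_ else if (pattern == "tumor_only") "primary" else "secondary"
  list(ms_pattern = pattern, retained = retained, tier = tier,
       maps_to_reference_proteome = maps_ref, multi_mapped_neo = multi_neo,
       spectral_count = tumor_sc + normal_sc)
}

#' Immunogenicity gate with 8/11-mer bypass
#'
#' 9- and 10-mers are classed \code{high} when the immunogenicity score is
#' strictly above the cutoff (default 0.7), otherwise \code{low}; 8- and
#' 11-mers fall outside the predictor's length support, bypass the gate and
#' are strictly retained (\code{NA-retained}).
#'
#' @param peptide Peptide sequence (length decides the bypass).
#' @param immuno_score Score in [0, 1]; required for 9-10-mers.
#' @param params \code{scoring_params}.
#' @return One of \code{"high"}, \code{"low"}, \code{"NA-retained"}.
#' @export
immunogenicity_gate <- function(peptide, immuno_score, params = scoring_params()) {
  L <- nchar(peptide)
  if (L %in% c(8L, 11L)) return("NA-retained")
  if (!L %in% c(9L, 10L)) stop("peptide length ", L, " outside the 8-11 candidate range")
  if (is.na(immuno_score)) stop("missing immunogenicity score for 9-10-mer ", peptide)
  if (immuno_score > params$immuno_cutoff) "high" else "low"
}

#' Parse a blastp tabular (outfmt 6 style) similarity table
#'
#' @param source Path or data.frame with at least \code{qseqid, sseqid,
#'   pident, length, evalue, bitscore}.
#' @return data.frame.
#' @export
parse_blast_table <- function(source) {
  tab <- if (is.data.frame(source)) source else {
    utils::read.delim(source, stringsAsFactors = FALSE)
  }
  need <- c("qseqid", "sseqid", "pident", "length", "evalue", "bitscore")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("similarity table missing column(s): ",
                             paste(miss, collapse = ", "))
  tab
}

#' Best similarity hit for a peptide
#'
#' Best hit by bitscore; ties broken by lower E-value, then longer
#' alignment, then subject id.
#'
#' @param blast data.frame from [parse_blast_table()].
#' @param peptide Query peptide id.
#' @return One-row data.frame, or NULL when the peptide has no hit.
#' @export
best_similarity_hit <- function(blast, peptide) {
  hits <- blast[blast$qseqid == peptide, , drop = FALSE]
  if (nrow(hits) == 0) return(NULL)
  ord <- order(-hits$bitscore, hits$evalue, -hits$length, hits$sseqid)
  hits[ord[1], , drop = FALSE]
}

#' Similarity-evidence gate
#'
#' Evidence when a best hit exists with E-value <= 200 and identity >= 80
#' percent (both inclusive). No full-coverage requirement: validated
#' neoantigen databases consist of short peptides, so identity plus
#' alignment length captures shared core features.
#'
#' @param best_hit One-row data.frame from [best_similarity_hit()], or
#'   NULL.
#' @param params \code{scoring_params}.
#' @return Logical scalar.
#' @export
similarity_gate <- function(best_hit, params = scoring_params()) {
  if (is.null(best_hit) || nrow(best_hit) == 0) return(FALSE)
  best_hit$evalue[1] <= params$evalue_cutoff &&
    best_hit$pident[1] >= params$identity_cutoff
}

#' Representative record per peptide-HLA pair
#'
#' The same pair may recur across cases; the record with the highest
#' immunogenicity score is the representative (all-NA groups stay NA).
#' Output order is deterministic (peptide, then allele).
#'
#' @param records data.frame with \code{peptide}, \code{allele} and
#'   \code{immuno_score}.
#' @return data.frame with one row per (peptide, allele).
#' @export
deduplicate_pair_scores <- function(records) {
  stopifnot(all(c("peptide", "allele", "immuno_score") %in% names(records)))
  parts <- split(records, paste(records$peptide, records$allele, sep = "\r"))
  out <- do.call(rbind, lapply(parts, function(g) {
    if (all(is.na(g$immuno_score))) return(g[1, , drop = FALSE])
    g[which.max(g$immuno_score), , drop = FALSE]
  }))
  out <- out[order(out$peptide, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the tiered prioritization funnel
#'
#' Applies the gates in the default order: generated candidates ->
#' processing prescreen (NetChop_Score) -> binding pass -> expression ->
#' MS evidence -> immunogenicity/similarity prioritization. Counts are
#' unique peptide sequences per tier and are non-increasing by
#' construction.
#'
#' @param peptides Candidate peptide data.frame (needs \code{sequence};
#'   \code{gene_symbol} used for the expression gate).
#' @param cleavage List of cleavage profiles keyed by peptide (from
#'   [parse_cleavage_table()]); peptides without a profile fail the
#'   prescreen.
#' @param binding Binding records data.frame (from [binding_records()]).
#' @param tpm data.frame with \code{gene, tpm}.
#' @param ms data.frame with \code{peptide, proteins} (semicolon-joined
#'   accessions), \code{tumor_spectral_count}, \code{normal_spectral_count}.
#' @param immuno data.frame with \code{peptide, allele, immuno_score} (NA
#'   for 8/11-mers).
#' @param similarity data.frame from [parse_blast_table()].
#' @param typed_alleles Optional sample allele set for [binding_pass()].
#' @param params \code{scoring_params}.
#' @return List with \code{table} (per-peptide result table) and
#'   \code{funnel} (a \code{funnel_report}).
#' @export
prioritize_candidates <- function(peptides, cleavage, binding, tpm, ms,
                                  immuno, similarity,
                                  typed_alleles = NULL,
                                  params = scoring_params()) {
  tab <- peptides[order(peptides$sequence), , drop = FALSE]
  tab <- tab[!duplicated(tab$sequence), , drop = FALSE]
  rownames(tab) <- NULL
  n0 <- nrow(tab)

  # --- processing prescreen -------------------------------------------------
  cle <- score_cleavage_profiles(cleavage[names(cleavage) %in% tab$sequence], params)
  tab <- merge(tab, cle, by.x = "sequence", by.y = "peptide", all.x = TRUE)
  tab$prescreen_pass[is.na(tab$prescreen_pass)] <- FALSE

  # --- binding --------------------------------------------------------------
  tab$binding_pass <- vapply(tab$sequence, function(p) {
    rec <- binding[binding$peptide == p, , drop = FALSE]
    binding_pass(rec, typed_alleles, params)
  }, logical(1))

  # --- expression -----------------------------------------------------------
  gene_tpm <- tpm$tpm[match(tab$gene_symbol, tpm$gene)]
  tab$gene_tpm <- gene_tpm
  tab$expressed <- suppressWarnings(expression_gate(gene_tpm))

  # --- MS evidence ----------------------------------------------------------
  ms_res <- lapply(tab$sequence, function(p) {
    rows <- ms[ms$peptide == p, , drop = FALSE]
    if (nrow(rows) == 0) {
      return(list(ms_pattern = "not_detected", retained = FALSE,
                  tier = NA_character_, maps_to_reference_proteome = FALSE,
                  multi_mapped_neo = FALSE, spectral_count = 0))
    }
    prots <- unique(unlist(strsplit(rows$proteins, ";", fixed = TRUE)))
    ms_evidence_gate(prots, rows$tumor_spectral_count, rows$normal_spectral_count)
  })
  tab$ms_pattern <- vapply(ms_res, `[[`, character(1), "ms_pattern")
  tab$ms_retained <- vapply(ms_res, `[[`, logical(1), "retained")
  tab$ms_tier <- vapply(ms_res, `[[`, character(1), "tier")
  tab$spectral_count <- vapply(ms_res, `[[`, numeric(1), "spectral_count")
  tab$multi_mapped_neo <- vapply(ms_res, `[[`, logical(1), "multi_mapped_neo")

  # --- immunogenicity + similarity -----------------------------------------
  imm <- deduplicate_pair_scores(immuno)
  tab$immuno_score <- vapply(tab$sequence, function(p) {
    s <- imm$immuno_score[imm$peptide == p]
    if (length(s) == 0 || all(is.na(s))) NA_real_ else max(s, na.rm = TRUE)
  }, numeric(1))
  tab$immuno_class <- vapply(seq_len(nrow(tab)), function(i) {
    tryCatch(immunogenicity_gate(tab$sequence[i], tab$immuno_score[i], params),
             error = function(e) NA_character_)
  }, character(1))
  tab$similarity_evidence <- vapply(tab$sequence, function(p) {
    similarity_gate(best_similarity_hit(similarity, p), params)
  }, logical(1))

  # --- cumulative tiers -----------------------------------------------------
  tab$pass_prescreen <- tab$prescreen_pass
  tab$pass_binding <- tab$pass_prescreen & tab$binding_pass
  tab$pass_expression <- tab$pass_binding & tab$expressed
  tab$pass_ms <- tab$pass_expression & tab$ms_retained
  tab$prioritized <- tab$pass_ms &
    (!is.na(tab$immuno_class) & tab$immuno_class %in% c("high", "NA-retained")) &
    tab$similarity_evidence

  funnel <- build_funnel(tab)
  tab <- tab[order(tab$sequence), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, funnel = funnel)
}

#' Build a funnel report from a prioritization table
#'
#' @param tab Table from [prioritize_candidates()].
#' @return \code{funnel_report}: data.frame of tier names and retained
#'   unique-peptide counts (non-increasing).
#' @export
build_funnel <- function(tab) {
  tiers <- c(generated = nrow(tab),
             netchop_prescreen = sum(tab$pass_prescreen),
             binding_pass = sum(tab$pass_binding),
             expressed = sum(tab$pass_expression),
             ms_supported = sum(tab$pass_ms),
             prioritized = sum(tab$prioritized))
  rep <- data.frame(tier = names(tiers), n_unique_peptides = as.integer(tiers),
                    stringsAsFactors = FALSE)
  if (any(diff(rep$n_unique_peptides) > 0)) {
    stop("funnel tier counts must be non-increasing")  # defensive; gates are cumulative
  }
  class(rep) <- c("funnel_report", "data.frame")
  rep
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Candidate funnel (unique peptide sequences):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-18s %d\n", x$tier[i], x$n_unique_peptides[i]))
  }
  invisible(x)
}
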