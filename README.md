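# svpepgen

Turning somatic **structural-variant breakpoints into prioritized
neoantigen candidates**. Structural variants (SVs) — deletions,
duplications, insertions, inversions and breakend fusions — rearrange
coding sequence and can create tumor-specific peptides absent from the
wild-type proteome. `svpepgen` implements the computational core of that
interpretation problem for people building SV-aware immunotherapy
pipelines: it maps VCF breakpoints into spliced transcript coordinates,
reconstructs mutant coding sequences per overlapping isoform, classifies
frameshift vs in-frame, translates with junction tracking, enumerates
junction-restricted 8–11-mer windows, removes wild-type-identical
peptides, and then scores, filters and ranks the candidates through a
cleavage-risk model, peptide–HLA binding pass rules, tiered multi-omics
evidence gates and a ranking-based benchmarking framework.

The package consumes the standard output shapes of upstream tools
(reference FASTA, GENCODE-style GTF, SV VCF incl. paired BND bracket
notation, NetChop-style per-position cleavage tables, NetMHCpan-/
MHCflurry-style binding tables, gene TPM tables, combined-peptide-style MS
search output, immunogenicity scores, blastp tabular hits) and does not
re-run those tools.

## The model at the core

Per peptide, internal positions (excluding both termini) with cleavage
score ≥ 0.5 count as potential internal cleavage sites, and

    Internal_Risk = α · max_internal_score + β · ln(1 + internal_cleavage_count)
    NetChop_Score = (N_score + C_score) / (1 + Internal_Risk)

with defaults α = 1.0, β = 0.3 and a prescreen at `NetChop_Score ≥ 0.5`.
Candidates then pass if **any** sample HLA allele satisfies `net_pass`
(SB/WB bind level) or `flurry_pass` (affinity < 500 nM and percentile rank
< 2.0), are gated on gene TPM > 0, on tumor-specific MS evidence
(`neo_`-prefixed hits with spectral count > 0; tumor-only primary,
tumor-and-normal secondary, normal-only removed), on immunogenicity
(> 0.7; 8/11-mers bypass with NA and are retained), and on similarity to
validated neoantigens (best blastp hit with identity ≥ 80 %, E-value ≤
200). Method comparison uses top-N cutoffs (50/75/100 % of the smaller
method's candidate budget) and two-sided Mann–Whitney U tests — exact by
enumeration at combined n ≤ 12 without ties, Edgeworth-refined normal
approximation otherwise.

## Worked example

```r
library(svpepgen)

# 1. deterministic toy bundle: genome, annotation, SV VCF, predictor tables
fx <- make_fixture(seed = 1, out_dir = file.path(tempdir(), "bundle"))

# 2. breakpoints -> mutant CDS -> junction-restricted 8-11-mer candidates
genome <- read_genome(fx$paths$genome)
index  <- load_annotation(fx$paths$gtf, genome)
events <- parse_sv_vcf(fx$paths$vcf)
gen    <- generate_candidate_peptides(events, index, genome)
length(events)        # 6   (the non-PASS record is dropped)
nrow(gen$peptides)    # 212 unique candidate peptides
print(gen$mutants[[1]])
#> mutant_cds del_if/TXA [DEL, in_frame via length_rule]: 198 nt (wt 201), junctions at 30

# 3. score, gate and rank the candidates
tabs <- read_fixture_tables(fx$paths)
res  <- prioritize_candidates(gen$peptides, tabs$cleavage, tabs$binding,
                              tabs$tpm, tabs$ms, tabs$immuno, tabs$similarity)
print(res$funnel)
#> Candidate funnel (unique peptide sequences):
#>   generated          212
#>   netchop_prescreen  196
#>   binding_pass       166
#>   expressed          137
#>   ms_supported       99
#>   prioritized        58

# 4. cleavage-risk model on one profile (one internal site at 0.6)
netchop_score(c(0.9, 0.1, 0.6, 0.1, 0.1, 0.1, 0.1, 0.8))[c("netchop_score", "pass")]
#> $netchop_score  0.9402945      # (0.9+0.8) / (1 + 0.6 + 0.3*ln 2)
#> $pass           TRUE

# 5. exact rank test at desk scale
mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#> $U 0; $p_two_sided 0.1; $method "exact"
```

The funnel counts are unique peptide sequences surviving each tier of the
cascade; `res$table` holds the per-peptide record (scores, per-gate flags,
MS pattern, immunogenicity class, similarity evidence) with full
event/transcript lineage, so the funnel can be re-cut in any gate order.

A thin command-line wrapper with `fixtures` / `peptides` / `prioritize` /
`benchmark` subcommands ships in `inst/cli/svpepgen.R`; thresholds and the
α/β weights are adjustable through a YAML config (`read_scoring_config()`).

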