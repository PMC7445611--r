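# Synthetic report generation: the fixed worked-example fixture and a seeded
# generator that stands in for a sequencing facility's feed. Generated codes
# are drawn from the registry value sets, HGVS strings from a small grammar,
# and genes from a bundled HGNC micro-list, so that a missingness-0 corpus
# validates cleanly by construction.

#' Bundled HGNC micro-list
#'
#' Twenty frequently reported cancer genes with their HGNC ids; avoids any
#' online lookup.
#' @return Data frame with columns \code{hgnc_id}, \code{symbol}.
#' @export
hgnc_micro_list <- function() {
  data.frame(
    hgnc_id = c("HGNC:1097", "HGNC:3236", "HGNC:6407", "HGNC:11998",
                "HGNC:8975", "HGNC:427", "HGNC:1100", "HGNC:1101",
                "HGNC:6342", "HGNC:7989", "HGNC:7029", "HGNC:3430",
                "HGNC:9588", "HGNC:5382", "HGNC:6192", "HGNC:3765",
                "HGNC:9967", "HGNC:10261", "HGNC:583", "HGNC:1787"),
    symbol = c("BRAF", "EGFR", "KRAS", "TP53", "PIK3CA", "ALK", "BRCA1",
               "BRCA2", "KIT", "NRAS", "MET", "ERBB2", "PTEN", "IDH1",
               "JAK2", "FLT3", "RET", "ROS1", "APC", "CDKN2A"),
    stringsAsFactors = FALSE)
}

#' The fixed worked-example report
#'
#' The subject block (identifier 12345678, Gildong Hong, born 1947-04-29,
#' sex code "1", ethnicity "2040-4") and the BRAF variant block (HGNC:1097,
#' notation \code{"c.1799T > A_p.V600E"}, effect "Substitution (missense)",
#' COSM476) reproduce the published specification example. The example prints
#' no classification, order, report, specimen or treatment values, so the
#' fixture completes them: the classification with the companion example
#' "Tier 1 (Pathogenic, Identified)", the treatment with vemurafenib (the
#' canonical BRAF V600E-targeted agent), and the remaining administrative
#' fields with synthetic values. The completed fixture is fully conformant.
#'
#' @return A \code{sequencing_report}.
#' @examples
#' worked_example()$subject$birth_date
#' @export
worked_example <- function() {
  sequencing_report(
    subject = list(identifier = "12345678", name = "Gildong Hong",
                   birth_date = "1947-04-29", sex_code = "1",
                   ethnicity_code = "2040-4"),
    order = list(order_id = "ORD-2026-0001", order_date = "2026-03-02",
                 ordering_clinician = "Dr. Chunhyang Seong",
                 legally_authorized_person = "Mongryong Lee",
                 performing_laboratory = "University Hospital Molecular Pathology Laboratory"),
    report = list(report_id = "RPT-2026-0001", status = "final",
                  test_code = "solid-tumor-ngs-panel",
                  issued_date = "2026-03-20",
                  interpretation_summary = "BRAF p.V600E activating mutation detected; BRAF-targeted therapy is indicated.",
                  assessed_condition = "Malignant melanoma"),
    specimen = list(biomaterial_type = "Tumor tissue (FFPE)",
                    specimen_id = "SPC-88421", collection_date = "2026-02-27"),
    variants = list(variant_record(
      gene_hgnc_id = "HGNC:1097", gene_symbol = "BRAF",
      hgvs_notation = "c.1799T > A_p.V600E",
      variant_effect = "Substitution (missense)",
      variant_db_id = "COSM476",
      classification = "Tier 1 (Pathogenic, Identified)",
      result_status = "final", assay_code = "targeted-ngs-panel",
      observed_date = "2026-03-18", test_method = "Targeted NGS panel",
      interpretation = "Pathogenic activating kinase mutation",
      comment = "Kinase domain (exon 15)")),
    treatments = list("Vemurafenib"))
}

#' Generator configuration
#'
#' @param seed Integer RNG seed; the same seed and configuration produce a
#'   byte-identical corpus.
#' @param n_reports Number of reports.
#' @param variants_min,variants_max Range of variants per report.
#' @param include_research_block Probability a report carries a research block.
#' @param missingness Probability each optional field is dropped (applies to
#'   optional fields only).
#' @param corrupt_required When TRUE, blank required fields so every report
#'   carries at least one error-severity issue (invalid-fixture mode).
#' @return A validated list of class \code{generator_config}.
#' @export
generator_config <- function(seed = 42L, n_reports = 10L, variants_min = 1L,
                             variants_max = 3L, include_research_block = 0.5,
                             missingness = 0, corrupt_required = FALSE) {
  if (n_reports < 1) stop("n_reports must be positive")
  if (variants_min < 0 || variants_max < variants_min) {
    stop("invalid variants range [", variants_min, ", ", variants_max, "]")
  }
  if (include_research_block < 0 || include_research_block > 1 ||
      missingness < 0 || missingness > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), n_reports = as.integer(n_reports),
                 variants_min = as.integer(variants_min),
                 variants_max = as.integer(variants_max),
                 include_research_block = include_research_block,
                 missingness = missingness,
                 corrupt_required = isTRUE(corrupt_required)),
            class = "generator_config")
}

.GIVEN_NAMES <- c("Minjun", "Seoyeon", "Doyun", "Jiwoo", "Haeun", "Siwoo",
                  "Jia", "Juwon", "Eunseo", "Hajun")
.FAMILY_NAMES <- c("Kim", "Lee", "Park", "Choi", "Jung", "Kang", "Cho",
                   "Yoon", "Jang", "Lim")
.LABS <- c("Central Genome Diagnostics Laboratory",
           "University Hospital Molecular Pathology Laboratory",
           "Metropolitan Clinical Sequencing Center")

.rand_date <- function(from, to) {
  as.character(as.Date(from) + sample.int(as.integer(as.Date(to) - as.Date(from)), 1))
}

.gen_variant <- function(obs_date) {
  gene <- hgnc_micro_list()[sample.int(20, 1), ]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 1)
  alt <- sample(setdiff(bases, ref), 1)
  pos <- sample.int(9000, 1) + 99
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_protein <- stats::runif(1) < 0.8
  spaced <- stats::runif(1) < 0.5  # facility dialect pads the substitution sign
  sep <- if (spaced) " > " else ">"
  notation <- paste0("c.", pos, ref, sep, alt)
  if (with_protein) {
    notation <- paste0(notation, "_p.", sample(aa, 1),
                       sample.int(800, 1) + 10, sample(aa, 1))
  }
  variant_record(
    gene_hgnc_id = gene$hgnc_id, gene_symbol = gene$symbol,
    hgvs_notation = notation,
    variant_effect = sample(.EFFECT_SUGGESTIONS, 1),
    variant_db_id = paste0("COSM", sample.int(999999, 1)),
    classification = classification_triple(
      sample(value_set("tier")$code, 1),
      sample(value_set("pathogeny")$code, 1),
      sample(value_set("clinical_relevance")$code, 1)),
    result_status = "final",
    assay_code = "targeted-ngs-panel",
    observed_date = obs_date,
    test_method = sample(c("Targeted NGS panel", "Whole exome sequencing"), 1),
    interpretation = sample(c("Clinically actionable variant",
                              "Variant of potential clinical relevance",
                              "Variant reviewed by molecular tumor board"), 1),
    comment = sample(c("Confirmed by orthogonal assay", "Hotspot region",
                       "Coverage above panel threshold"), 1))
}

.gen_research <- function(missingness) {
  chrom <- sample(c(as.character(1:22), "X"), 1)
  start <- sample.int(2e8, 1)
  full <- list(
    "research.condition_code" = sample(c("C43.9", "C34.90", "C18.9"), 1),
    "research.study_id" = paste0("STUDY-", sample.int(9000, 1) + 999),
    "research.consent_status" = sample(c("granted", "research-limited"), 1),
    "research.coded_diagnosis" = sample(c("SNOMED:372244006", "SNOMED:254637007"), 1),
    "research.report_category" = "GE",
    "research.sequence_type" = "dna",
    "research.coordinate_system" = "1-based",
    "research.reference_assembly" = sample(c("GRCh37", "GRCh38"), 1),
    "research.chromosome" = chrom,
    "research.reference_seq_id" = paste0("NC_0000", sample.int(23, 1)),
    "research.strand" = sample(c("+", "-"), 1),
    "research.sequence_window" = list(start = start, end = start + sample.int(5000, 1)),
    "research.variant_position" = list(start = start + 100, end = start + 101),
    "research.observed_allele" = sample(c("A", "C", "G", "T"), 1),
    "research.reference_allele" = sample(c("A", "C", "G", "T"), 1),
    "research.read_coverage" = sample.int(4000, 1) + 500,
    "research.quality_score" = round(stats::runif(1, 20, 60), 1),
    "research.repository_pointer" = list(
      url = paste0("https://repository.example.org/seq/", sample.int(99999, 1)),
      name = "institutional sequence archive"),
    "research.sequencing_platform" = list(
      manufacturer = sample(c("Illumina", "Thermo Fisher"), 1),
      model = sample(c("NovaSeq 6000", "NextSeq 550", "Ion GeneStudio S5"), 1)),
    "research.analysis_platform" = list(
      name = sample(c("in-house somatic pipeline", "community variant pipeline"), 1),
      version = paste0("v", sample.int(9, 1), ".", sample.int(20, 1))),
    "research.base_calling" = sample(c("RTA3", "BaseSpace basecaller"), 1),
    "research.qc_metrics" = list(
      mean_depth = round(stats::runif(1, 200, 1500)),
      target_coverage = round(stats::runif(1, 0.9, 1), 3),
      uniformity = round(stats::runif(1, 0.8, 1), 3),
      q30_fraction = round(stats::runif(1, 0.85, 0.99), 3),
      total_reads = sample.int(2e7, 1) + 1e6,
      mapped_fraction = round(stats::runif(1, 0.9, 1), 3),
      duplication_rate = round(stats::runif(1, 0.01, 0.3), 3)),
    "research.flowcell_id" = paste0("FC", sample.int(99999, 1)),
    "research.tumor_mutational_burden" = round(stats::runif(1, 0.5, 40), 1),
    "research.microsatellite_status" = sample(c("MSS", "MSI-H", "MSI-L"), 1),
    "research.tumor_purity" = round(stats::runif(1, 0.2, 0.95), 2),
    "research.hrd_score" = round(stats::runif(1, 0, 100)),
    "research.mutational_signature" = sample(c("SBS1", "SBS4", "SBS7a"), 1),
    "research.circulating_dna_fraction" = round(stats::runif(1, 0, 0.5), 3))
  keep <- stats::runif(length(full)) >= missingness
  out <- full[keep]
  if (length(out) == 0) NULL else out
}

.gen_report <- function(config, idx) {
  name <- paste(sample(.GIVEN_NAMES, 1), sample(.FAMILY_NAMES, 1))
  order_date <- .rand_date("2024-01-01", "2026-06-30")
  obs_date <- as.character(as.Date(order_date) + sample.int(14, 1))
  issued <- as.character(as.Date(obs_date) + sample.int(7, 1))
  nvar <- if (config$variants_max == config$variants_min) config$variants_min
          else sample(seq(config$variants_min, config$variants_max), 1)
  rep <- sequencing_report(
    subject = list(identifier = sprintf("%08d", sample.int(99999999, 1)),
                   name = name,
                   birth_date = .rand_date("1935-01-01", "2005-12-31"),
                   sex_code = sample(value_set("sex_iso22220")$code, 1),
                   ethnicity_code = sample(value_set("race_hl7v3")$code, 1)),
    order = list(order_id = sprintf("ORD-%05d", idx),
                 order_date = order_date,
                 ordering_clinician = paste("Dr.", sample(.FAMILY_NAMES, 1)),
                 legally_authorized_person = paste(sample(.GIVEN_NAMES, 1),
                                                   sample(.FAMILY_NAMES, 1)),
                 performing_laboratory = sample(.LABS, 1)),
    report = list(report_id = sprintf("RPT-%05d", idx), status = "final",
                  test_code = "solid-tumor-ngs-panel", issued_date = issued,
                  interpretation_summary = sample(
                    c("Actionable somatic variant(s) detected.",
                      "No actionable somatic variant detected.",
                      "Findings of uncertain significance; follow-up advised."), 1),
                  assessed_condition = sample(c("Malignant melanoma",
                                                "Lung adenocarcinoma",
                                                "Colorectal carcinoma"), 1)),
    specimen = list(biomaterial_type = sample(c("Tumor tissue (FFPE)",
                                                "Fresh frozen tumor tissue",
                                                "Peripheral blood"), 1),
                    specimen_id = sprintf("SPC-%05d", sample.int(99999, 1)),
                    collection_date = order_date),
    variants = lapply(seq_len(nvar), function(i) .gen_variant(obs_date)),
    treatments = as.list(sample(c("Vemurafenib", "Dabrafenib", "Osimertinib",
                                  "Trametinib", "Cetuximab"),
                                sample.int(2, 1))),
    research = if (stats::runif(1) < config$include_research_block) {
      .gen_research(config$missingness)
    })
  if (config$corrupt_required) {
    # blank a random non-empty subset of required report-level fields
    rep$subject$name <- NULL
    if (stats::runif(1) < 0.5) rep$order$order_id <- NULL
    if (stats::runif(1) < 0.5) rep$report$issued_date <- NULL
  }
  rep
}

#' Generate a corpus of synthetic sequencing reports
#'
#' Deterministic under the configured seed; with \code{missingness = 0} and
#' \code{corrupt_required = FALSE} every generated report validates cleanly.
#' The RNG state of the session is left untouched.
#'
#' @param config A [generator_config()].
#' @return List of \code{sequencing_report}s.
#' @export
generate_reports <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  lapply(seq_len(config$n_reports), function(i) .gen_report(config, i))
}
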