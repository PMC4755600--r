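## One-call characterization pipeline: composition -> MT-likeness ->
## module decomposition -> Cu capacity, with optional gene-model and
## peak-assignment stages, serialized to a single JSON report.

REPORT_SCHEMA_VERSION <- "1.0"

#' Configuration for the characterization pipeline
#'
#' @param protein_fasta Path to a protein FASTA (first record is analysed),
#'   or `NULL` when `protein` is given directly.
#' @param protein Optional [protein_record()] (overrides `protein_fasta`).
#' @param thresholds MT-likeness cutoffs ([mt_thresholds()]).
#' @param profiles Box profiles for [decompose()].
#' @param allow_degenerate Admit 6-Cys degenerate boxes.
#' @param n_term_extension Residues prepended for the mass computation.
#' @param cdna_fasta,genome_fasta Optional paths enabling the gene-model
#'   stage.
#' @param splice A [splice_params()] object.
#' @param promoter_window Upstream window (bp) scanned for promoter motifs
#'   when the gene-model stage runs (default 1500).
#' @param motifs Promoter motifs ([default_motifs()]).
#' @param peaks_csv Optional deconvoluted peak CSV enabling the
#'   stoichiometry stage (uses the protein's computed apo mass).
#' @param metals Metal specs for peak assignment.
#' @param tolerance_rel Relative mass tolerance for peak assignment.
#' @param observed_majors Optional observed major Cu counts for the
#'   capacity-consistency stage.
#' @param out_dir Optional output directory for `report.json`/`report.txt`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(protein_fasta = NULL, protein = NULL,
                            thresholds = mt_thresholds(),
                            profiles = list(seven_cys_profile()),
                            allow_degenerate = TRUE, n_term_extension = "",
                            cdna_fasta = NULL, genome_fasta = NULL,
                            splice = splice_params(), promoter_window = 1500L,
                            motifs = default_motifs(), peaks_csv = NULL,
                            metals = default_metals(c("Zn", "Cu")),
                            tolerance_rel = 0.001, observed_majors = NULL,
                            out_dir = NULL) {
  if (is.null(protein) && is.null(protein_fasta)) {
    stop("pipeline needs a protein (protein_fasta or protein)", call. = FALSE)
  }
  for (path in c(protein_fasta, cdna_fasta, genome_fasta, peaks_csv)) {
    if (!is.null(path) && !file.exists(path)) {
      stop(sprintf("input file not found: %s", path), call. = FALSE)
    }
  }
  structure(list(protein_fasta = protein_fasta, protein = protein,
                 thresholds = thresholds, profiles = profiles,
                 allow_degenerate = allow_degenerate,
                 n_term_extension = n_term_extension,
                 cdna_fasta = cdna_fasta, genome_fasta = genome_fasta,
                 splice = splice, promoter_window = promoter_window,
                 motifs = motifs, peaks_csv = peaks_csv, metals = metals,
                 tolerance_rel = tolerance_rel,
                 observed_majors = observed_majors, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full characterization pipeline
#'
#' Stages: composition summary, MT-likeness verdict, Cys-box architecture,
#' Cu(I) capacity prediction, and optionally spliced gene-model
#' reconstruction with promoter scan and deconvoluted-peak stoichiometry
#' assignment. Any stage error aborts the run with the stage name attached;
#' no partial report is written.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return List of class `pipeline_report` (also written as JSON + text
#'   summary when `config$out_dir` is set).
#' @export
run_report <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_line <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    log_line("[%s] running", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  record <- stage("input", {
    if (!is.null(config$protein)) as_protein_record(config$protein)
    else read_protein_fasta(config$protein_fasta)[[1]]
  })
  comp <- stage("characterize", summarize_composition(record))
  verdict <- stage("mt_screen", is_mt_like(comp, config$thresholds))
  arch <- stage("decompose", decompose(record, config$profiles,
                                       allow_degenerate = config$allow_degenerate))
  capacity <- stage("capacity", cu_capacity(arch))
  apo <- stage("mass", average_mass(record, config$n_term_extension))

  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    protein_id = record$id,
    composition = unclass(comp)[c("length", "cys_count", "cys_fraction",
                                  "his_count", "met_count", "aromatic_count",
                                  "cys_in_cxc", "average_mass_da")],
    apo_mass_with_extension = apo,
    mt_verdict = unclass(verdict),
    architecture = architecture_report(arch),
    capacity = unclass(capacity)[c("base_total", "extra_cys", "max_total")]
  )
  if (!is.null(config$observed_majors)) {
    report$capacity_consistency <- stage("capacity_consistency",
      capacity_consistency(capacity, config$observed_majors))
  }
  if (!is.null(config$cdna_fasta) && !is.null(config$genome_fasta)) {
    model <- stage("genemodel", {
      cdna <- read_dna_fasta(config$cdna_fasta)[1]
      genome <- read_dna_fasta(config$genome_fasta)[1]
      spliced_align(cdna, genome, config$splice)
    })
    promoter <- stage("promoter", {
      genome <- read_dna_fasta(config$genome_fasta)[[1]]
      coding <- model$coding
      ## genomic position of the A of the ATG on the model strand
      hits <- data.frame()
      if (!is.na(coding$coding_start) && model$strand == "+") {
        atg_g <- map_cdna_to_genome(model, coding$coding_start, coding$coding_start)
        atg_pos <- atg_g$start0[1] + 1L
        win_from <- max(1L, atg_pos - config$promoter_window)
        if (atg_pos > 1L) {
          upstream <- substr(genome, win_from, atg_pos - 1L)
          hits <- scan_promoter(upstream, config$motifs)
        }
      }
      hits
    })
    report$gene_model <- list(
      scaffold_id = model$scaffold_id, strand = model$strand,
      n_exons = nrow(model$exons), n_introns = nrow(model$introns),
      exons = model$exons, introns = model$introns,
      mismatches = model$mismatches, coding = model$coding)
    report$promoter_hits <- promoter
    report$gff3 <- export_gff3(model)
  }
  if (!is.null(config$peaks_csv)) {
    assignments <- stage("assign_peaks", {
      peaks <- read_peaklist(config$peaks_csv)
      assign_peaks(peaks$mass_da, apo_mass = apo, metals = config$metals,
                   cys_count = comp$cys_count,
                   tolerance_rel = config$tolerance_rel)
    })
    report$peak_assignments <- best_assignments(assignments)
  }
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    json_path <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    writeLines(format_report(report), file.path(config$out_dir, "report.txt"))
    if (!is.null(report$gff3)) {
      writeLines(report$gff3, file.path(config$out_dir, "model.gff3"))
    }
    log_line("[output] wrote %s", json_path)
  }
  report
}

## human-readable summary derived from the report object (single source of
## truth: everything here is read back from the structured fields)
format_report <- function(report) {
  c(sprintf("modmt report (schema %s)", report$schema_version),
    sprintf("protein: %s", report$protein_id),
    sprintf("length %d aa, Cys %d (%.1f%%), %d in CXC; His %d; aromatics %d",
            report$composition$length, report$composition$cys_count,
            100 * report$composition$cys_fraction, report$composition$cys_in_cxc,
            report$composition$his_count, report$composition$aromatic_count),
    sprintf("average mass %.2f Da (with extension: %.2f Da)",
            report$composition$average_mass_da, report$apo_mass_with_extension),
    sprintf("MT-like: %s", report$mt_verdict$is_mt_like),
    sprintf("architecture: %s", report$architecture$totals_line),
    sprintf("Cu capacity: base %d, max %d", report$capacity$base_total,
            report$capacity$max_total),
    if (!is.null(report$gene_model)) {
      sprintf("gene model: %d exons / %d introns on %s (%s), %d mismatches",
              report$gene_model$n_exons, report$gene_model$n_introns,
              report$gene_model$scaffold_id, report$gene_model$strand,
              report$gene_model$mismatches)
    },
    if (!is.null(report$promoter_hits) && nrow(report$promoter_hits) > 0) {
      sprintf("promoter: %s", paste(sprintf("%s@%d", report$promoter_hits$motif_name,
                                            report$promoter_hits$offset), collapse = ", "))
    },
    if (!is.null(report$peak_assignments)) {
      sprintf("peaks: %s", paste(report$peak_assignments$best_label, collapse = ", "))
    })
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Paths of the database sequence records used for validation
#'
#' The full-length MT cDNA, protein, genomic scaffold region and the
#' 104-residue partial ORF that validation against published values needs
#' are GenBank/JGI records and are not redistributed with the package.
#' Download them (FASTA) and place them under the given directory as
#' `KM244758.1.fasta` (cDNA), `AJK28606.1.fasta` (protein),
#' `JH711530.1.fasta` (scaffold or scaffold slice covering the locus) and
#' `EIW70699.fasta` (partial ORF protein).
#'
#' @param dir Directory holding the records (defaults to the package's
#'   `extdata/accessions`).
#' @return Named character vector of file paths (existing or not).
#' @export
tmmt_accession_files <- function(dir = system.file("extdata", "accessions",
                                                   package = "modmt")) {
  if (is.null(dir) || dir == "") dir <- file.path("inst", "extdata", "accessions")
  c(cdna = file.path(dir, "KM244758.1.fasta"),
    protein = file.path(dir, "AJK28606.1.fasta"),
    scaffold = file.path(dir, "JH711530.1.fasta"),
    partial_orf = file.path(dir, "EIW70699.fasta"))
}
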