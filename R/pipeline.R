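# Pipeline orchestration: file-in/file-out wrappers tying the stages
# together (design -> genotype -> express -> summarize; aflp;
# simulate), used directly from R or through the bundled command-line
# script (inst/cli/homeocaps.R).

pkg_version <- function() {
  as.character(utils::packageVersion("homeoCAPS"))
}

write_tsv_report <- function(df, path, config_note = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# homeoCAPS ", pkg_version(),
                    if (nzchar(config_note)) paste0(" | ", config_note)),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

config_note <- function(gel, extra = character(0L)) {
  paste(c(sprintf("min_detectable_bp=%g", gel$min_detectable_bp),
          sprintf("comigration_rel_tol=%g", gel$comigration_rel_tol),
          extra), collapse = " ")
}

#' Design stage: assay report from alleles and an enzyme panel
#'
#' @param alleles_fasta FASTA of parental allele pairs (see
#'   [read_fasta()] / [locus_alleles()] for the header convention).
#' @param enzymes_tsv optional enzyme panel TSV (default: bundled
#'   panel).
#' @param out_dir output directory (created if needed).
#' @param gel a [gel_config()].
#' @return Invisibly, the assay table; writes `assays.tsv` with loci
#'   lacking any informative enzyme flagged. Warns when no locus is
#'   informative.
#' @export
run_design <- function(alleles_fasta, enzymes_tsv = NULL,
                       out_dir = ".", gel = gel_config()) {
  alleles <- locus_alleles(read_fasta(alleles_fasta))
  panel <- if (is.null(enzymes_tsv)) default_enzyme_panel() else
    read_enzymes(enzymes_tsv)
  assays <- design_best_assays(alleles, panel, gel)
  tab <- assay_table(assays)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_report(tab, file.path(out_dir, "assays.tsv"),
                   config_note(gel))
  if (!any(tab$informative)) {
    warning("no locus has an informative assay under this panel",
            call. = FALSE)
  }
  invisible(tab)
}

#' Full pipeline: genotype, expression and summary reports
#'
#' Runs assay design, genomic-tier genotyping (including
#' parental-polymorphism exclusion), cDNA-tier expression calling and
#' the study tallies, writing `genotype_calls.tsv`,
#' `expression_calls.tsv`, `locus_summary.tsv`, `per_population.tsv`
#' and `study_summary.json`. Deterministic given identical inputs.
#'
#' @param alleles_fasta FASTA of parental allele pairs.
#' @param observations_tsv observed band patterns (see
#'   [read_observations()]).
#' @param individuals_tsv individuals table (see
#'   [read_individuals()]).
#' @param enzymes_tsv optional enzyme panel TSV.
#' @param out_dir output directory.
#' @param gel a [gel_config()].
#' @param decimals decimal places for report percentages.
#' @return Invisibly, a list with the study object, expression calls
#'   and summary.
#' @export
run_pipeline <- function(alleles_fasta, observations_tsv,
                         individuals_tsv, enzymes_tsv = NULL,
                         out_dir = ".", gel = gel_config(),
                         decimals = 1) {
  alleles <- locus_alleles(read_fasta(alleles_fasta))
  panel <- if (is.null(enzymes_tsv)) default_enzyme_panel() else
    read_enzymes(enzymes_tsv)
  observations <- read_observations(observations_tsv)
  if (nrow(observations) == 0L) {
    stop("observations file is empty", call. = FALSE)
  }
  individuals <- read_individuals(individuals_tsv)
  assays <- design_best_assays(alleles, panel, gel)
  study <- genotype_study(observations, assays, individuals)
  expr <- expression_study(study, observations, assays)
  summ <- study_summary(study, individuals, expr, decimals)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  note <- config_note(gel, sprintf("decimals=%d", decimals))
  write_tsv_report(study$calls,
                   file.path(out_dir, "genotype_calls.tsv"), note)
  write_tsv_report(expr, file.path(out_dir, "expression_calls.tsv"),
                   note)
  ls_df <- data.frame(
    locus_id = vapply(study$locus_summaries, `[[`, character(1L),
                      "locus_id"),
    gene_status = vapply(study$locus_summaries, `[[`, character(1L),
                         "gene_status"),
    lost_parents = vapply(study$locus_summaries, function(s)
      paste(s$lost_parent_set, collapse = ","), character(1L)),
    stringsAsFactors = FALSE)
  write_tsv_report(ls_df, file.path(out_dir, "locus_summary.tsv"), note)
  write_tsv_report(summ$per_population,
                   file.path(out_dir, "per_population.tsv"), note)
  summ_json <- unclass(summ)
  summ_json$gene_status <- as.list(summ$gene_status)
  jsonlite::write_json(summ_json,
                       file.path(out_dir, "study_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(study = study, expression = expr, summary = summ))
}

#' AFLP stage: Table-style summary from a fragment matrix
#'
#' @param matrix_tsv fragment matrix TSV (see
#'   [read_fragment_matrix()]).
#' @param individuals_tsv individuals table.
#' @param out_dir output directory.
#' @param decimals decimal places for percentages.
#' @return Invisibly, the `aflp_summary`; writes `aflp_summary.tsv` and
#'   `aflp_summary.json`.
#' @export
run_aflp <- function(matrix_tsv, individuals_tsv, out_dir = ".",
                     decimals = 1) {
  individuals <- read_individuals(individuals_tsv)
  m <- read_fragment_matrix(matrix_tsv, individuals)
  s <- summarize_matrix(m, decimals)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  classes <- c("monomorphic", "polymorphic", "novel",
               "maternal_origin", "paternal_origin", "other")
  df <- data.frame(class = c("total", classes),
                   count = c(s$total,
                             vapply(classes, function(cl) s[[cl]],
                                    numeric(1L))),
                   percent = c(100,
                               vapply(classes, function(cl)
                                 s[[paste0("pct_", cl)]], numeric(1L))),
                   stringsAsFactors = FALSE)
  write_tsv_report(df, file.path(out_dir, "aflp_summary.tsv"),
                   sprintf("decimals=%d", decimals))
  jsonlite::write_json(unclass(s),
                       file.path(out_dir, "aflp_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(s)
}

#' Simulation stage: write a synthetic dataset to disk
#'
#' Emits the same FASTA/TSV formats the pipeline consumes
#' (`alleles.fasta`, `individuals.tsv`, `observations.tsv`) plus the
#' ground truth (`truth.tsv`) and a manifest recording the seed and
#' package version.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @return Invisibly, the `caps_sim` object.
#' @export
run_simulate <- function(cfg, out_dir = ".") {
  sim <- simulate_cohort(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(alleles_to_fasta_df(sim$alleles),
              file.path(out_dir, "alleles.fasta"))
  note <- sprintf("seed=%d", cfg$seed)
  write_tsv_report(sim$individuals,
                   file.path(out_dir, "individuals.tsv"), note)
  write_tsv_report(sim$observations,
                   file.path(out_dir, "observations.tsv"), note)
  truth <- sim$truth
  truth$silenced_parents <- paste0(
    ifelse(truth$silenced_maternal, "maternal", ""),
    ifelse(truth$silenced_maternal & truth$silenced_paternal, ",", ""),
    ifelse(truth$silenced_paternal, "paternal", ""))
  write_tsv_report(
    truth[, c("individual_id", "locus_id", "state", "silenced_parents")],
    file.path(out_dir, "truth.tsv"), note)
  manifest <- list(tool = "homeoCAPS", version = pkg_version(),
                   seed = cfg$seed, n_loci = cfg$n_loci,
                   locus_length = cfg$locus_length)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(sim)
}
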