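# Study-level tallies: gene-status counts, per-parent homeolog loss
# percentages, silencing tallies and per-population breakdowns.

round_half_up <- function(x, decimals) {
  s <- 10^decimals
  floor(x * s + 0.5 + 1e-9) / s
}

#' Printed-percentage convention
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals`
#' places. Half-up (rather than banker's) rounding reproduces the
#' display convention used for population-survey tables (e.g. 11/58
#' prints as 18.97 at two decimals).
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @param decimals decimal places (default 1).
#' @return Rounded percentage.
#' @export
percent <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) {
    stop("percent() needs a positive denominator", call. = FALSE)
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Tally locus-level gene statuses
#'
#' @param summaries list of locus summaries (from [genotype_study()] or
#'   [summarize_locus()]).
#' @return Named integer vector: `additive_all`, `loss_detected`,
#'   `excluded` and `uninformative` counts. The first three partition
#'   the assayable genes.
#' @export
tally_gene_status <- function(summaries) {
  ids <- vapply(summaries, `[[`, character(1L), "locus_id")
  if (anyDuplicated(ids)) {
    stop("duplicate locus_id '", ids[duplicated(ids)][1L],
         "' in summaries", call. = FALSE)
  }
  st <- vapply(summaries, `[[`, character(1L), "gene_status")
  c(additive_all = sum(st == "additive_all"),
    loss_detected = sum(st == "loss_detected"),
    excluded = sum(st == "excluded_parental_polymorphism"),
    uninformative = sum(st == "uninformative"))
}

#' Per-parent homeolog loss tally
#'
#' The denominator is homeologs assayed = 2 x informative
#' (non-excluded, non-uninformative) genes: each gene contributes one
#' maternal and one paternal homeolog. Excluded loci contribute
#' nothing. Per-individual event counts deduplicate by (individual,
#' locus).
#'
#' @param summaries list of locus summaries.
#' @param calls optional genotype-call data.frame (from
#'   [genotype_study()]) for the per-individual counts.
#' @param decimals decimal places for the percentages (default 1).
#' @return List with `informative_gene_count`, `homeologs_assayed`,
#'   per-parent `genes_with_loss` and `percent_of_homeologs`,
#'   `combined` gene-level losses and percentage, and (when `calls` is
#'   given) `individuals_with_loss`.
#' @export
tally_by_parent <- function(summaries, calls = NULL, decimals = 1) {
  st <- vapply(summaries, `[[`, character(1L), "gene_status")
  informative <- summaries[st %in% c("additive_all", "loss_detected")]
  n_inf <- length(informative)
  homeologs <- 2L * n_inf
  lost_m <- sum(vapply(informative, function(s)
    "maternal" %in% s$lost_parent_set, logical(1L)))
  lost_p <- sum(vapply(informative, function(s)
    "paternal" %in% s$lost_parent_set, logical(1L)))
  out <- list(
    informative_gene_count = n_inf,
    homeologs_assayed = homeologs,
    maternal = list(
      genes_with_loss = lost_m,
      percent_of_homeologs = if (homeologs > 0)
        percent(lost_m, homeologs, decimals) else NA_real_),
    paternal = list(
      genes_with_loss = lost_p,
      percent_of_homeologs = if (homeologs > 0)
        percent(lost_p, homeologs, decimals) else NA_real_),
    combined = list(
      genes_with_loss = lost_m + lost_p,
      percent_of_homeologs = if (homeologs > 0)
        percent(lost_m + lost_p, homeologs, decimals) else NA_real_)
  )
  if (!is.null(calls)) {
    loss <- calls[calls$call %in% c("loss_maternal", "loss_paternal"), ,
                  drop = FALSE]
    loss <- unique(loss[, c("individual_id", "locus_id", "call")])
    out$individuals_with_loss <- length(unique(loss$individual_id))
    out$loss_events <- nrow(loss)
  }
  out
}

#' Silencing tallies at the cDNA tier
#'
#' Counts genes with at least one silenced individual (gene level) and
#' individuals with at least one silencing event (individual level).
#' The gene-level denominator is 2 x the number of informative genes
#' assayed at the cDNA tier.
#'
#' @param expr_calls expression-call data.frame from
#'   [expression_study()].
#' @param decimals decimal places (default 1).
#' @return List with `cdna_gene_count`, `cdna_homeologs`,
#'   `genes_with_silencing`, `silenced_homeologs` (gene-level,
#'   per-parent deduplicated), `percent_of_homeologs`,
#'   `individuals_with_silencing`.
#' @export
tally_silencing <- function(expr_calls, decimals = 1) {
  loci <- unique(expr_calls$locus_id)
  sil <- expr_calls[expr_calls$expression_call %in%
                      c("silenced_maternal", "silenced_paternal"), ,
                    drop = FALSE]
  # gene-level: a (locus, silenced parent) pair counts once
  pairs <- unique(sil[, c("locus_id", "expression_call")])
  homeologs <- 2L * length(loci)
  list(
    cdna_gene_count = length(loci),
    cdna_homeologs = homeologs,
    genes_with_silencing = length(unique(sil$locus_id)),
    silenced_homeologs = nrow(pairs),
    percent_of_homeologs = if (homeologs > 0)
      percent(nrow(pairs), homeologs, decimals) else NA_real_,
    individuals_with_silencing = length(unique(sil$individual_id))
  )
}

#' Per-population loss and silencing breakdown
#'
#' Counts, per population, the distinct loci with at least one loss
#' call and the distinct loci with at least one silencing call among
#' that population's individuals. A locus lost in two populations
#' counts once in each.
#'
#' @param calls genotype-call data.frame (with `population_id`).
#' @param individuals individuals data.frame (used to validate ids and
#'   enumerate populations).
#' @param expr_calls optional expression-call data.frame.
#' @return data.frame with `population_id`, `loss_loci`,
#'   `silencing_loci`.
#' @export
per_population_breakdown <- function(calls, individuals,
                                     expr_calls = NULL) {
  unknown <- setdiff(calls$individual_id, individuals$individual_id)
  if (length(unknown)) {
    stop("calls reference unknown individual(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pop_of <- stats::setNames(individuals$population_id,
                            individuals$individual_id)
  pops <- unique(pop_of[unique(calls$individual_id)])
  loss <- calls[calls$call %in% c("loss_maternal", "loss_paternal"), ,
                drop = FALSE]
  out <- data.frame(population_id = pops, loss_loci = 0L,
                    silencing_loci = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(pops)) {
    ids <- names(pop_of)[pop_of == pops[i]]
    out$loss_loci[i] <-
      length(unique(loss$locus_id[loss$individual_id %in% ids]))
    if (!is.null(expr_calls)) {
      sil <- expr_calls[expr_calls$expression_call %in%
                          c("silenced_maternal", "silenced_paternal") &
                          expr_calls$individual_id %in% ids, , drop = FALSE]
      out$silencing_loci[i] <- length(unique(sil$locus_id))
    }
  }
  out
}

#' Assemble the full study summary
#'
#' @param study `caps_study` from [genotype_study()].
#' @param individuals individuals data.frame.
#' @param expr_calls optional expression-call data.frame.
#' @param decimals decimal places for percentages.
#' @return List of class `study_summary` combining the gene-status
#'   partition, the per-parent loss tally, silencing tallies and the
#'   per-population breakdown.
#' @export
study_summary <- function(study, individuals, expr_calls = NULL,
                          decimals = 1) {
  status <- tally_gene_status(study$locus_summaries)
  parent <- tally_by_parent(study$locus_summaries, study$calls, decimals)
  sil <- if (!is.null(expr_calls) && nrow(expr_calls))
    tally_silencing(expr_calls, decimals) else NULL
  pops <- per_population_breakdown(study$calls, individuals, expr_calls)
  structure(list(
    genes_surveyed = sum(status[c("additive_all", "loss_detected",
                                  "excluded")]),
    gene_status = status,
    loss_tally = parent,
    silencing = sil,
    per_population = pops
  ), class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Study summary:", x$genes_surveyed, "assayable genes\n")
  cat("  additive:", x$gene_status[["additive_all"]],
      "| loss:", x$gene_status[["loss_detected"]],
      "| excluded:", x$gene_status[["excluded"]], "\n")
  lt <- x$loss_tally
  cat("  homeologs assayed:", lt$homeologs_assayed, "\n")
  cat(sprintf("  maternal losses: %d genes (%s%%)\n",
              lt$maternal$genes_with_loss,
              format(lt$maternal$percent_of_homeologs)))
  cat(sprintf("  paternal losses: %d genes (%s%%)\n",
              lt$paternal$genes_with_loss,
              format(lt$paternal$percent_of_homeologs)))
  if (!is.null(x$silencing)) {
    cat(sprintf("  silenced homeologs: %d of %d (%s%%)\n",
                x$silencing$silenced_homeologs, x$silencing$cdna_homeologs,
                format(x$silencing$percent_of_homeologs)))
  }
  invisible(x)
}
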