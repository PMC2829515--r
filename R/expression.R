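# cDNA-tier expression calling: separating true homeolog silencing
# from absence that merely reflects a genomic loss. This contrast is
# the methodological core: a missing transcript band is only evidence
# of silencing when the genomic tier shows the homeolog is still there.

EXPRESSION_CALLS <- c("both_expressed", "silenced_maternal",
                      "silenced_paternal", "absent_due_to_genomic_loss",
                      "unscorable")

#' Call the expression state of one individual at one locus
#'
#' Contrasts the cDNA band pattern with the genomic genotype call.
#' Silencing of a parent requires an additive genomic call together
#' with zero matched cDNA diagnostic bands for that parent and at
#' least one for the other; when the genomic call is a loss, a missing
#' transcript is `absent_due_to_genomic_loss`, never silencing. An
#' unscorable or ambiguous genomic call makes the expression tier
#' unscorable too.
#'
#' @param genomic_call genotype enum from [call_genotype()].
#' @param cdna_bands observed cDNA band sizes (numeric vector).
#' @param assay the locus's informative `caps_assay`.
#' @return One of the expression enums.
#' @export
call_expression <- function(genomic_call, cdna_bands, assay) {
  if (!isTRUE(assay$informative)) {
    stop("call_expression requires an informative assay", call. = FALSE)
  }
  if (genomic_call %in% c("unscorable", "ambiguous_polymorphism")) {
    return("unscorable")
  }
  tol <- assay$gel$comigration_rel_tol
  m <- count_matched(cdna_bands, assay$maternal_diagnostic, tol)
  p <- count_matched(cdna_bands, assay$paternal_diagnostic, tol)
  if (genomic_call == "additive") {
    if (m >= 1L && p >= 1L) return("both_expressed")
    if (m == 0L && p >= 1L) return("silenced_maternal")
    if (m >= 1L && p == 0L) return("silenced_paternal")
    return("unscorable")  # empty or uninterpretable lane
  }
  if (genomic_call == "loss_maternal") {
    if (m == 0L && p >= 1L) return("absent_due_to_genomic_loss")
    return("unscorable")
  }
  if (genomic_call == "loss_paternal") {
    if (p == 0L && m >= 1L) return("absent_due_to_genomic_loss")
    return("unscorable")
  }
  stop("unknown genomic call '", genomic_call, "'", call. = FALSE)
}

#' Relative homeolog expression ratio from band intensities
#'
#' Per-parent intensity is the sum over that parent's matched
#' diagnostic bands; the ratio is paternal over maternal. This is the
#' optional quantitative readout behind dominance statements (e.g.
#' rDNA transcription dominated by one parent's units); the binary
#' silencing call never depends on it.
#'
#' @param intensities named numeric vector, names are band sizes (bp)
#'   as printed in the observations table.
#' @param assay the locus's informative `caps_assay`.
#' @param dominance_threshold ratio beyond which one parent is called
#'   dominant (default 2.0).
#' @return List with `maternal_intensity`, `paternal_intensity`,
#'   `ratio` (`NA` when maternal is 0) and `dominance` (`balanced`,
#'   `paternal_dominant`, `maternal_dominant`, `exclusive_paternal`,
#'   `exclusive_maternal`, or `unscorable` when no diagnostic band was
#'   measured).
#' @export
expression_ratio <- function(intensities, assay, dominance_threshold = 2) {
  if (dominance_threshold <= 1) {
    stop("dominance_threshold must exceed 1", call. = FALSE)
  }
  tol <- assay$gel$comigration_rel_tol
  sizes <- as.numeric(names(intensities))
  sum_parent <- function(diag) {
    hit <- vapply(sizes, band_in_set, logical(1L), set = diag, tol = tol)
    sum(intensities[hit])
  }
  m <- sum_parent(assay$maternal_diagnostic)
  p <- sum_parent(assay$paternal_diagnostic)
  measured <- any(vapply(sizes, band_in_set, logical(1L),
                         set = c(assay$maternal_diagnostic,
                                 assay$paternal_diagnostic), tol = tol))
  if (!measured) {
    return(list(maternal_intensity = NA_real_, paternal_intensity = NA_real_,
                ratio = NA_real_, dominance = "unscorable"))
  }
  ratio <- if (m > 0) p / m else NA_real_
  dominance <- if (m == 0 && p > 0) {
    "exclusive_paternal"
  } else if (p == 0 && m > 0) {
    "exclusive_maternal"
  } else if (ratio >= dominance_threshold) {
    "paternal_dominant"
  } else if (ratio <= 1 / dominance_threshold) {
    "maternal_dominant"
  } else {
    "balanced"
  }
  list(maternal_intensity = m, paternal_intensity = p,
       ratio = ratio, dominance = dominance)
}

#' Run the cDNA-tier expression stage over a whole study
#'
#' Pairs every cDNA observation of a polyploid or F1 individual with
#' that individual's genomic genotype call at the same locus and calls
#' the expression state. cDNA observations without a genomic
#' counterpart yield no silencing call (only "not detected"), enforcing
#' that silencing cannot be inferred from transcript data alone.
#'
#' @param study `caps_study` from [genotype_study()].
#' @param observations observations data.frame (the `cdna` tier rows
#'   are used).
#' @param assays named list of `caps_assay` per locus.
#' @return data.frame of expression calls per individual x locus.
#' @export
expression_study <- function(study, observations, assays) {
  cdna <- observations[observations$tier == "cdna", , drop = FALSE]
  key <- paste(study$calls$individual_id, study$calls$locus_id)
  genomic_call <- stats::setNames(study$calls$call, key)
  keep <- paste(cdna$individual_id, cdna$locus_id) %in% key
  cdna <- cdna[keep, , drop = FALSE]
  n <- nrow(cdna)
  out <- data.frame(
    individual_id = cdna$individual_id, locus_id = cdna$locus_id,
    genomic_call = character(n), expression_call = character(n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    g <- genomic_call[[paste(cdna$individual_id[i], cdna$locus_id[i])]]
    out$genomic_call[i] <- g
    out$expression_call[i] <- call_expression(
      g, parse_bands(cdna$bands[i]), assays[[cdna$locus_id[i]]]
    )
  }
  out
}
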