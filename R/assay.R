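# Diagnostic CAPS assay design: which enzymes distinguish the two
# parental alleles of a locus on a gel.

new_caps_assay <- function(locus_id, enzyme, site, cut_offset,
                           maternal_bands, paternal_bands, gel) {
  tol <- gel$comigration_rel_tol
  md <- band_setdiff(maternal_bands, paternal_bands, tol)
  pd <- band_setdiff(paternal_bands, maternal_bands, tol)
  structure(list(
    locus_id = locus_id, enzyme = enzyme, site = site,
    cut_offset = cut_offset,
    maternal_bands = maternal_bands, paternal_bands = paternal_bands,
    maternal_diagnostic = md, paternal_diagnostic = pd,
    informative = length(md) > 0L && length(pd) > 0L,
    gel = gel
  ), class = "caps_assay")
}

#' Design candidate CAPS assays for one locus
#'
#' Digests both parental alleles with every enzyme in the panel,
#' converts the fragments to gel bands, and computes the
#' parent-diagnostic bands by set difference under the co-migration
#' comparator. An assay is informative when both parents retain at
#' least one diagnostic band.
#'
#' @param locus_id locus identifier.
#' @param maternal,paternal concrete parental allele sequences.
#' @param panel enzyme data.frame (`name`, `site`, `cut_offset`), e.g.
#'   [default_enzyme_panel()].
#' @param gel a [gel_config()].
#' @param both_strands scan both strands (default `TRUE`).
#' @return List of `caps_assay` objects, one per enzyme, sorted
#'   informative-first then by enzyme name.
#' @export
design_assays <- function(locus_id, maternal, paternal,
                          panel = default_enzyme_panel(),
                          gel = gel_config(), both_strands = TRUE) {
  maternal <- assert_concrete(maternal, paste0("maternal allele of ", locus_id))
  paternal <- assert_concrete(paternal, paste0("paternal allele of ", locus_id))
  if (nrow(panel) == 0L) return(list())
  assays <- lapply(seq_len(nrow(panel)), function(i) {
    mb <- to_band_set(digest_sequence(maternal, panel$site[i],
                                      panel$cut_offset[i], both_strands), gel)
    pb <- to_band_set(digest_sequence(paternal, panel$site[i],
                                      panel$cut_offset[i], both_strands), gel)
    new_caps_assay(locus_id, panel$name[i], panel$site[i],
                   panel$cut_offset[i], mb, pb, gel)
  })
  informative <- vapply(assays, `[[`, logical(1L), "informative")
  nm <- vapply(assays, `[[`, character(1L), "enzyme")
  assays[order(!informative, nm)]
}

#' Design assays for every locus of an allele table
#'
#' @param alleles data.frame from [locus_alleles()] (`locus_id`,
#'   `maternal`, `paternal`).
#' @inheritParams design_assays
#' @return Named list (by locus) of `caps_assay` objects: the first
#'   informative assay per locus, or an uninformative placeholder when
#'   no enzyme distinguishes the alleles.
#' @export
design_best_assays <- function(alleles, panel = default_enzyme_panel(),
                               gel = gel_config(), both_strands = TRUE) {
  out <- lapply(seq_len(nrow(alleles)), function(i) {
    design_assays(alleles$locus_id[i], alleles$maternal[i],
                  alleles$paternal[i], panel, gel, both_strands)[[1L]]
  })
  names(out) <- alleles$locus_id
  out
}

#' Predict the gel pattern of a polyploid genotype state
#'
#' @param assay an informative `caps_assay`.
#' @param state one of `"additive"` (union of both parents' bands,
#'   co-migration merged), `"maternal_only"`, `"paternal_only"`.
#' @return Band set (descending numeric vector).
#' @export
predict_polyploid_bands <- function(assay, state) {
  if (!isTRUE(assay$informative)) {
    stop("predict_polyploid_bands requires an informative assay",
         call. = FALSE)
  }
  switch(state,
    additive = band_union(assay$maternal_bands, assay$paternal_bands,
                          assay$gel),
    maternal_only = assay$maternal_bands,
    paternal_only = assay$paternal_bands,
    stop("unknown genotype state '", state, "'", call. = FALSE)
  )
}

#' @export
print.caps_assay <- function(x, ...) {
  cat("CAPS assay: locus", x$locus_id, "| enzyme", x$enzyme,
      paste0("(", x$site, "/", x$cut_offset, ")"),
      if (x$informative) "[informative]" else "[uninformative]", "\n")
  cat("  maternal bands:", paste(x$maternal_bands, collapse = ", "), "\n")
  cat("  paternal bands:", paste(x$paternal_bands, collapse = ", "), "\n")
  cat("  diagnostic (maternal):",
      paste(x$maternal_diagnostic, collapse = ", "), "\n")
  cat("  diagnostic (paternal):",
      paste(x$paternal_diagnostic, collapse = ", "), "\n")
  invisible(x)
}

# comma-joined descending band string (the TSV convention)
format_bands <- function(bands) {
  paste(sort(bands, decreasing = TRUE), collapse = ",")
}

parse_bands <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0L))
  as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]])
}

#' Tabulate designed assays
#'
#' @param assays list of `caps_assay` objects.
#' @return data.frame with one row per assay: locus, enzyme, parental
#'   and diagnostic band lists (comma-joined, descending) and the
#'   informative flag.
#' @export
assay_table <- function(assays) {
  data.frame(
    locus_id = vapply(assays, `[[`, character(1L), "locus_id"),
    enzyme = vapply(assays, `[[`, character(1L), "enzyme"),
    maternal_bands = vapply(assays, function(a) format_bands(a$maternal_bands),
                            character(1L)),
    paternal_bands = vapply(assays, function(a) format_bands(a$paternal_bands),
                            character(1L)),
    maternal_diagnostic = vapply(assays,
                                 function(a) format_bands(a$maternal_diagnostic),
                                 character(1L)),
    paternal_diagnostic = vapply(assays,
                                 function(a) format_bands(a$paternal_diagnostic),
                                 character(1L)),
    informative = vapply(assays, `[[`, logical(1L), "informative"),
    stringsAsFactors = FALSE
  )
}
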