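# Genomic-tier CAPS genotype calling: additive, homeolog loss,
# ambiguity from within-parent polymorphism, or unscorable.

GENOTYPE_CALLS <- c("additive", "loss_maternal", "loss_paternal",
                    "ambiguous_polymorphism", "unscorable")

# how many of the diagnostic bands are present in the observed lane
count_matched <- function(observed, diagnostic, tol) {
  if (length(diagnostic) == 0L) return(0L)
  sum(vapply(diagnostic, band_in_set, logical(1L),
             set = observed, tol = tol))
}

#' Call the genomic genotype of one individual at one locus
#'
#' Observed bands are matched against the assay's parent-diagnostic
#' bands with the co-migration comparator. At least one matched
#' diagnostic band per parent is required (shared fragments carry no
#' parent information, and partial lane dropout must not flip a call):
#' both parents matched gives `additive`; only the paternal side gives
#' `loss_maternal`; only the maternal side gives `loss_paternal`. An
#' empty lane, or a lane matching neither parent, is `unscorable`
#' (never a double loss: a tetraploid lacking both homeologs would not
#' amplify).
#'
#' @param bands observed band sizes (numeric vector; empty = failed
#'   lane).
#' @param assay an informative `caps_assay` for the locus.
#' @return List with `call` (one of the genotype enums) and `evidence`
#'   (matched diagnostic-band counts per parent).
#' @export
call_genotype <- function(bands, assay) {
  if (!isTRUE(assay$informative)) {
    stop("call_genotype requires an informative assay", call. = FALSE)
  }
  tol <- assay$gel$comigration_rel_tol
  m <- count_matched(bands, assay$maternal_diagnostic, tol)
  p <- count_matched(bands, assay$paternal_diagnostic, tol)
  call <- if (length(bands) == 0L) {
    "unscorable"
  } else if (m >= 1L && p >= 1L) {
    "additive"
  } else if (m == 0L && p >= 1L) {
    "loss_maternal"
  } else if (m >= 1L && p == 0L) {
    "loss_paternal"
  } else {
    "unscorable"
  }
  list(call = call,
       evidence = list(maternal_matched = m, paternal_matched = p))
}

#' Detect within-parent polymorphism at a locus
#'
#' Groups the genomic band patterns of one parent species' individuals
#' by band-set equality under the co-migration comparator. More than
#' one pattern class means the parent is polymorphic at this locus,
#' which makes loss calls in the polyploid uninterpretable (the locus
#' is then excluded from loss tallies).
#'
#' @param band_sets list of observed band vectors, one per parent
#'   individual, all at the same locus.
#' @param tol co-migration tolerance.
#' @return List with `polymorphic` (logical) and `n_classes` (distinct
#'   pattern classes).
#' @export
detect_parental_polymorphism <- function(band_sets, tol = 0.05) {
  if (length(band_sets) == 0L) {
    stop("detect_parental_polymorphism needs at least one pattern",
         call. = FALSE)
  }
  classes <- list()
  for (bs in band_sets) {
    seen <- any(vapply(classes, band_sets_equal, logical(1L),
                       b = bs, tol = tol))
    if (!seen) classes <- c(classes, list(bs))
  }
  list(polymorphic = length(classes) > 1L, n_classes = length(classes))
}

positional_identity <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(av == bv)
}

#' Sequencing-based confirmation of a putative homeolog loss
#'
#' A gel-inferred loss can instead be a restriction-site polymorphism:
#' sequencing the undigested amplicon distinguishes the two, since a
#' true loss recovers only one parental sequence while a lost cut site
#' still recovers both. Each recovered sequence is assigned to the
#' parental allele with the greater positional identity over the shared
#' coordinate frame (alleles pre-aligned or simulator-born,
#' equal-length); sequences below `min_identity` to both parents, or
#' equidistant from them, are left unassigned rather than guessed.
#'
#' @param recovered character vector of recovered amplicon sequences.
#' @param maternal,paternal parental allele sequences.
#' @param min_identity minimum positional identity for an assignment
#'   (default 0.95).
#' @return List with `recovered_haplotypes` (subset of
#'   `c("maternal", "paternal")`) and `result`: `confirmed_loss`
#'   (exactly one haplotype), `restriction_site_polymorphism` (both),
#'   or `inconclusive` (none assignable, including length-incompatible
#'   comparison frames).
#' @export
confirm_loss <- function(recovered, maternal, paternal,
                         min_identity = 0.95) {
  haps <- character(0L)
  for (s in recovered) {
    if (nchar(s) != nchar(maternal) || nchar(s) != nchar(paternal)) {
      next  # incompatible frame: flagged by omission, not fatal
    }
    im <- positional_identity(s, maternal)
    ip <- positional_identity(s, paternal)
    if (max(im, ip) < min_identity || im == ip) next
    haps <- union(haps, if (im > ip) "maternal" else "paternal")
  }
  result <- if (length(haps) == 1L) {
    "confirmed_loss"
  } else if (length(haps) == 2L) {
    "restriction_site_polymorphism"
  } else {
    "inconclusive"
  }
  list(recovered_haplotypes = haps, result = result)
}

#' Summarize genotype calls across individuals at one locus
#'
#' @param calls character vector of per-individual genotype calls.
#' @param polymorphic_parent was within-parent polymorphism detected at
#'   this locus (which excludes it from loss analyses)?
#' @param locus_id locus identifier.
#' @return List with `locus_id`, `gene_status` (`additive_all`,
#'   `loss_detected` or `excluded_parental_polymorphism`) and
#'   `lost_parent_set`.
#' @export
summarize_locus <- function(calls, polymorphic_parent = FALSE,
                            locus_id = NA_character_) {
  if (length(calls) == 0L) {
    stop("summarize_locus needs at least one call", call. = FALSE)
  }
  lost <- character(0L)
  if (any(calls == "loss_maternal")) lost <- c(lost, "maternal")
  if (any(calls == "loss_paternal")) lost <- c(lost, "paternal")
  status <- if (polymorphic_parent) {
    "excluded_parental_polymorphism"
  } else if (length(lost)) {
    "loss_detected"
  } else {
    "additive_all"
  }
  list(locus_id = locus_id, gene_status = status,
       lost_parent_set = lost)
}

#' Read an observed band-pattern table
#'
#' @param path TSV with columns `individual_id`, `locus_id`, `tier`
#'   (`genomic` or `cdna`), `bands` (comma-joined bp, descending; empty
#'   for a failed lane) and optionally `intensities`
#'   (semicolon-joined `band=value`).
#' @return Validated data.frame.
#' @export
read_observations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#",
                          colClasses = "character")
  required <- c("individual_id", "locus_id", "tier", "bands")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("observations table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- !df$tier %in% c("genomic", "cdna")
  if (any(bad)) {
    stop("unknown tier '", df$tier[bad][1L], "' at row ",
         which(bad)[1L], call. = FALSE)
  }
  df$bands[is.na(df$bands)] <- ""
  df
}

# parse an "band=value;band=value" intensity string to a named vector
parse_intensities <- function(s) {
  if (is.na(s) || !nzchar(s)) return(stats::setNames(numeric(0L), character(0L)))
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) as.numeric(x[2L]), numeric(1L)),
                  vapply(kv, `[[`, character(1L), 1L))
}

#' Run the genomic-tier genotyping stage over a whole study
#'
#' For every polyploid or F1 individual and every locus with an
#' informative assay, calls the genotype from the genomic band pattern;
#' assesses within-parent polymorphism per locus per parent species
#' across all sampled parent individuals (any polymorphism excludes the
#' locus, globally); and summarizes each locus.
#'
#' @param observations data.frame as from [read_observations()].
#' @param assays named list of `caps_assay` per locus (see
#'   [design_best_assays()]).
#' @param individuals individuals data.frame (see
#'   [read_individuals()]).
#' @return Object of class `caps_study`: `calls` (per individual x
#'   locus), `locus_summaries` (per locus), `polymorphic_loci`.
#' @export
genotype_study <- function(observations, assays, individuals) {
  unknown <- setdiff(observations$individual_id, individuals$individual_id)
  if (length(unknown)) {
    stop("observations reference unknown individual(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unknown_loci <- setdiff(observations$locus_id, names(assays))
  if (length(unknown_loci)) {
    stop("observations reference unknown locus/loci: ",
         paste(unknown_loci, collapse = ", "), call. = FALSE)
  }
  genomic <- observations[observations$tier == "genomic", , drop = FALSE]
  role_of <- stats::setNames(individuals$role, individuals$individual_id)
  pop_of <- stats::setNames(individuals$population_id,
                            individuals$individual_id)

  loci <- names(assays)
  informative <- vapply(assays, `[[`, logical(1L), "informative")

  # Parental polymorphism per locus (either parent species). The
  # screen is reference-based: a parent individual's lane flags the
  # locus when it shows a band outside that parent's predicted digest
  # pattern (an extra amplicon class). Missing bands alone never flag:
  # lane dropout would otherwise exclude every locus under gel noise,
  # while real within-parent polymorphism manifests as extra bands
  # (typically the other parent's amplicon class).
  polymorphic <- stats::setNames(logical(length(loci)), loci)
  for (lc in loci) {
    a <- assays[[lc]]
    tol <- a$gel$comigration_rel_tol
    for (r in c("maternal_parent", "paternal_parent")) {
      ref <- if (r == "maternal_parent") a$maternal_bands else
        a$paternal_bands
      ids <- individuals$individual_id[individuals$role == r]
      sub <- genomic[genomic$locus_id == lc &
                       genomic$individual_id %in% ids, , drop = FALSE]
      if (nrow(sub) == 0L) next
      extra <- vapply(sub$bands, function(s) {
        bs <- parse_bands(s)
        length(band_setdiff(bs, ref, tol)) > 0L
      }, logical(1L))
      if (any(extra)) polymorphic[lc] <- TRUE
    }
  }

  # per-individual calls at informative loci
  tgt <- genomic[role_of[genomic$individual_id] %in%
                   c("polyploid", "f1_hybrid"), , drop = FALSE]
  tgt <- tgt[informative[tgt$locus_id], , drop = FALSE]
  n <- nrow(tgt)
  calls <- data.frame(
    individual_id = character(n), population_id = character(n),
    role = character(n), locus_id = character(n),
    call = character(n), maternal_matched = integer(n),
    paternal_matched = integer(n), stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    res <- call_genotype(parse_bands(tgt$bands[i]),
                         assays[[tgt$locus_id[i]]])
    call <- res$call
    if (polymorphic[tgt$locus_id[i]] && call != "unscorable") {
      call <- "ambiguous_polymorphism"
    }
    calls[i, ] <- list(tgt$individual_id[i], pop_of[tgt$individual_id[i]],
                       role_of[tgt$individual_id[i]], tgt$locus_id[i],
                       call, res$evidence$maternal_matched,
                       res$evidence$paternal_matched)
  }

  # locus summaries over informative loci with at least one call
  summaries <- list()
  for (lc in loci) {
    if (!informative[lc]) {
      summaries[[lc]] <- list(locus_id = lc, gene_status = "uninformative",
                              lost_parent_set = character(0L))
      next
    }
    lc_calls <- calls$call[calls$locus_id == lc]
    if (length(lc_calls) == 0L) next
    # exclusion is judged on the raw diagnostic evidence, so re-derive
    # loss flags from the unmasked calls when not polymorphic
    summaries[[lc]] <- summarize_locus(
      if (polymorphic[lc]) rep("additive", length(lc_calls)) else lc_calls,
      polymorphic_parent = polymorphic[lc], locus_id = lc
    )
  }
  structure(list(calls = calls, locus_summaries = summaries,
                 polymorphic_loci = names(polymorphic)[polymorphic]),
            class = "caps_study")
}

#' @export
print.caps_study <- function(x, ...) {
  st <- vapply(x$locus_summaries, `[[`, character(1L), "gene_status")
  cat("CAPS study:", nrow(x$calls), "genotype calls over",
      length(x$locus_summaries), "loci\n")
  print(table(gene_status = st))
  invisible(x)
}
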