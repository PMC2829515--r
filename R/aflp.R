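# cDNA-AFLP fragment scoring: monomorphic vs polymorphic fragments and
# the polymorphic subtypes (novel / maternal-origin / paternal-origin /
# other) over a presence/absence matrix spanning the two diploid
# parents and the polyploid.

#' Construct a validated AFLP fragment matrix
#'
#' @param presence logical (or 0/1) matrix, fragments in rows,
#'   individuals in columns (column names = individual ids). The grid
#'   must be complete: absence is `FALSE`, never missing.
#' @param individuals individuals data.frame covering every column and
#'   containing at least one individual of each of the roles
#'   `maternal_parent`, `paternal_parent` and `polyploid`.
#' @param fragments optional data.frame with `fragment_id`,
#'   `primer_pair`, `approx_size`; defaults are generated from row
#'   names.
#' @return Object of class `fragment_matrix`.
#' @export
fragment_matrix <- function(presence, individuals, fragments = NULL) {
  presence <- as.matrix(presence)
  if (any(is.na(presence))) {
    stop("presence grid must be complete (no missing cells)",
         call. = FALSE)
  }
  if (is.numeric(presence)) {
    if (!all(presence %in% c(0, 1))) {
      stop("presence cells must be 0/1", call. = FALSE)
    }
    presence <- presence == 1
  }
  if (!is.logical(presence)) {
    stop("presence grid must be logical or 0/1", call. = FALSE)
  }
  unknown <- setdiff(colnames(presence), individuals$individual_id)
  if (length(unknown)) {
    stop("individual(s) absent from individuals table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  roles <- individuals$role[match(colnames(presence),
                                  individuals$individual_id)]
  for (r in c("maternal_parent", "paternal_parent", "polyploid")) {
    if (!r %in% roles) {
      stop("fragment matrix needs at least one individual with role '",
           r, "'", call. = FALSE)
    }
  }
  if (is.null(fragments)) {
    ids <- rownames(presence)
    if (is.null(ids)) ids <- sprintf("frag%04d", seq_len(nrow(presence)))
    fragments <- data.frame(fragment_id = ids,
                            primer_pair = NA_character_,
                            approx_size = NA_real_,
                            stringsAsFactors = FALSE)
  }
  structure(list(presence = presence, roles = roles,
                 individuals = individuals, fragments = fragments),
            class = "fragment_matrix")
}

#' Classify one AFLP fragment
#'
#' A fragment present in every individual is `monomorphic`; anything
#' else is `polymorphic`, subdivided by where it occurs: `novel`
#' (present in polyploids, absent from both diploid parents),
#' `maternal_origin` (shared by polyploids and the maternal parent
#' only), `paternal_origin` (symmetric) or `other` (every remaining
#' polymorphic pattern, counted but not subdivided).
#'
#' @param present logical presence vector across individuals.
#' @param roles matching role vector; all three of `maternal_parent`,
#'   `paternal_parent` and `polyploid` must occur.
#' @param polyploid_quantifier `"any"` (default: shared-origin subtypes
#'   require presence in at least one polyploid) or `"all"` (in every
#'   polyploid).
#' @return List with `major` (`monomorphic`/`polymorphic`) and
#'   `subtype` (`NA` for monomorphic fragments).
#' @export
classify_fragment <- function(present, roles,
                              polyploid_quantifier = c("any", "all")) {
  polyploid_quantifier <- match.arg(polyploid_quantifier)
  for (r in c("maternal_parent", "paternal_parent", "polyploid")) {
    if (!r %in% roles) {
      stop("role '", r, "' missing from dataset", call. = FALSE)
    }
  }
  if (all(present)) {
    return(list(major = "monomorphic", subtype = NA_character_))
  }
  quant <- if (polyploid_quantifier == "any") any else all
  in_poly <- quant(present[roles == "polyploid"])
  in_mat <- any(present[roles == "maternal_parent"])
  in_pat <- any(present[roles == "paternal_parent"])
  subtype <- if (in_poly && !in_mat && !in_pat) {
    "novel"
  } else if (in_poly && in_mat && !in_pat) {
    "maternal_origin"
  } else if (in_poly && in_pat && !in_mat) {
    "paternal_origin"
  } else {
    "other"
  }
  list(major = "polymorphic", subtype = subtype)
}

#' Summarize an AFLP fragment matrix
#'
#' Applies [classify_fragment()] to every row and reports counts plus
#' display percentages (round-half-up; the raw fractions are also
#' retained).
#'
#' @param m a `fragment_matrix`.
#' @param decimals decimal places for display percentages (default 1).
#' @param polyploid_quantifier see [classify_fragment()].
#' @return List of class `aflp_summary` with `total`, per-class counts
#'   (`monomorphic`, `polymorphic`, `novel`, `maternal_origin`,
#'   `paternal_origin`, `other`), matching `pct_*` display percentages
#'   and `frac_*` raw fractions.
#' @export
summarize_matrix <- function(m, decimals = 1,
                             polyploid_quantifier = c("any", "all")) {
  stopifnot(inherits(m, "fragment_matrix"))
  if (nrow(m$presence) == 0L) {
    stop("cannot summarize an empty fragment matrix", call. = FALSE)
  }
  polyploid_quantifier <- match.arg(polyploid_quantifier)
  cls <- apply(m$presence, 1L, function(row) {
    cl <- classify_fragment(row, m$roles, polyploid_quantifier)
    if (cl$major == "monomorphic") "monomorphic" else cl$subtype
  })
  total <- length(cls)
  counts <- c(
    monomorphic = sum(cls == "monomorphic"),
    novel = sum(cls == "novel"),
    maternal_origin = sum(cls == "maternal_origin"),
    paternal_origin = sum(cls == "paternal_origin"),
    other = sum(cls == "other")
  )
  counts <- c(counts,
              polymorphic = total - unname(counts["monomorphic"]))
  pct <- vapply(counts, percent, numeric(1L),
                denominator = total, decimals = decimals)
  frac <- counts / total
  out <- c(list(total = total), as.list(counts),
           stats::setNames(as.list(pct), paste0("pct_", names(counts))),
           stats::setNames(as.list(frac), paste0("frac_", names(counts))))
  structure(out, class = "aflp_summary")
}

#' @export
print.aflp_summary <- function(x, ...) {
  cat("cDNA-AFLP summary:", x$total, "fragments\n")
  for (cl in c("monomorphic", "polymorphic", "novel",
               "maternal_origin", "paternal_origin", "other")) {
    cat(sprintf("  %-16s %5d  (%s%%)\n", cl, x[[cl]],
                format(x[[paste0("pct_", cl)]])))
  }
  invisible(x)
}

#' Read an AFLP presence/absence matrix
#'
#' @param path TSV whose first three columns are `fragment_id`,
#'   `primer_pair`, `approx_size`, followed by one 0/1 column per
#'   individual.
#' @param individuals individuals data.frame; every matrix column must
#'   be present in it.
#' @return A `fragment_matrix`.
#' @export
read_fragment_matrix <- function(path, individuals) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  fixed <- c("fragment_id", "primer_pair", "approx_size")
  missing <- setdiff(fixed, names(df))
  if (length(missing)) {
    stop("fragment matrix ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cells <- as.matrix(df[, setdiff(names(df), fixed), drop = FALSE])
  bad <- which(!(cells %in% c(0, 1)) | is.na(cells), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-binary cell '", cells[bad[1L, , drop = FALSE]],
         "' at fragment '", df$fragment_id[bad[1L, 1L]], "', column '",
         colnames(cells)[bad[1L, 2L]], "'", call. = FALSE)
  }
  storage.mode(cells) <- "numeric"
  rownames(cells) <- df$fragment_id
  fragment_matrix(cells, individuals, df[, fixed])
}

#' Write an AFLP fragment matrix
#'
#' @param m a `fragment_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fragment_matrix <- function(m, path) {
  df <- cbind(m$fragments,
              as.data.frame(m$presence * 1L, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
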