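# FASTA and tabular readers for sequences, individuals and parental
# allele pairs.

SEQUENCE_ROLES <- c("maternal_parent", "paternal_parent", "polyploid",
                    "f1_hybrid")

# Parse "key=value" tokens from a FASTA description string. Unknown
# tokens are ignored; missing keys yield NA.
parse_description_tokens <- function(desc) {
  out <- c(role = NA_character_, species = NA_character_,
           locus = NA_character_)
  if (is.na(desc) || !nzchar(desc)) return(out)
  tokens <- strsplit(trimws(desc), "[[:space:]]+")[[1L]]
  kv <- regmatches(tokens, regexec("^([A-Za-z_]+)=(.+)$", tokens))
  for (m in kv) {
    if (length(m) == 3L && m[2L] %in% names(out)) out[m[2L]] <- m[3L]
  }
  out
}

#' Read a FASTA file of annotated DNA sequences
#'
#' Record descriptions may carry `role=`, `species=` and `locus=`
#' tokens (e.g. `>L1_m role=maternal_parent species=T.porrifolius
#' locus=L1`); unknown tokens are ignored. Residues are validated
#' against the 15-letter IUPAC DNA alphabet and uppercased.
#'
#' @param path path to a FASTA file.
#' @return A data.frame with columns `seq_id`, `residues`, `role`,
#'   `species_label`, `locus_id`, one row per record, order preserved.
#'   An empty file yields a zero-row frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  n <- length(set)
  out <- data.frame(
    seq_id = character(n), residues = character(n),
    role = character(n), species_label = character(n),
    locus_id = character(n), stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)
  headers <- names(set)
  for (i in seq_len(n)) {
    parts <- regmatches(headers[i],
                        regexec("^(\\S+)\\s*(.*)$", headers[i]))[[1L]]
    seq_id <- parts[2L]
    tok <- parse_description_tokens(parts[3L])
    out$seq_id[i] <- seq_id
    out$residues[i] <- validate_iupac(as.character(set[[i]]),
                                      paste0("record '", seq_id, "'"))
    out$role[i] <- tok[["role"]]
    out$species_label[i] <- tok[["species"]]
    out$locus_id[i] <- tok[["locus"]]
  }
  if (anyDuplicated(out$seq_id)) {
    dup <- out$seq_id[duplicated(out$seq_id)][1L]
    stop("duplicate seq_id '", dup, "' in ", path, call. = FALSE)
  }
  bad_role <- !is.na(out$role) & !out$role %in% SEQUENCE_ROLES
  if (any(bad_role)) {
    stop("unknown role '", out$role[bad_role][1L], "' for record '",
         out$seq_id[bad_role][1L], "'", call. = FALSE)
  }
  out
}

#' Write annotated sequences to FASTA
#'
#' Inverse of [read_fasta()]: role, species and locus metadata are
#' serialized as `key=value` description tokens.
#'
#' @param seqs data.frame as returned by [read_fasta()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  desc <- vapply(seq_len(nrow(seqs)), function(i) {
    tok <- character(0)
    if (!is.na(seqs$role[i])) tok <- c(tok, paste0("role=", seqs$role[i]))
    if (!is.na(seqs$species_label[i])) {
      tok <- c(tok, paste0("species=", seqs$species_label[i]))
    }
    if (!is.na(seqs$locus_id[i])) {
      tok <- c(tok, paste0("locus=", seqs$locus_id[i]))
    }
    if (length(tok)) paste(seqs$seq_id[i], paste(tok, collapse = " ")) else
      seqs$seq_id[i]
  }, character(1L))
  set <- Biostrings::BStringSet(seqs$residues)
  names(set) <- desc
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read an individuals table
#'
#' @param path TSV with columns `individual_id`, `population_id`,
#'   `role`, `species_label`.
#' @return Validated data.frame (unique individual ids, known roles,
#'   nonempty population ids).
#' @export
read_individuals <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  required <- c("individual_id", "population_id", "role", "species_label")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("individuals table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_individuals(df)
}

validate_individuals <- function(df) {
  if (anyDuplicated(df$individual_id)) {
    stop("duplicate individual_id '",
         df$individual_id[duplicated(df$individual_id)][1L], "'",
         call. = FALSE)
  }
  if (any(is.na(df$population_id) | !nzchar(df$population_id))) {
    stop("population_id must be nonempty for every individual",
         call. = FALSE)
  }
  bad <- !df$role %in% SEQUENCE_ROLES
  if (any(bad)) {
    stop("unknown role '", df$role[bad][1L], "' for individual '",
         df$individual_id[bad][1L], "'", call. = FALSE)
  }
  df
}

#' Pair maternal and paternal alleles per locus
#'
#' Groups an annotated sequence frame (from [read_fasta()]) by
#' `locus_id` and extracts the maternal/paternal allele pair for each
#' locus.
#'
#' @param seqs data.frame as returned by [read_fasta()]; every record
#'   needs a `locus_id` and a parental role.
#' @return data.frame with columns `locus_id`, `maternal`, `paternal`
#'   (residue strings), one row per locus, in first-appearance order.
#' @export
locus_alleles <- function(seqs) {
  if (any(is.na(seqs$locus_id))) {
    stop("every allele record needs a locus= token", call. = FALSE)
  }
  loci <- unique(seqs$locus_id)
  out <- data.frame(locus_id = loci, maternal = NA_character_,
                    paternal = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(loci)) {
    sub <- seqs[seqs$locus_id == loci[i], ]
    m <- sub$residues[sub$role == "maternal_parent"]
    p <- sub$residues[sub$role == "paternal_parent"]
    if (length(m) != 1L || length(p) != 1L) {
      stop("locus '", loci[i], "' needs exactly one maternal_parent and ",
           "one paternal_parent allele", call. = FALSE)
    }
    out$maternal[i] <- m
    out$paternal[i] <- p
  }
  out
}

# Serialize an allele table back to the annotated-FASTA convention.
alleles_to_fasta_df <- function(alleles,
                                maternal_species = "maternal",
                                paternal_species = "paternal") {
  n <- nrow(alleles)
  data.frame(
    seq_id = c(paste0(alleles$locus_id, "_mat"),
               paste0(alleles$locus_id, "_pat")),
    residues = c(alleles$maternal, alleles$paternal),
    role = rep(c("maternal_parent", "paternal_parent"), each = n),
    species_label = rep(c(maternal_species, paternal_species), each = n),
    locus_id = rep(alleles$locus_id, 2L),
    stringsAsFactors = FALSE
  )
}
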