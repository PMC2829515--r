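# Restriction-enzyme panel handling (REBASE-like minimal subset:
# name, IUPAC recognition site, top-strand cut offset).

validate_enzymes <- function(df) {
  required <- c("name", "site", "cut_offset")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("enzyme table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate enzyme name '", df$name[duplicated(df$name)][1L],
         "' in panel", call. = FALSE)
  }
  df$site <- vapply(seq_len(nrow(df)),
                    function(i) validate_iupac(df$site[i],
                                               paste0("site of ", df$name[i])),
                    character(1L))
  len <- nchar(df$site)
  if (any(len < 4L | len > 8L)) {
    bad <- df$name[len < 4L | len > 8L][1L]
    stop("recognition site of '", bad, "' must be 4-8 bp", call. = FALSE)
  }
  df$cut_offset <- as.integer(df$cut_offset)
  if (any(is.na(df$cut_offset) | df$cut_offset < 0L | df$cut_offset > len)) {
    stop("cut_offset must lie in [0, site length] for every enzyme",
         call. = FALSE)
  }
  df[, required]
}

#' Read a restriction-enzyme panel
#'
#' @param path TSV with columns `name`, `site` (IUPAC recognition
#'   sequence, 4-8 bp) and `cut_offset` (bp from the 5' start of the
#'   site on the top strand).
#' @return Validated enzyme data.frame.
#' @export
read_enzymes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  validate_enzymes(df)
}

#' Bundled default enzyme panel
#'
#' Common 4- and 6-cutters (plus two degenerate-site enzymes) with
#' their top-strand cut offsets, as used for CAPS assay design when no
#' custom panel is supplied.
#'
#' @return Enzyme data.frame with columns `name`, `site`, `cut_offset`.
#' @export
default_enzyme_panel <- function() {
  path <- system.file("extdata", "default_enzymes.tsv",
                      package = "homeoCAPS", mustWork = TRUE)
  read_enzymes(path)
}
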