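# In-silico restriction digestion and the agarose gel model.
#
# Coordinates: cut positions are between-base indices, i.e. the number
# of bases 5' of the scissile bond, in [1, length-1]. Cuts at 0 or at
# the full length would create zero-length (gel-invisible) fragments
# and are discarded.

# logical vector over window start positions (1-based) where the
# concrete sequence matches the (possibly degenerate) pattern.
match_windows <- function(seq_chars, pattern_chars) {
  n <- length(seq_chars)
  k <- length(pattern_chars)
  if (n < k) return(logical(0L))
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    allowed <- iupac_set(pattern_chars[j])
    ok <- ok & seq_chars[seq.int(j, j + n - k)] %in% allowed
  }
  ok
}

#' Locate restriction-enzyme cut sites on a linear sequence
#'
#' Scans a concrete substrate for occurrences of an (IUPAC-degenerate)
#' recognition site. With `both_strands = TRUE` (the default; real
#' enzymes cut duplex DNA) windows whose reverse complement matches the
#' site are also recognized; each recognition window yields a single
#' duplex cut at `window_start + cut_offset` in top-strand coordinates,
#' so palindromic sites deduplicate naturally.
#'
#' @param seq concrete DNA string (degenerate substrate bases are
#'   rejected).
#' @param site IUPAC recognition sequence.
#' @param cut_offset bp from the 5' start of the site to the cut.
#' @param both_strands scan both strands (default `TRUE`).
#' @return Sorted integer vector of distinct between-base cut positions
#'   in `[1, nchar(seq) - 1]`; empty when there is no site.
#' @export
find_cut_sites <- function(seq, site, cut_offset, both_strands = TRUE) {
  seq <- assert_concrete(seq, "digestion substrate")
  site <- validate_iupac(site, "recognition site")
  n <- nchar(seq)
  k <- nchar(site)
  if (k > n) return(integer(0L))
  sv <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pv <- strsplit(site, "", fixed = TRUE)[[1L]]
  hits <- match_windows(sv, pv)
  if (both_strands) {
    rc <- strsplit(reverse_complement(site), "", fixed = TRUE)[[1L]]
    if (!identical(rc, pv)) hits <- hits | match_windows(sv, rc)
  }
  starts <- which(hits)                    # 1-based window starts
  cuts <- sort(unique(starts - 1L + as.integer(cut_offset)))
  cuts[cuts >= 1L & cuts <= n - 1L]
}

#' Digest a sequence and return fragment lengths
#'
#' Complete digestion of a linear substrate: fragments are the lengths
#' of the maximal uncut intervals, so they always sum to the sequence
#' length and number one more than the cuts.
#'
#' @inheritParams find_cut_sites
#' @return Integer vector of fragment lengths (unsorted multiset).
#' @export
digest_sequence <- function(seq, site, cut_offset, both_strands = TRUE) {
  cuts <- find_cut_sites(seq, site, cut_offset, both_strands)
  diff(c(0L, cuts, nchar(seq)))
}

#' Gel resolution configuration
#'
#' @param min_detectable_bp fragments shorter than this run off the
#'   gel and are invisible (default 50 bp).
#' @param comigration_rel_tol relative size tolerance under which two
#'   bands co-migrate and are indistinguishable (default 0.05, i.e.
#'   5 percent of the larger band).
#' @return List of class `gel_config`.
#' @export
gel_config <- function(min_detectable_bp = 50, comigration_rel_tol = 0.05) {
  if (min_detectable_bp < 1) {
    stop("min_detectable_bp must be >= 1", call. = FALSE)
  }
  if (comigration_rel_tol < 0 || comigration_rel_tol >= 1) {
    stop("comigration_rel_tol must lie in [0, 1)", call. = FALSE)
  }
  structure(list(min_detectable_bp = min_detectable_bp,
                 comigration_rel_tol = comigration_rel_tol),
            class = "gel_config")
}

# co-migration comparator: two bands are indistinguishable iff their
# size difference is within tol of the larger band.
bands_comigrate <- function(a, b, tol) {
  abs(a - b) <= tol * pmax(a, b)
}

# is band b represented in set (under the comparator)?
band_in_set <- function(b, set, tol) {
  length(set) > 0L && any(bands_comigrate(b, set, tol))
}

# bands of a absent from b under the comparator
band_setdiff <- function(a, b, tol) {
  a[!vapply(a, band_in_set, logical(1L), set = b, tol = tol)]
}

# band-set equality under the comparator (mutual containment and
# equal cardinality)
band_sets_equal <- function(a, b, tol) {
  length(a) == length(b) &&
    all(vapply(a, band_in_set, logical(1L), set = b, tol = tol)) &&
    all(vapply(b, band_in_set, logical(1L), set = a, tol = tol))
}

#' Convert digestion fragments to observable gel bands
#'
#' Fragments below the detection limit are dropped; the remainder are
#' clustered greedily from the largest down, merging any length within
#' the co-migration tolerance of the current cluster's largest member.
#' Each cluster is represented by its largest length.
#'
#' @param fragments numeric vector of fragment lengths (bp).
#' @param gel a [gel_config()].
#' @return Descending-sorted numeric vector of representative band
#'   lengths; may be empty if everything ran off the gel.
#' @export
to_band_set <- function(fragments, gel = gel_config()) {
  x <- fragments[fragments >= gel$min_detectable_bp]
  x <- sort(x, decreasing = TRUE)
  reps <- numeric(0L)
  for (l in x) {
    if (length(reps) &&
        bands_comigrate(reps[length(reps)], l, gel$comigration_rel_tol)) {
      next  # merges into the current cluster
    }
    reps <- c(reps, l)
  }
  reps
}

# merged union of two band sets under the gel model
band_union <- function(a, b, gel) {
  to_band_set(c(a, b), gel)
}
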