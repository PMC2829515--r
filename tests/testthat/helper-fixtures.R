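# Shared helpers: hand-built assays, random sequences and tiny panels.

# an assay object with prescribed band sets (no digestion involved)
make_test_assay <- function(maternal_bands = c(120, 80),
                            paternal_bands = 200,
                            gel = gel_config(),
                            locus_id = "Ltest", enzyme = "EcoRI") {
  homeoCAPS:::new_caps_assay(locus_id, enzyme, "GAATTC", 1L,
                             maternal_bands, paternal_bands, gel)
}

random_concrete_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}

random_iupac_seq <- function(len) {
  paste(sample(homeoCAPS:::IUPAC_LETTERS, len, replace = TRUE),
        collapse = "")
}

# independent site-scan oracle built on Biostrings::matchPattern
# (degenerate pattern, concrete subject)
oracle_cut_sites <- function(seq, site, cut_offset, both_strands = TRUE) {
  subject <- Biostrings::DNAString(seq)
  starts <- Biostrings::start(
    Biostrings::matchPattern(site, subject, fixed = "subject"))
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(site)))
    if (rc != site) {
      starts <- union(starts, Biostrings::start(
        Biostrings::matchPattern(rc, subject, fixed = "subject")))
    }
  }
  cuts <- sort(unique(starts - 1L + cut_offset))
  cuts[cuts >= 1L & cuts <= nchar(seq) - 1L]
}

# the spec-style constructed locus: 200 bp, maternal EcoRI site
# destroyed in the paternal allele (maternal digest {120, 80},
# paternal {200})
constructed_locus_200 <- function() {
  bg <- strrep("A", 200)
  splice <- function(s, repl, pos) {
    paste0(substr(s, 1, pos), repl, substr(s, pos + 7, 200))
  }
  list(maternal = splice(bg, "GAATTC", 79),  # cut at 80 -> {80, 120}
       paternal = splice(bg, "AAATTC", 79))
}

minimal_individuals <- function(n_poly = 2, n_mat = 2, n_pat = 2) {
  data.frame(
    individual_id = c(sprintf("TM-%02d", seq_len(n_poly)),
                      sprintf("TPO-%02d", seq_len(n_mat)),
                      sprintf("TDU-%02d", seq_len(n_pat))),
    population_id = "TestPop",
    role = rep(c("polyploid", "maternal_parent", "paternal_parent"),
               c(n_poly, n_mat, n_pat)),
    species_label = rep(c("poly", "mat", "pat"),
                        c(n_poly, n_mat, n_pat)),
    stringsAsFactors = FALSE)
}
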