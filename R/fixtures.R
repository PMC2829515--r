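# Deterministic fixture builders: datasets constructed so that the
# real classification pipeline reproduces requested tallies exactly.
# Used to validate the pipeline against published integer tallies and
# percentages over stated denominators.

#' Build an AFLP fragment matrix with prescribed class counts
#'
#' Constructs a presence/absence matrix whose rows classify (via
#' [classify_fragment()]) into exactly the requested counts. Rows not
#' covered by a named class are polymorphic "other" fragments (present
#' in the maternal parent only).
#'
#' @param total total fragment count.
#' @param monomorphic,novel,maternal_origin,paternal_origin requested
#'   class counts; their sum must not exceed `total`.
#' @param n_polyploid,n_maternal,n_paternal individuals per role.
#' @return A `fragment_matrix`.
#' @export
aflp_fixture_from_counts <- function(total, monomorphic, novel = 0L,
                                     maternal_origin = 0L,
                                     paternal_origin = 0L,
                                     n_polyploid = 4L, n_maternal = 3L,
                                     n_paternal = 3L) {
  counts <- c(monomorphic = monomorphic, novel = novel,
              maternal_origin = maternal_origin,
              paternal_origin = paternal_origin)
  if (any(counts < 0) || total < 0) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  if (sum(counts) > total) {
    stop("inconsistent fixture spec: ",
         paste(names(counts), counts, sep = "=", collapse = " + "),
         " = ", sum(counts), " exceeds total = ", total, call. = FALSE)
  }
  other <- total - sum(counts)
  individuals <- data.frame(
    individual_id = c(sprintf("TM-%02d", seq_len(n_polyploid)),
                      sprintf("TPO-%02d", seq_len(n_maternal)),
                      sprintf("TDU-%02d", seq_len(n_paternal))),
    population_id = "Fixture",
    role = rep(c("polyploid", "maternal_parent", "paternal_parent"),
               c(n_polyploid, n_maternal, n_paternal)),
    species_label = rep(c("polyploid", "maternal", "paternal"),
                        c(n_polyploid, n_maternal, n_paternal)),
    stringsAsFactors = FALSE)
  roles <- individuals$role
  n_ind <- nrow(individuals)
  pattern <- function(cl) {
    row <- logical(n_ind)
    switch(cl,
      monomorphic = { row[] <- TRUE },
      novel = { row[roles == "polyploid"] <- TRUE },
      maternal_origin = {
        row[roles %in% c("polyploid", "maternal_parent")] <- TRUE },
      paternal_origin = {
        row[roles %in% c("polyploid", "paternal_parent")] <- TRUE },
      other = { row[roles == "maternal_parent"] <- TRUE }
    )
    row
  }
  cls <- rep(c(names(counts), "other"), c(counts, other))
  presence <- t(vapply(cls, pattern, logical(n_ind)))
  rownames(presence) <- sprintf("frag%05d", seq_len(total))
  colnames(presence) <- individuals$individual_id
  fragment_matrix(presence, individuals)
}

# an allele pair whose maternal copy carries an intact EcoRI site and
# whose paternal copy carries the site-destroying substitution; the
# all-A background guarantees no other site of any default-panel
# enzyme on either strand
fixture_allele_pair <- function(length = 400L, cut_at = 160L) {
  site <- "GAATTC"
  bg <- strrep("A", length)
  pos <- cut_at  # site starts at cut_at (0-based), cut_offset 1
  splice <- function(s, repl) {
    paste0(substr(s, 1L, pos), repl, substr(s, pos + 7L, length))
  }
  list(maternal = splice(bg, site), paternal = splice(bg, "AAATTC"))
}

#' Build a deterministic CAPS study with prescribed loss tallies
#'
#' Constructs a full noise-free study (alleles, assays, individuals,
#' genomic + cDNA observations) whose classification by
#' [genotype_study()], [expression_study()] and the tally functions
#' reproduces the requested gene-level counts exactly:
#' `paternal_loss_genes` genes with a paternal-homeolog loss,
#' `maternal_loss_genes` with a maternal loss,
#' `both_parent_loss_genes` counted in both (losses of either copy in
#' different individuals), `excluded_genes` loci polymorphic within the
#' paternal parent species, and `silenced_genes` additive genes whose
#' paternal homeolog is silenced in one individual. cDNA observations
#' cover `cdna_genes` informative additive genes (including the
#' silenced ones).
#'
#' @param n_genes total loci surveyed (default 30).
#' @param paternal_loss_genes,maternal_loss_genes gene-level per-parent
#'   loss counts (defaults 7 and 4).
#' @param both_parent_loss_genes genes counted in both per-parent
#'   tallies (default 2).
#' @param excluded_genes loci excluded for within-parent polymorphism
#'   (default 1).
#' @param silenced_genes additive genes with a silenced paternal
#'   homeolog (default 2).
#' @param cdna_genes genes assayed at the cDNA tier (default 15).
#' @param n_polyploid,n_maternal,n_paternal cohort sizes (defaults 40,
#'   20, 40).
#' @return List with `alleles`, `assays`, `individuals`,
#'   `observations`, plus the requested design in `design`.
#' @export
caps_fixture_from_counts <- function(n_genes = 30L,
                                     paternal_loss_genes = 7L,
                                     maternal_loss_genes = 4L,
                                     both_parent_loss_genes = 2L,
                                     excluded_genes = 1L,
                                     silenced_genes = 2L,
                                     cdna_genes = 15L,
                                     n_polyploid = 40L,
                                     n_maternal = 20L,
                                     n_paternal = 40L) {
  loss_genes <- paternal_loss_genes + maternal_loss_genes -
    both_parent_loss_genes
  checks <- c(
    "both_parent_loss_genes <= min(per-parent counts)" =
      both_parent_loss_genes <= min(paternal_loss_genes,
                                    maternal_loss_genes),
    "loss + excluded genes <= n_genes" =
      loss_genes + excluded_genes <= n_genes,
    "silenced + loss + excluded genes <= n_genes" =
      silenced_genes + loss_genes + excluded_genes <= n_genes,
    "cdna_genes fits among non-excluded, non-loss genes" =
      cdna_genes <= n_genes - loss_genes - excluded_genes,
    "silenced_genes <= cdna_genes" = silenced_genes <= cdna_genes,
    "cohorts nonempty" = min(n_polyploid, n_maternal, n_paternal) >= 1L
  )
  if (!all(checks)) {
    stop("inconsistent fixture spec: violated constraint '",
         names(checks)[!checks][1L], "'", call. = FALSE)
  }

  loci <- sprintf("L%03d", seq_len(n_genes))
  pair <- fixture_allele_pair()
  alleles <- data.frame(locus_id = loci,
                        maternal = pair$maternal,
                        paternal = pair$paternal,
                        stringsAsFactors = FALSE)
  gel <- gel_config()
  assays <- design_best_assays(alleles, default_enzyme_panel(), gel)

  individuals <- data.frame(
    individual_id = c(sprintf("TM-%02d", seq_len(n_polyploid)),
                      sprintf("TPO-%02d", seq_len(n_maternal)),
                      sprintf("TDU-%02d", seq_len(n_paternal))),
    population_id = "Fixture",
    role = rep(c("polyploid", "maternal_parent", "paternal_parent"),
               c(n_polyploid, n_maternal, n_paternal)),
    species_label = rep(c("T. mirus", "T. porrifolius", "T. dubius"),
                        c(n_polyploid, n_maternal, n_paternal)),
    stringsAsFactors = FALSE)

  # gene roles by position: losses first, excluded last, cDNA genes in
  # the additive middle
  pat_only <- paternal_loss_genes - both_parent_loss_genes
  mat_only <- maternal_loss_genes - both_parent_loss_genes
  paternal_loss_loci <- loci[seq_len(paternal_loss_genes)]
  maternal_loss_loci <- loci[seq.int(pat_only + 1L,
                                     pat_only + maternal_loss_genes)]
  excluded_loci <- if (excluded_genes > 0L)
    loci[seq.int(n_genes - excluded_genes + 1L, n_genes)] else character(0L)
  additive_loci <- setdiff(loci, c(paternal_loss_loci, maternal_loss_loci,
                                   excluded_loci))
  cdna_loci <- additive_loci[seq_len(cdna_genes)]
  silenced_loci <- cdna_loci[seq_len(silenced_genes)]

  tm1 <- individuals$individual_id[individuals$role == "polyploid"][1L]
  tm2 <- individuals$individual_id[individuals$role == "polyploid"][2L]
  tdu <- individuals$individual_id[individuals$role == "paternal_parent"]
  extra_copy_ids <- tdu[seq_len(min(2L, length(tdu)))]

  n_ind <- nrow(individuals)
  n_rows <- n_genes * n_ind + cdna_genes * n_ind
  o_ind <- character(n_rows); o_loc <- character(n_rows)
  o_tier <- character(n_rows); o_bands <- character(n_rows)
  row <- 0L
  emit <- function(ind, lc, tier, bands) {
    row <<- row + 1L
    o_ind[row] <<- ind; o_loc[row] <<- lc
    o_tier[row] <<- tier; o_bands[row] <<- format_bands(bands)
  }
  for (lc in loci) {
    a <- assays[[lc]]
    additive <- band_union(a$maternal_bands, a$paternal_bands, gel)
    for (j in seq_len(nrow(individuals))) {
      ind <- individuals$individual_id[j]
      role <- individuals$role[j]
      if (role == "maternal_parent") {
        g <- a$maternal_bands
      } else if (role == "paternal_parent") {
        g <- if (lc %in% excluded_loci && ind %in% extra_copy_ids)
          additive else a$paternal_bands
      } else {
        g <- additive
        if (lc %in% paternal_loss_loci && ind == tm1) g <- a$maternal_bands
        if (lc %in% maternal_loss_loci && ind == tm2) g <- a$paternal_bands
      }
      emit(ind, lc, "genomic", g)
      if (lc %in% cdna_loci) {
        cb <- if (role == "maternal_parent") {
          a$maternal_bands
        } else if (role == "paternal_parent") {
          a$paternal_bands
        } else if (lc %in% silenced_loci && ind == tm1) {
          a$maternal_bands  # paternal homeolog silenced
        } else {
          additive
        }
        emit(ind, lc, "cdna", cb)
      }
    }
  }
  observations <- data.frame(
    individual_id = o_ind[seq_len(row)], locus_id = o_loc[seq_len(row)],
    tier = o_tier[seq_len(row)], bands = o_bands[seq_len(row)],
    stringsAsFactors = FALSE)
  list(alleles = alleles, assays = assays, individuals = individuals,
       observations = observations,
       design = list(loci = loci,
                     paternal_loss_loci = paternal_loss_loci,
                     maternal_loss_loci = maternal_loss_loci,
                     excluded_loci = excluded_loci,
                     cdna_loci = cdna_loci,
                     silenced_loci = silenced_loci))
}
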