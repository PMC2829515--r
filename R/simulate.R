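# Synthetic allopolyploid study generator with known ground truth.
#
# The generator emulates the sampling design of a natural-population
# homeolog survey: two diverged parental haplotypes per locus, a
# polyploid cohort with parent-biased homeolog loss and conditional
# silencing, diploid parent cohorts (optionally polymorphic at some
# loci), F1 hybrids with zero loss and silencing, and noisy gel
# observations (band dropout + multiplicative size jitter).

POPULATION_NAMES <- c("Pullman-1", "Pullman-2", "Palouse", "Oakesdale",
                      "Rosalia", "Tekoa", "Arizona")

# per-component deterministic substreams derived from one root seed,
# so that e.g. changing the noise setting does not perturb the
# genotype truth. Offsets keep seeds well under 2^31.
substream_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000000L) * 10L + stage
}

#' Simulation configuration
#'
#' Defaults mirror a 30-gene, seven-population survey of a young
#' allotetraploid: 40 polyploids, 40 paternal-parent and 20
#' maternal-parent diploids, loci ~400 bp with 2 percent parental
#' divergence, gene-level loss biased toward the paternal homeolog,
#' rare conditional silencing and occasional within-parent
#' polymorphism. Noise is off by default.
#'
#' @param seed root integer seed; identical config + seed gives a
#'   byte-identical dataset.
#' @param n_loci number of loci (default 30).
#' @param locus_length amplicon length in bp (default 400).
#' @param divergence per-site substitution probability between the
#'   parental alleles (default 0.02).
#' @param n_polyploid,n_maternal,n_paternal,n_f1 cohort sizes per role
#'   (defaults 40, 20, 40, 0).
#' @param n_populations number of polyploid populations of independent
#'   origin (default 7).
#' @param loss_prob_paternal,loss_prob_maternal per-individual,
#'   per-locus homeolog loss probabilities (defaults 0.02 and 0.01:
#'   paternal-biased).
#' @param silencing_prob probability that a retained homeolog is
#'   silenced (default 0.01).
#' @param parental_polymorphism_prob per-locus probability that the
#'   paternal parent species is polymorphic (default 0.03).
#' @param band_dropout_prob per-band dropout probability (default 0).
#' @param size_jitter_rel multiplicative band-size jitter half-width
#'   (default 0).
#' @param panel enzyme panel (default [default_enzyme_panel()]).
#' @param gel a [gel_config()].
#' @param ensure_informative plant a diagnostic restriction site per
#'   locus (default `TRUE`), emulating the marker-selection step of a
#'   CAPS study, where loci are chosen because a diagnostic site
#'   exists.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_loci = 30L, locus_length = 400L,
                       divergence = 0.02,
                       n_polyploid = 40L, n_maternal = 20L,
                       n_paternal = 40L, n_f1 = 0L,
                       n_populations = 7L,
                       loss_prob_paternal = 0.02,
                       loss_prob_maternal = 0.01,
                       silencing_prob = 0.01,
                       parental_polymorphism_prob = 0.03,
                       band_dropout_prob = 0,
                       size_jitter_rel = 0,
                       panel = default_enzyme_panel(),
                       gel = gel_config(),
                       ensure_informative = TRUE) {
  probs <- c(divergence = divergence,
             loss_prob_paternal = loss_prob_paternal,
             loss_prob_maternal = loss_prob_maternal,
             silencing_prob = silencing_prob,
             parental_polymorphism_prob = parental_polymorphism_prob,
             band_dropout_prob = band_dropout_prob,
             size_jitter_rel = size_jitter_rel)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probability out of [0,1]: ", names(probs)[bad][1L], " = ",
         probs[bad][1L], call. = FALSE)
  }
  if (n_loci < 0L || locus_length < 20L && n_loci > 0L) {
    stop("need n_loci >= 0 and locus_length >= 20", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), n_loci = as.integer(n_loci),
    locus_length = as.integer(locus_length), divergence = divergence,
    n_polyploid = as.integer(n_polyploid),
    n_maternal = as.integer(n_maternal),
    n_paternal = as.integer(n_paternal), n_f1 = as.integer(n_f1),
    n_populations = as.integer(n_populations),
    loss_prob_paternal = loss_prob_paternal,
    loss_prob_maternal = loss_prob_maternal,
    silencing_prob = silencing_prob,
    parental_polymorphism_prob = parental_polymorphism_prob,
    band_dropout_prob = band_dropout_prob,
    size_jitter_rel = size_jitter_rel,
    panel = panel, gel = gel,
    ensure_informative = ensure_informative
  ), class = "sim_config")
}

# concrete instantiation of a (possibly degenerate) site
concretize_site <- function(site) {
  chars <- strsplit(site, "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(ch) {
    s <- iupac_set(ch)
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1L)), collapse = "")
}

# mutate one position of a concrete site occurrence so the pattern no
# longer matches there (skips N positions, where any base matches)
destroy_site <- function(occurrence, site) {
  oc <- strsplit(occurrence, "", fixed = TRUE)[[1L]]
  pc <- strsplit(site, "", fixed = TRUE)[[1L]]
  cand <- which(vapply(pc, function(ch) length(iupac_set(ch)) < 4L,
                       logical(1L)))
  j <- if (length(cand) == 1L) cand else sample(cand, 1L)
  alt <- setdiff(CONCRETE_BASES, iupac_set(pc[j]))
  oc[j] <- if (length(alt) == 1L) alt else sample(alt, 1L)
  paste(oc, collapse = "")
}

#' Simulate diverged parental allele pairs
#'
#' The maternal allele is drawn uniformly over A/C/G/T; the paternal
#' allele applies an independent per-site substitution at the
#' configured divergence (uniform among the three alternative bases),
#' so both alleles share one coordinate frame. With
#' `ensure_informative`, one enzyme site from the panel is planted
#' intact in one parent and destroyed by a single substitution in the
#' other (alternating direction across loci).
#'
#' @param cfg a [sim_config()].
#' @return data.frame with `locus_id`, `maternal`, `paternal`.
#' @export
simulate_parental_alleles <- function(cfg) {
  set.seed(substream_seed(cfg$seed, 1L))
  n <- cfg$n_loci
  L <- cfg$locus_length
  out <- data.frame(locus_id = sprintf("L%03d", seq_len(n)),
                    maternal = character(n), paternal = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    mat <- sample(CONCRETE_BASES, L, replace = TRUE)
    pat <- mat
    sub <- which(stats::runif(L) < cfg$divergence)
    for (s in sub) {
      pat[s] <- sample(setdiff(CONCRETE_BASES, mat[s]), 1L)
    }
    mat <- paste(mat, collapse = "")
    pat <- paste(pat, collapse = "")
    if (cfg$ensure_informative) {
      e <- cfg$panel[sample(nrow(cfg$panel), 1L), ]
      k <- nchar(e$site)
      # cut must leave both fragments comfortably on the gel
      lo <- max(1L, ceiling(0.3 * L))
      hi <- min(L - k, floor(0.7 * L))
      pos <- if (lo >= hi) lo else sample(lo:hi, 1L)
      occ <- concretize_site(e$site)
      broken <- destroy_site(occ, e$site)
      splice <- function(s, repl) {
        paste0(substr(s, 1L, pos - 1L), repl, substr(s, pos + k, L))
      }
      if (i %% 2L == 1L) {  # alternate which parent carries the site
        mat <- splice(mat, occ); pat <- splice(pat, broken)
      } else {
        mat <- splice(mat, broken); pat <- splice(pat, occ)
      }
    }
    out$maternal[i] <- mat
    out$paternal[i] <- pat
  }
  out
}

# gel noise: independent band dropout, then multiplicative size
# jitter, then re-merging under the gel model
apply_gel_noise <- function(bands, dropout, jitter, gel) {
  if (length(bands) == 0L) return(bands)
  keep <- stats::runif(length(bands)) >= dropout
  bands <- bands[keep]
  if (length(bands) && jitter > 0) {
    bands <- bands * stats::runif(length(bands), 1 - jitter, 1 + jitter)
  }
  to_band_set(bands, gel)
}

build_individuals <- function(cfg) {
  pops <- POPULATION_NAMES[((seq_len(cfg$n_populations) - 1L) %%
                              length(POPULATION_NAMES)) + 1L]
  rows <- list()
  add <- function(prefix, n, role, species) {
    if (n == 0L) return()
    pop <- pops[((seq_len(n) - 1L) %% length(pops)) + 1L]
    rows[[length(rows) + 1L]] <<- data.frame(
      individual_id = sprintf("%s-%02d", prefix, seq_len(n)),
      population_id = pop, role = role, species_label = species,
      stringsAsFactors = FALSE)
  }
  add("TM", cfg$n_polyploid, "polyploid", "T. mirus")
  add("TPO", cfg$n_maternal, "maternal_parent", "T. porrifolius")
  add("TDU", cfg$n_paternal, "paternal_parent", "T. dubius")
  add("F1", cfg$n_f1, "f1_hybrid", "T. dubius x T. porrifolius")
  do.call(rbind, rows)
}

#' Simulate a complete ground-truthed cohort study
#'
#' Draws per-individual, per-locus homeolog losses (never both: when
#' both parents' draws fire, the later maternal draw is suppressed and
#' logged), conditional silencing of retained homeologs, optional
#' within-parent polymorphism in the paternal parent species, and gel
#' observations at both tiers derived from the truth through the noise
#' model. F1 hybrids have loss and silencing probabilities forced to
#' zero. Loci with no informative assay are carried in the assay table
#' but emit no observations.
#'
#' @param cfg a [sim_config()].
#' @param alleles optional allele table (defaults to
#'   [simulate_parental_alleles()] under the same config).
#' @return Object of class `caps_sim`: `config`, `alleles`, `assays`
#'   (named list, one best assay per locus), `individuals`, `truth`,
#'   `observations` (genomic + cdna rows), `polymorphic_loci`,
#'   `suppressed_events`.
#' @export
simulate_cohort <- function(cfg, alleles = NULL) {
  if (is.null(alleles)) alleles <- simulate_parental_alleles(cfg)
  assays <- design_best_assays(alleles, cfg$panel, cfg$gel)
  informative <- vapply(assays, `[[`, logical(1L), "informative")
  individuals <- build_individuals(cfg)
  loci <- alleles$locus_id

  callers <- individuals[individuals$role %in% c("polyploid", "f1_hybrid"), ]

  # --- truth: losses -------------------------------------------------
  set.seed(substream_seed(cfg$seed, 2L))
  truth <- expand.grid(individual_id = callers$individual_id,
                       locus_id = loci, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  truth <- truth[order(match(truth$individual_id, callers$individual_id),
                       match(truth$locus_id, loci)), ]
  rownames(truth) <- NULL
  is_f1 <- individuals$role[match(truth$individual_id,
                                  individuals$individual_id)] == "f1_hybrid"
  lp_p <- ifelse(is_f1, 0, cfg$loss_prob_paternal)
  lp_m <- ifelse(is_f1, 0, cfg$loss_prob_maternal)
  pat_loss <- stats::runif(nrow(truth)) < lp_p
  mat_loss <- stats::runif(nrow(truth)) < lp_m
  suppressed <- pat_loss & mat_loss
  mat_loss[suppressed] <- FALSE  # never both; later draw suppressed
  truth$state <- ifelse(pat_loss, "maternal_only",
                        ifelse(mat_loss, "paternal_only", "additive"))

  # --- truth: silencing (retained homeologs only) --------------------
  set.seed(substream_seed(cfg$seed, 3L))
  sp <- ifelse(is_f1, 0, cfg$silencing_prob)
  truth$silenced_maternal <- truth$state != "paternal_only" &
    stats::runif(nrow(truth)) < sp
  truth$silenced_paternal <- truth$state != "maternal_only" &
    stats::runif(nrow(truth)) < sp

  # --- within-parent polymorphism (paternal parent species) ----------
  set.seed(substream_seed(cfg$seed, 4L))
  polymorphic <- stats::runif(length(loci)) <
    cfg$parental_polymorphism_prob
  names(polymorphic) <- loci
  pat_ids <- individuals$individual_id[individuals$role == "paternal_parent"]
  extra_copy <- list()  # per polymorphic locus: which paternal parents
  for (lc in loci[polymorphic]) {
    if (length(pat_ids) == 0L) { polymorphic[lc] <- FALSE; next }
    k <- max(1L, floor(length(pat_ids) / 4L))
    extra_copy[[lc]] <- sample(pat_ids, k)
  }

  # --- observations ---------------------------------------------------
  set.seed(substream_seed(cfg$seed, 5L))
  truth_key <- paste(truth$individual_id, truth$locus_id)
  state_of <- stats::setNames(truth$state, truth_key)
  sil_m <- stats::setNames(truth$silenced_maternal, truth_key)
  sil_p <- stats::setNames(truth$silenced_paternal, truth_key)

  n_rows <- 2L * sum(informative) * nrow(individuals)
  o_ind <- character(n_rows); o_loc <- character(n_rows)
  o_tier <- character(n_rows); o_bands <- character(n_rows)
  row <- 0L
  emit <- function(ind, lc, tier, bands) {
    row <<- row + 1L
    o_ind[row] <<- ind; o_loc[row] <<- lc
    o_tier[row] <<- tier; o_bands[row] <<- format_bands(bands)
  }
  for (lc in loci) {
    if (!informative[lc]) next
    a <- assays[[lc]]
    for (j in seq_len(nrow(individuals))) {
      ind <- individuals$individual_id[j]
      role <- individuals$role[j]
      key <- paste(ind, lc)
      if (role == "maternal_parent") {
        g_bands <- a$maternal_bands
        c_bands <- a$maternal_bands
      } else if (role == "paternal_parent") {
        has_extra <- polymorphic[lc] && ind %in% extra_copy[[lc]]
        g_bands <- if (has_extra)
          band_union(a$paternal_bands, a$maternal_bands, cfg$gel)
        else a$paternal_bands
        c_bands <- g_bands
      } else {
        st <- state_of[[key]]
        g_bands <- predict_polyploid_bands(a, st)
        expr_m <- st != "paternal_only" && !sil_m[[key]]
        expr_p <- st != "maternal_only" && !sil_p[[key]]
        c_bands <- numeric(0L)
        if (expr_m && expr_p) {
          c_bands <- band_union(a$maternal_bands, a$paternal_bands, cfg$gel)
        } else if (expr_m) {
          c_bands <- a$maternal_bands
        } else if (expr_p) {
          c_bands <- a$paternal_bands
        }
      }
      emit(ind, lc, "genomic",
           apply_gel_noise(g_bands, cfg$band_dropout_prob,
                           cfg$size_jitter_rel, cfg$gel))
      emit(ind, lc, "cdna",
           apply_gel_noise(c_bands, cfg$band_dropout_prob,
                           cfg$size_jitter_rel, cfg$gel))
    }
  }
  observations <- data.frame(
    individual_id = o_ind[seq_len(row)], locus_id = o_loc[seq_len(row)],
    tier = o_tier[seq_len(row)], bands = o_bands[seq_len(row)],
    stringsAsFactors = FALSE)

  structure(list(
    config = cfg, alleles = alleles, assays = assays,
    individuals = individuals, truth = truth,
    observations = observations,
    polymorphic_loci = names(polymorphic)[polymorphic],
    suppressed_events = truth_key[suppressed]
  ), class = "caps_sim")
}

#' @export
print.caps_sim <- function(x, ...) {
  cat("Synthetic CAPS study:", nrow(x$alleles), "loci,",
      nrow(x$individuals), "individuals,",
      nrow(x$observations), "observed lanes\n")
  cat("  informative loci:",
      sum(vapply(x$assays, `[[`, logical(1L), "informative")), "\n")
  cat("  polymorphic parent loci:",
      length(x$polymorphic_loci), "\n")
  invisible(x)
}

#' Simulate a cDNA-AFLP presence/absence matrix
#'
#' Fragments are drawn from configured class frequencies; each class's
#' presence pattern is generated to classify as that class under
#' [classify_fragment()] (with the `any` quantifier).
#'
#' @param n_fragments number of fragments.
#' @param class_probs named numeric vector of frequencies for
#'   `monomorphic`, `novel`, `maternal_origin`, `paternal_origin`,
#'   `other`; normalized to sum to one.
#' @param n_polyploid,n_maternal,n_paternal individuals per role.
#' @param seed integer seed.
#' @return A `fragment_matrix`.
#' @export
simulate_aflp_matrix <- function(n_fragments,
                                 class_probs = c(monomorphic = 0.35,
                                                 novel = 0.005,
                                                 maternal_origin = 0.05,
                                                 paternal_origin = 0.035,
                                                 other = 0.56),
                                 n_polyploid = 10L, n_maternal = 10L,
                                 n_paternal = 6L, seed = 1L) {
  classes <- c("monomorphic", "novel", "maternal_origin",
               "paternal_origin", "other")
  if (!all(classes %in% names(class_probs))) {
    stop("class_probs must name all of: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  probs <- class_probs[classes] / sum(class_probs[classes])
  set.seed(substream_seed(seed, 6L))
  individuals <- data.frame(
    individual_id = c(sprintf("TM-%02d", seq_len(n_polyploid)),
                      sprintf("TPO-%02d", seq_len(n_maternal)),
                      sprintf("TDU-%02d", seq_len(n_paternal))),
    population_id = "Pullman-1",
    role = rep(c("polyploid", "maternal_parent", "paternal_parent"),
               c(n_polyploid, n_maternal, n_paternal)),
    species_label = rep(c("T. mirus", "T. porrifolius", "T. dubius"),
                        c(n_polyploid, n_maternal, n_paternal)),
    stringsAsFactors = FALSE)
  roles <- individuals$role
  n_ind <- nrow(individuals)
  draw <- sample(classes, n_fragments, replace = TRUE, prob = probs)
  some <- function(n) {  # nonempty random subset indicator
    x <- stats::runif(n) < 0.6
    if (!any(x)) x[sample.int(n, 1L)] <- TRUE
    x
  }
  presence <- matrix(FALSE, n_fragments, n_ind)
  colnames(presence) <- individuals$individual_id
  for (i in seq_len(n_fragments)) {
    row <- logical(n_ind)
    cl <- draw[i]
    if (cl == "monomorphic") {
      row[] <- TRUE
    } else if (cl == "novel") {
      row[roles == "polyploid"] <- some(n_polyploid)
    } else if (cl == "maternal_origin") {
      row[roles == "polyploid"] <- some(n_polyploid)
      row[roles == "maternal_parent"] <- some(n_maternal)
    } else if (cl == "paternal_origin") {
      row[roles == "polyploid"] <- some(n_polyploid)
      row[roles == "paternal_parent"] <- some(n_paternal)
    } else {
      # polymorphic, absent from all polyploids (not a named subtype)
      row[roles == "maternal_parent"] <- some(n_maternal)
    }
    presence[i, ] <- row
  }
  rownames(presence) <- sprintf("frag%05d", seq_len(n_fragments))
  fragment_matrix(presence, individuals)
}
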