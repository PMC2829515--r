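# Genomic-tier genotype calling, parental-polymorphism detection,
# sequencing confirmation and locus summaries.

test_that("call_genotype covers the diagnostic-match decision table exhaustively", {
  a <- make_test_assay(c(120, 80), 200)
  # (maternal matched?, paternal matched?) -> one call each
  cases <- list(
    list(bands = c(200, 120, 80), call = "additive"),       # (>=1, >=1)
    list(bands = c(120, 80),      call = "loss_paternal"),  # (>=1, 0)
    list(bands = 200,             call = "loss_maternal"),  # (0, >=1)
    list(bands = 60,              call = "unscorable"),     # (0, 0), bands present
    list(bands = numeric(0),      call = "unscorable")      # failed lane
  )
  for (cs in cases) {
    res <- call_genotype(cs$bands, a)
    expect_identical(res$call, cs$call)
    expect_true(res$call %in% c("additive", "loss_maternal",
                                "loss_paternal", "unscorable"))
  }
  # one matched diagnostic band per parent suffices (partial dropout
  # of shared or extra diagnostic bands must not flip the call)
  expect_identical(call_genotype(c(200, 120), a)$call, "additive")
  expect_identical(call_genotype(80, a)$call, "loss_paternal")
  expect_error(call_genotype(200, make_test_assay(100, 100)),
               "informative")
})

test_that("individuals missing one parent's diagnostics get the matching loss call", {
  # one individual retains only paternal diagnostics, another only
  # maternal ones (two directions of homeolog loss at the same gene)
  a <- make_test_assay(c(250, 150), c(400))
  expect_identical(call_genotype(400, a)$call, "loss_maternal")
  expect_identical(call_genotype(c(250, 150), a)$call, "loss_paternal")
})

test_that("detect_parental_polymorphism counts band-pattern classes", {
  five_same <- rep(list(c(300, 150)), 5)
  res <- detect_parental_polymorphism(five_same)
  expect_false(res$polymorphic)
  expect_equal(res$n_classes, 1L)

  res2 <- detect_parental_polymorphism(list(c(300), c(300, 150)))
  expect_true(res2$polymorphic)
  expect_equal(res2$n_classes, 2L)

  # paternal-parent individuals carrying an extra band of the other
  # parent's amplicon class
  pat <- c(rep(list(400), 4), rep(list(c(400, 250, 150)), 2))
  res3 <- detect_parental_polymorphism(pat)
  expect_true(res3$polymorphic)
  expect_gte(res3$n_classes, 2L)

  # co-migrating sizes fall in one class
  res4 <- detect_parental_polymorphism(list(c(300), c(302)))
  expect_false(res4$polymorphic)
  expect_error(detect_parental_polymorphism(list()), "at least one")
})

test_that("confirm_loss separates true loss from restriction-site polymorphism", {
  loc <- constructed_locus_200()
  only_m <- confirm_loss(loc$maternal, loc$maternal, loc$paternal)
  expect_identical(only_m$result, "confirmed_loss")
  expect_identical(only_m$recovered_haplotypes, "maternal")

  both <- confirm_loss(c(loc$maternal, loc$paternal),
                       loc$maternal, loc$paternal)
  expect_identical(both$result, "restriction_site_polymorphism")

  expect_identical(confirm_loss(character(0), loc$maternal,
                                loc$paternal)$result, "inconclusive")
  # equidistant recovered sequence: never fabricate a parent assignment
  # (alleles differ at one site; a third base there ties the identities)
  tie <- paste0(substr(loc$maternal, 1, 79), "C",
                substr(loc$maternal, 81, 200))
  expect_identical(confirm_loss(tie, loc$maternal, loc$paternal)$result,
                   "inconclusive")
  # length-incompatible frame is inconclusive, not fatal
  expect_identical(confirm_loss("ACGT", loc$maternal, loc$paternal)$result,
                   "inconclusive")
  # below the identity floor nothing is assigned
  expect_identical(
    confirm_loss(strrep("G", 200), loc$maternal, loc$paternal,
                 min_identity = 0.95)$result,
    "inconclusive")
})

test_that("summarize_locus applies the exclusion-overrides-loss rule", {
  expect_identical(summarize_locus(rep("additive", 10))$gene_status,
                   "additive_all")
  s <- summarize_locus(c(rep("additive", 10), "loss_maternal"))
  expect_identical(s$gene_status, "loss_detected")
  expect_identical(s$lost_parent_set, "maternal")
  expect_identical(
    summarize_locus(c("additive", "loss_paternal"),
                    polymorphic_parent = TRUE)$gene_status,
    "excluded_parental_polymorphism")
  expect_error(summarize_locus(character(0)), "at least one")
})

test_that("noise-free simulated studies are recovered with exact labels", {
  cfg <- sim_config(seed = 21, n_loci = 15, n_polyploid = 12,
                    n_maternal = 4, n_paternal = 6,
                    loss_prob_paternal = 0.15, loss_prob_maternal = 0.08,
                    silencing_prob = 0, parental_polymorphism_prob = 0)
  sim <- simulate_cohort(cfg)
  st <- genotype_study(sim$observations, sim$assays, sim$individuals)
  truth_state <- stats::setNames(
    sim$truth$state, paste(sim$truth$individual_id, sim$truth$locus_id))
  got <- st$calls$call
  want <- truth_state[paste(st$calls$individual_id, st$calls$locus_id)]
  map <- c(additive = "additive", loss_paternal = "maternal_only",
           loss_maternal = "paternal_only")
  expect_identical(unname(map[got]), unname(want))
  # sequencing-based confirmation never mistakes a simulated loss for
  # restriction-site polymorphism: a lost homeolog leaves only one
  # parental amplicon to recover
  lost <- sim$truth[sim$truth$state != "additive", ][1:5, ]
  for (i in seq_len(nrow(lost))) {
    al <- sim$alleles[sim$alleles$locus_id == lost$locus_id[i], ]
    recovered <- if (lost$state[i] == "maternal_only") al$maternal else
      al$paternal
    expect_identical(confirm_loss(recovered, al$maternal, al$paternal)$result,
                     "confirmed_loss")
  }
})

test_that("F1 hybrid cohorts are fully additive at every informative locus", {
  cfg <- sim_config(seed = 8, n_loci = 20, n_polyploid = 0, n_f1 = 6,
                    n_maternal = 3, n_paternal = 3,
                    loss_prob_paternal = 0, loss_prob_maternal = 0,
                    silencing_prob = 0, parental_polymorphism_prob = 0)
  sim <- simulate_cohort(cfg)
  st <- genotype_study(sim$observations, sim$assays, sim$individuals)
  expect_gt(nrow(st$calls), 0L)
  expect_true(all(st$calls$call == "additive"))
})

test_that("genotype_study excludes parentally polymorphic loci and validates ids", {
  f <- caps_fixture_from_counts(n_genes = 6, paternal_loss_genes = 1,
                                maternal_loss_genes = 1,
                                both_parent_loss_genes = 0,
                                excluded_genes = 1, silenced_genes = 1,
                                cdna_genes = 2, n_polyploid = 4,
                                n_maternal = 2, n_paternal = 4)
  st <- genotype_study(f$observations, f$assays, f$individuals)
  expect_identical(st$polymorphic_loci, f$design$excluded_loci)
  status <- vapply(st$locus_summaries, `[[`, character(1), "gene_status")
  expect_identical(unname(status[f$design$excluded_loci]),
                   "excluded_parental_polymorphism")
  # calls at the excluded locus are masked as ambiguous
  amb <- st$calls$call[st$calls$locus_id %in% f$design$excluded_loci]
  expect_true(all(amb == "ambiguous_polymorphism"))

  bad_obs <- f$observations
  bad_obs$individual_id[1] <- "ghost"
  expect_error(genotype_study(bad_obs, f$assays, f$individuals),
               "unknown individual")
})
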