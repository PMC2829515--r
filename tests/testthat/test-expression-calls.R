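# cDNA-tier expression calling and the intensity-ratio readout.

test_that("call_expression decision table: silencing only on an additive genomic call", {
  a <- make_test_assay(c(120, 80), 200)
  cdna_patterns <- list(
    both = c(200, 120, 80), mat_only = c(120, 80),
    pat_only = 200, none = numeric(0), junk = 60)

  # genomic additive: the only branch that can yield silencing
  expect_identical(call_expression("additive", cdna_patterns$both, a),
                   "both_expressed")
  expect_identical(call_expression("additive", cdna_patterns$pat_only, a),
                   "silenced_maternal")
  expect_identical(call_expression("additive", cdna_patterns$mat_only, a),
                   "silenced_paternal")
  expect_identical(call_expression("additive", cdna_patterns$none, a),
                   "unscorable")

  # genomic loss: a missing transcript reflects the loss, never silencing
  expect_identical(call_expression("loss_maternal", cdna_patterns$pat_only, a),
                   "absent_due_to_genomic_loss")
  expect_identical(call_expression("loss_paternal", cdna_patterns$mat_only, a),
                   "absent_due_to_genomic_loss")

  # exhaustive sweep: no genomic call other than additive ever yields a
  # silencing label, and every combination yields exactly one legal enum
  for (g in c("additive", "loss_maternal", "loss_paternal",
              "ambiguous_polymorphism", "unscorable")) {
    for (p in cdna_patterns) {
      call <- call_expression(g, p, a)
      expect_true(call %in% c("both_expressed", "silenced_maternal",
                              "silenced_paternal",
                              "absent_due_to_genomic_loss", "unscorable"))
      if (g != "additive") {
        expect_false(call %in% c("silenced_maternal", "silenced_paternal"))
      }
      if (g %in% c("ambiguous_polymorphism", "unscorable")) {
        expect_identical(call, "unscorable")
      }
    }
  }
})

test_that("expression_ratio computes per-parent sums, dominance and scale invariance", {
  a <- make_test_assay(c(120, 80), 200)
  r1 <- expression_ratio(c("200" = 0.5, "120" = 0.3, "80" = 0.2), a)
  expect_equal(r1$ratio, 1.0)
  expect_identical(r1$dominance, "balanced")
  expect_equal(r1$maternal_intensity, 0.5)  # sum over both maternal bands

  r2 <- expression_ratio(c("200" = 0.9, "120" = 0.1), a)
  expect_equal(r2$ratio, 9.0)
  expect_identical(r2$dominance, "paternal_dominant")

  r3 <- expression_ratio(c("200" = 0.4, "120" = 0), a)
  expect_identical(r3$dominance, "exclusive_paternal")
  expect_true(is.na(r3$ratio))

  r4 <- expression_ratio(c("200" = 0, "120" = 0.4), a)
  expect_identical(r4$dominance, "exclusive_maternal")

  # no diagnostic band measured -> unscorable sentinel
  r5 <- expression_ratio(c("60" = 1.0), a)
  expect_identical(r5$dominance, "unscorable")

  # scale invariance: intensities are relative
  base <- c("200" = 0.6, "120" = 0.25, "80" = 0.15)
  for (c0 in c(0.01, 3, 1000)) {
    ra <- expression_ratio(base, a)
    rb <- expression_ratio(base * c0, a)
    expect_equal(ra$ratio, rb$ratio)
    expect_identical(ra$dominance, rb$dominance)
  }
  expect_error(expression_ratio(base, a, dominance_threshold = 1), "exceed 1")
})

test_that("noise-free expression labels are recovered exactly", {
  cfg <- sim_config(seed = 31, n_loci = 12, n_polyploid = 10,
                    n_maternal = 3, n_paternal = 4,
                    loss_prob_paternal = 0.1, loss_prob_maternal = 0.05,
                    silencing_prob = 0.1, parental_polymorphism_prob = 0)
  sim <- simulate_cohort(cfg)
  st <- genotype_study(sim$observations, sim$assays, sim$individuals)
  ex <- expression_study(st, sim$observations, sim$assays)
  tr <- sim$truth
  key <- paste(tr$individual_id, tr$locus_id)
  want <- ifelse(tr$state == "maternal_only",
                 ifelse(tr$silenced_maternal, "unscorable",
                        "absent_due_to_genomic_loss"),
          ifelse(tr$state == "paternal_only",
                 ifelse(tr$silenced_paternal, "unscorable",
                        "absent_due_to_genomic_loss"),
          ifelse(tr$silenced_maternal & tr$silenced_paternal, "unscorable",
          ifelse(tr$silenced_maternal, "silenced_maternal",
          ifelse(tr$silenced_paternal, "silenced_paternal",
                 "both_expressed")))))
  want <- stats::setNames(want, key)
  expect_identical(ex$expression_call,
                   unname(want[paste(ex$individual_id, ex$locus_id)]))
  # cross-tier consistency: no silencing call for a homeolog the truth
  # marks lost
  lost_keys <- key[tr$state != "additive"]
  sil <- ex[ex$expression_call %in% c("silenced_maternal",
                                      "silenced_paternal"), ]
  expect_false(any(paste(sil$individual_id, sil$locus_id) %in% lost_keys))
})

test_that("silencing false-positive rate per homeolog is bounded by the dropout probability", {
  for (p in c(0.01, 0.05)) {
    n_calls <- 0L
    n_fp <- 0L
    for (s in 1:2) {
      cfg <- sim_config(seed = 1200 + s, loss_prob_paternal = 0,
                        loss_prob_maternal = 0, silencing_prob = 0,
                        parental_polymorphism_prob = 0,
                        band_dropout_prob = p)
      sim <- simulate_cohort(cfg)
      st <- genotype_study(sim$observations, sim$assays, sim$individuals)
      ex <- expression_study(st, sim$observations, sim$assays)
      # every lane is truly additive and fully expressed by construction
      add <- ex[ex$genomic_call == "additive", ]
      n_calls <- n_calls + 2L * nrow(add)  # two homeologs per lane
      n_fp <- n_fp + sum(add$expression_call %in%
                           c("silenced_maternal", "silenced_paternal"))
    }
    expect_gte(n_calls, 2000L)
    expect_lte(n_fp / n_calls, p)
  }
})
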