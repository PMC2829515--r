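# Ground-truthed simulator: determinism, substitution model, loss-rate
# recovery and the never-both-homeologs rule.

test_that("sim_config validates probabilities", {
  expect_error(sim_config(loss_prob_paternal = 1.2), "out of \\[0,1\\]")
  expect_error(sim_config(divergence = -0.1), "out of \\[0,1\\]")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("identical config and seed reproduce byte-identical datasets", {
  cfg <- sim_config(seed = 99, n_loci = 8, n_polyploid = 6,
                    n_maternal = 3, n_paternal = 3,
                    band_dropout_prob = 0.05, size_jitter_rel = 0.01)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$alleles, b$alleles)
  expect_identical(a$truth, b$truth)
  expect_identical(a$observations, b$observations)
  # run-to-disk determinism: both trees serialize identically
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_simulate(cfg, d1)
  run_simulate(cfg, d2)
  for (f in c("alleles.fasta", "individuals.tsv", "observations.tsv",
              "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("zero divergence gives identical allele pairs; positive divergence matches binomial moments", {
  cfg0 <- sim_config(seed = 5, n_loci = 10, divergence = 0,
                     ensure_informative = FALSE)
  al0 <- simulate_parental_alleles(cfg0)
  expect_identical(al0$maternal, al0$paternal)

  cfg <- sim_config(seed = 5, n_loci = 100, locus_length = 1000,
                    divergence = 0.01, ensure_informative = FALSE)
  al <- simulate_parental_alleles(cfg)
  diffs <- vapply(seq_len(nrow(al)), function(i) {
    sum(strsplit(al$maternal[i], "")[[1]] !=
          strsplit(al$paternal[i], "")[[1]])
  }, numeric(1))
  # mean differences per locus ~ Binomial(1000, 0.01): 3-SE band on the
  # mean of 100 loci
  se_mean <- sqrt(1000 * 0.01 * 0.99 / 100)
  expect_lt(abs(mean(diffs) - 10), 3 * se_mean)
})

test_that("simulated alleles written as FASTA are reproducible byte-for-byte", {
  cfg <- sim_config(seed = 77, n_loci = 5)
  p1 <- withr::local_tempfile(fileext = ".fasta")
  p2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(alleles_to_fasta_df(simulate_parental_alleles(cfg)), p1)
  write_fasta(alleles_to_fasta_df(simulate_parental_alleles(cfg)), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("pipeline-recovered loss rates equal realized rates and track the configured grid", {
  # grid of (paternal, maternal) loss probabilities; noise-free; the
  # pipeline estimate must equal the realized simulated rate exactly
  # and sit inside the 99% binomial band around the configured rate
  grid <- expand.grid(pp = c(0, 0.05, 0.1), pm = c(0, 0.05, 0.1))
  for (g in seq_len(nrow(grid))) {
    pp <- grid$pp[g]; pm <- grid$pm[g]
    cfg <- sim_config(seed = 4000 + g, n_loci = 30, n_polyploid = 40,
                      n_maternal = 10, n_paternal = 10,
                      loss_prob_paternal = pp, loss_prob_maternal = pm,
                      silencing_prob = 0, parental_polymorphism_prob = 0)
    sim <- simulate_cohort(cfg)
    st <- genotype_study(sim$observations, sim$assays, sim$individuals)
    n <- nrow(st$calls)
    est_p <- mean(st$calls$call == "loss_paternal")
    est_m <- mean(st$calls$call == "loss_maternal")
    truth <- sim$truth[paste(sim$truth$individual_id, sim$truth$locus_id)
                       %in% paste(st$calls$individual_id,
                                  st$calls$locus_id), ]
    expect_equal(est_p, mean(truth$state == "maternal_only"))
    expect_equal(est_m, mean(truth$state == "paternal_only"))
    # 99% binomial interval around each configured rate (the rare
    # suppression of simultaneous draws shifts the maternal mean by at
    # most pm * pp, far inside the interval width at these sizes)
    ci <- function(p) stats::qbinom(c(0.005, 0.995), n, p) / n
    expect_true(est_p >= ci(pp)[1] && est_p <= ci(pp)[2])
    expect_true(est_m >= ci(pm)[1] && est_m <= ci(pm)[2])
  }
})

test_that("paternal-biased configurations yield paternal-biased loss percentages on average", {
  diffs <- numeric(20)
  for (s in seq_along(diffs)) {
    cfg <- sim_config(seed = 7000 + s, n_loci = 12, n_polyploid = 12,
                      n_maternal = 4, n_paternal = 4,
                      loss_prob_paternal = 0.1, loss_prob_maternal = 0.02,
                      silencing_prob = 0, parental_polymorphism_prob = 0)
    sim <- simulate_cohort(cfg)
    st <- genotype_study(sim$observations, sim$assays, sim$individuals)
    tp <- tally_by_parent(st$locus_summaries, st$calls)
    diffs[s] <- tp$paternal$percent_of_homeologs -
      tp$maternal$percent_of_homeologs
  }
  expect_gt(mean(diffs), 0)
})

test_that("homeolog losses never hit both parents; suppressed draws are logged", {
  cfg <- sim_config(seed = 42, n_loci = 20, n_polyploid = 30,
                    n_maternal = 5, n_paternal = 5,
                    loss_prob_paternal = 0.5, loss_prob_maternal = 0.5)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$state %in%
                    c("additive", "maternal_only", "paternal_only")))
  expect_gt(length(sim$suppressed_events), 0)
  # silencing is only ever defined for retained homeologs
  expect_false(any(sim$truth$silenced_maternal &
                     sim$truth$state == "paternal_only"))
  expect_false(any(sim$truth$silenced_paternal &
                     sim$truth$state == "maternal_only"))
})

test_that("certain parental polymorphism excludes every locus", {
  cfg <- sim_config(seed = 13, n_loci = 10, n_polyploid = 5,
                    n_maternal = 3, n_paternal = 6,
                    parental_polymorphism_prob = 1)
  sim <- simulate_cohort(cfg)
  expect_setequal(sim$polymorphic_loci, sim$alleles$locus_id)
  st <- genotype_study(sim$observations, sim$assays, sim$individuals)
  status <- vapply(st$locus_summaries, `[[`, character(1), "gene_status")
  informative <- vapply(sim$assays, `[[`, logical(1), "informative")
  expect_true(all(status[informative] == "excluded_parental_polymorphism"))
  # the parent patterns themselves show >1 class at every scorable locus
  for (lc in sim$alleles$locus_id[informative]) {
    pats <- sim$observations[sim$observations$locus_id == lc &
                               sim$observations$tier == "genomic" &
                               grepl("^TDU", sim$observations$individual_id), ]
    sets <- lapply(pats$bands, homeoCAPS:::parse_bands)
    expect_true(detect_parental_polymorphism(sets)$polymorphic)
  }
})

test_that("simulated AFLP matrices recover configured class frequencies", {
  m <- simulate_aflp_matrix(10000,
                            class_probs = c(monomorphic = 0.35, novel = 0,
                                            maternal_origin = 0,
                                            paternal_origin = 0,
                                            other = 0.65),
                            seed = 55)
  s <- summarize_matrix(m)
  se <- sqrt(0.35 * 0.65 / 10000)
  expect_lt(abs(s$frac_monomorphic - 0.35), 3 * se)

  all_mono <- simulate_aflp_matrix(
    100, class_probs = c(monomorphic = 1, novel = 0, maternal_origin = 0,
                         paternal_origin = 0, other = 0), seed = 2)
  expect_equal(summarize_matrix(all_mono)$pct_monomorphic, 100.0)

  m1 <- simulate_aflp_matrix(50, seed = 10)
  m2 <- simulate_aflp_matrix(50, seed = 10)
  expect_identical(m1$presence, m2$presence)
})
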