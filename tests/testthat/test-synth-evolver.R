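test_that("random CDS draws uniform sense codons, deterministically by seed", {
  set.seed(31)
  a <- random_cds(3)
  expect_equal(nchar(a), 9L)
  expect_no_error(translate_cds(a))
  set.seed(31)
  expect_identical(random_cds(3), a)
  expect_error(random_cds(2))

  set.seed(32)
  big <- codons_of(random_cds(10000))
  freq <- table(factor(big, levels = paranome:::sense_codons())) / 10000
  p <- 1 / 61
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(freq - p) < 3.3 * se))
})

test_that("evolution to Ks zero is the identity and negative targets error", {
  set.seed(33)
  x <- random_cds(50)
  expect_identical(evolve_to_ks(x, 0), x)
  expect_error(evolve_to_ks(x, -0.1))
})

test_that("NG86 recovers the simulator's target Ks across divergences", {
  # estimator consistency at the study conditions: 200 pairs x 500 codons,
  # divergence split evenly across both branches
  set.seed(11)
  for (t in c(0.2, 0.8, 1.5)) {
    ks <- replicate(200, {
      root <- random_cds(500)
      a <- evolve_to_ks(root, t / 2)
      b <- evolve_to_ks(root, t / 2)
      estimate_ks_ng86(list(codons_of(a), codons_of(b)))$ks
    })
    expect_lt(abs(mean(ks) - t), 0.07 * (1 + t))
  }
})

test_that("one-sided and two-sided evolution give additive divergence", {
  set.seed(34)
  one <- replicate(60, {
    root <- random_cds(500)
    b <- evolve_to_ks(root, 0.8)
    estimate_ks_ng86(list(codons_of(root), codons_of(b)))$ks
  })
  expect_lt(abs(mean(one) - 0.8), 0.07 * 1.8)
})

test_that("paranome simulation honours retention, SSD and determinism", {
  none <- simulate_paranome(simulation_config(n_base_genes = 20,
                                              gene_len_codons = 30,
                                              wgd_retention = 0, ssd_rate = 0,
                                              seed = 35))
  expect_length(none$transcriptome, 20L)
  expect_equal(nrow(none$truth), 0L)

  all_kept <- simulate_paranome(simulation_config(n_base_genes = 100,
                                                  gene_len_codons = 30,
                                                  wgd_retention = 1,
                                                  ssd_rate = 0, seed = 36))
  expect_length(all_kept$transcriptome, 200L)
  expect_equal(nrow(all_kept$truth), 100L)
  expect_true(all(all_kept$truth$event_class == "WGD"))
  expect_true(all(all_kept$truth$true_ks == 0.8))

  cfg <- simulation_config(n_base_genes = 10, gene_len_codons = 30,
                           wgd_retention = 0.5, ssd_rate = 0.5, seed = 37)
  expect_identical(simulate_paranome(cfg), simulate_paranome(cfg))
})

test_that("event counts match their generating distributions", {
  sim <- simulate_paranome(simulation_config(n_base_genes = 400,
                                             gene_len_codons = 9,
                                             wgd_retention = 0.5,
                                             ssd_rate = 0.4, seed = 38))
  n_wgd <- sum(sim$truth$event_class == "WGD" &
                 sim$truth$true_ks == 0.8)
  # retention is Bernoulli(0.5) per gene; WGD pairs at exactly wgd_ks are
  # those whose MRCA is the WGD node
  expect_lt(abs(n_wgd - 200), 3 * sqrt(400 * 0.25))
  n_genes <- length(sim$transcriptome)
  n_ssd_copies <- n_genes - 400 - n_wgd
  expect_lt(abs(n_ssd_copies - 160), 3 * sqrt(160))
})

test_that("species-pair simulation produces the shared-WGD pair structure", {
  sim <- simulate_species_pair(simulation_config(
    n_base_genes = 30, gene_len_codons = 30, wgd_ks = 0.8,
    wgd_retention = 1, ssd_rate = 0, speciation_ks = 0.6, seed = 39))
  expect_length(sim$transcriptome_a, 60L)
  expect_length(sim$transcriptome_b, 60L)
  tr <- sim$truth
  in_a <- function(g) g %in% sim$transcriptome_a$id
  cross <- xor(in_a(tr$gene_a), in_a(tr$gene_b))
  # per base gene: 1 within-species WGD pair per species, 4 cross pairs
  # (2 orthologs at the speciation, 2 paralogs dating the WGD)
  expect_equal(sum(!cross), 60L)
  expect_true(all(tr$true_ks[!cross] == 0.8))
  expect_equal(sum(cross), 120L)
  expect_equal(sum(cross & tr$event_class == "SPECIATION"), 60L)
  expect_true(all(tr$true_ks[cross & tr$event_class == "SPECIATION"] == 0.6))
  expect_true(all(tr$true_ks[cross & tr$event_class == "WGD"] == 0.8))

  lone <- simulate_species_pair(simulation_config(
    n_base_genes = 15, gene_len_codons = 30, wgd_retention = 0,
    ssd_rate = 0, speciation_ks = 0.6, seed = 40))
  expect_true(all(lone$truth$event_class == "SPECIATION"))
  expect_true(all(lone$truth$true_ks == 0.6))

  cfg <- simulation_config(n_base_genes = 10, gene_len_codons = 30,
                           speciation_ks = 0.6, seed = 41)
  expect_identical(simulate_species_pair(cfg), simulate_species_pair(cfg))
  expect_error(simulate_species_pair(simulation_config(n_base_genes = 5)),
               "speciation_ks")
  expect_error(simulation_config(speciation_ks = 0.9, wgd_ks = 0.8))
})
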