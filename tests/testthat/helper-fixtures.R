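# Shared simulation fixtures, built once per test session. The heavier
# end-to-end runs are memoised here because several files probe different
# aspects of the same seeded analysis.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small paranome: 60 base genes, planted WGD at 0.8 over SSD background
small_paranome <- function() {
  fixture("small_paranome", function() {
    sim <- simulate_paranome(simulation_config(
      n_base_genes = 60, wgd_ks = 0.8, wgd_retention = 0.6,
      ssd_rate = 0.3, seed = 501))
    cfg <- pipeline_config(rng_seed = 501)
    dist <- build_paranome_distribution(sim$transcriptome, cfg)
    list(sim = sim, cfg = cfg, dist = dist)
  })
}

# full-size paranome at the study scale (300 base genes), planted WGD 0.8
study_paranome <- function(wgd_ks, seed) {
  fixture(paste0("study_", wgd_ks), function() {
    sim <- simulate_paranome(simulation_config(
      n_base_genes = 300, wgd_ks = wgd_ks, wgd_retention = 0.6,
      ssd_rate = 0.3, seed = seed))
    cfg <- pipeline_config(rng_seed = seed)
    dist <- build_paranome_distribution(sim$transcriptome, cfg)
    list(sim = sim, cfg = cfg, dist = dist)
  })
}

# grow a clean n-member family by serial duplications at distinct ages,
# all far below the saturation ceiling
serial_family <- function(n, len = 400, ages = seq(0.4, 1.6, length.out = n - 1)) {
  ev <- data.frame(t = sort(ages / 2, decreasing = TRUE), class = "SSD")
  st <- paranome:::.grow_family("fam", random_cds(len), ev,
                                omega = 0.2, kappa = 2)
  ids <- sprintf("g%02d", seq_along(st$ids))
  paranome:::new_cds_set(ids, st$seq,
                         vapply(st$seq, translate_cds, character(1),
                                USE.NAMES = FALSE))
}
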