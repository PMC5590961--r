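ks_tab <- function(a, b, ks) data.frame(gene_a = a, gene_b = b, ks = ks)

test_that("subfamily splitting is single-linkage under the Ks ceiling", {
  one <- split_subfamilies(c("a", "b"), ks_tab("a", "b", 0.8), 5)
  expect_equal(one, list(c("a", "b")))
  two <- split_subfamilies(c("a", "b"), ks_tab("a", "b", 7), 5)
  expect_equal(canon_partition(two), list("a", "b"))
  chain <- split_subfamilies(c("a", "b", "c"),
                             ks_tab(c("a", "b", "a"), c("b", "c", "c"),
                                    c(4, 4, 6)), 5)
  expect_equal(chain, list(c("a", "b", "c")))
  # saturated pairs never link
  sat <- split_subfamilies(c("a", "b"), ks_tab("a", "b", Inf), 5)
  expect_equal(canon_partition(sat), list("a", "b"))
})

test_that("neighbor joining solves three taxa in closed form and recovers additive matrices", {
  D <- matrix(c(0, 3, 8, 3, 0, 9, 8, 9, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  # three-point formulas: la = (dab + dac - dbc)/2 etc.
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd[rownames(D), colnames(D)], D, tolerance = 1e-10)

  set.seed(91)
  for (k in 1:10) {
    n <- sample(4:9, 1)
    true <- ape::rtree(n)
    DM <- ape::cophenetic.phylo(true)
    rec <- nj_tree(DM)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(DM), colnames(DM)], DM,
                 tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(true), rec), 0,
                 ignore_attr = TRUE)
  }

  pair <- nj_tree(matrix(c(0, 1.2, 1.2, 0), 2, 2,
                         dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(sum(pair$edge.length), 1.2)
})

test_that("midpoint rooting bisects pairs, centres symmetric trees, finds WGD roots", {
  pair <- midpoint_root(nj_tree(matrix(c(0, 1, 1, 0), 2, 2,
                                       dimnames = list(c("x", "y"),
                                                       c("x", "y")))))
  expect_equal(pair$Nnode, 1L)
  expect_equal(pair$edge.length, c(0.5, 0.5))

  sym <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  rooted <- midpoint_root(ape::unroot(sym))
  expect_equal(rooted$Nnode, 3L)
  # the root splits {a,b} from {c,d}
  kids <- rooted$edge[rooted$edge[, 1] == 5, 2]
  clades <- lapply(kids, function(k)
    sort(rooted$tip.label[phangorn::Descendants(rooted, k, "tips")[[1]]]))
  expect_true(identical(canon_partition(clades), list(c("a", "b"), c("c", "d"))))

  # ultrametric WGD families: the root must separate the two WGD clades
  set.seed(92)
  hits <- 0
  for (k in 1:20) {
    # true distances of a retention-1 family with an extra young SSD copy
    D <- matrix(0.8, 3, 3, dimnames = list(c("a1", "a2", "a3"),
                                           c("a1", "a2", "a3")))
    diag(D) <- 0
    D["a1", "a2"] <- D["a2", "a1"] <- 0.2   # young SSD inside clade one
    noise <- matrix(runif(9, -0.02, 0.02), 3, 3)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    tr <- midpoint_root(nj_tree(pmax(D + noise, 0.01)))
    kids <- tr$edge[tr$edge[, 1] == 4, 2]
    clades <- lapply(kids, function(x)
      sort(tr$tip.label[phangorn::Descendants(tr, x, "tips")[[1]]]))
    if (identical(canon_partition(clades), list(c("a1", "a2"), "a3"))) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / 20, 0.9)
})

test_that("duplication-node weights follow the 1/m rule and conserve mass", {
  # pair family: one entry at weight one
  pair <- midpoint_root(nj_tree(matrix(c(0, 0.8, 0.8, 0), 2, 2,
                                       dimnames = list(c("A", "B"),
                                                       c("A", "B")))))
  wd <- weight_duplication_nodes(pair, ks_tab("A", "B", 0.8))
  expect_equal(nrow(wd), 1L)
  expect_equal(wd$weight, 1)

  # ((A,B),C): node over {A,B} has m = 1; the root has m = 2 at weight 1/2
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  kt <- ks_tab(c("A", "A", "B"), c("B", "C", "C"), c(0.2, 0.9, 1.1))
  wd2 <- weight_duplication_nodes(tr, kt)
  expect_equal(sum(wd2$weight), 2)
  per_node <- tapply(wd2$weight, wd2$node_id, sum)
  expect_true(all(abs(per_node - 1) < 1e-12))
  root_rows <- wd2[wd2$weight == 0.5, ]
  expect_equal(sort(root_rows$ks), c(0.9, 1.1))
  expect_equal(root_rows$node_consensus_ks, c(1.0, 1.0))

  # caterpillar on six leaves: total mass n - 1 = 5
  cat6 <- ape::read.tree(
    text = "(((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,F:5);")
  tips <- cat6$tip.label
  pr <- t(combn(tips, 2))
  kt6 <- ks_tab(pr[, 1], pr[, 2], runif(nrow(pr), 0.1, 2))
  wd6 <- weight_duplication_nodes(cat6, kt6)
  expect_equal(nrow(wd6), nrow(pr))            # n(n-1)/2 = 15 raw estimates
  expect_equal(sum(wd6$weight), 5)
  expect_true(all(abs(tapply(wd6$weight, wd6$node_id, sum) - 1) < 1e-12))

  # a missing cross-pair estimate reduces m
  kt_miss <- kt[-2, ]
  wd_miss <- weight_duplication_nodes(tr, kt_miss)
  expect_equal(sum(wd_miss$weight[wd_miss$node_id ==
                                    wd_miss$node_id[wd_miss$ks == 1.1]]), 1)
})

test_that("a retention-1 simulation yields one unit-weight entry per base gene", {
  sim <- simulate_paranome(simulation_config(n_base_genes = 60,
                                             wgd_retention = 1, ssd_rate = 0,
                                             gene_len_codons = 200, seed = 95))
  dist <- build_paranome_distribution(sim$transcriptome,
                                      pipeline_config(rng_seed = 95))
  expect_gte(nrow(dist), 57)          # >= 95% of families recovered
  expect_true(all(dist$weight == 1))
  expect_error(build_paranome_distribution(
    paranome:::new_cds_set(character(0), character(0), character(0)),
    pipeline_config()), "empty")
})

test_that("the pipeline is deterministic for a fixed seed", {
  fx <- small_paranome()
  again <- build_paranome_distribution(fx$sim$transcriptome, fx$cfg)
  expect_equal(as.data.frame(fx$dist), as.data.frame(again))
})

test_that("the weighted KDE has unit-mass kernels and linear weights", {
  single <- data.frame(ks = 0.8, weight = 1)
  d <- kde_density(single, bandwidth = 0.1)
  expect_equal(d$ks[which.max(d$density)], 0.8, tolerance = 0.02)
  dd <- kde_density(data.frame(ks = 0.8, weight = 2), bandwidth = 0.1)
  expect_equal(dd$density, 2 * d$density, tolerance = 1e-10)

  fx <- small_paranome()
  dens <- kde_density(fx$dist)
  dx <- diff(dens$ks[1:2])
  integral <- sum(dens$density) * dx
  expect_equal(integral, attr(dens, "total_weight"), tolerance = 0.01)
  expect_error(kde_density(single, bandwidth = -1), "bandwidth")
})

test_that("peak calling separates planted bursts and ignores flat backgrounds", {
  set.seed(96)
  flat <- data.frame(ks = runif(300, 0.05, 3), weight = 1)
  pf <- detect_peaks(kde_density(flat, bandwidth = 0.15))
  if (nrow(pf)) {
    expect_lt(max(pf$mass), 0.35 * 300)
  }

  burst <- rbind(flat,
                 data.frame(ks = rnorm(250, 0.8, 0.08), weight = 1))
  pb <- detect_peaks(kde_density(burst, bandwidth = 0.1))
  expect_gte(nrow(pb), 1L)
  expect_true(pb$lo[1] <= 0.8 && pb$hi[1] >= 0.8)
  expect_equal(pb$mode_ks[1], 0.8, tolerance = 0.1)

  two <- rbind(data.frame(ks = rnorm(200, 0.4, 0.05), weight = 1),
               data.frame(ks = rnorm(200, 1.6, 0.1), weight = 1))
  pt <- detect_peaks(kde_density(two, bandwidth = 0.08))
  expect_gte(nrow(pt), 2L)
  top2 <- pt[1:2, ]
  top2 <- top2[order(top2$mode_ks), ]
  expect_equal(top2$mode_ks[1], 0.4, tolerance = 0.1)
  expect_equal(top2$mode_ks[2], 1.6, tolerance = 0.15)
  expect_lt(top2$hi[1], top2$lo[2])  # half-height intervals separated
})

test_that("redundancy correction shrinks a big family's mass by (n-1)/(n(n-1)/2)", {
  set.seed(97)
  # twenty copies born in a single burst at Ks 0.8
  root <- random_cds(300)
  nts <- vapply(1:20, function(i) evolve_to_ks(root, 0.4), character(1))
  ids <- sprintf("g%02d", 1:20)
  cds <- paranome:::new_cds_set(
    ids, nts, vapply(nts, translate_cds, character(1), USE.NAMES = FALSE))
  cfg <- pipeline_config(rng_seed = 97)
  kt <- paranome:::.family_ks_table(ids, cds, cfg)
  expect_equal(nrow(kt), 190L)  # n(n-1)/2 raw estimates
  corrected <- paranome:::.family_distribution("F0001", ids, kt, cfg)
  window <- function(ks) ks >= 0.5 & ks <= 1.1
  raw_mass <- sum(window(kt$ks))
  cor_mass <- sum(corrected$weight[window(corrected$ks)])
  expect_equal(sum(corrected$weight), 19)
  expect_equal(raw_mass / cor_mass, 10, tolerance = 0.2)
})
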