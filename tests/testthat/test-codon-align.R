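# frame-preserving deletion of whole codons, for making gappy families
drop_codons <- function(nt, at) {
  paste(codons_of(nt)[-at], collapse = "")
}

test_that("global alignment of identical peptides is gap-free at the diagonal score", {
  p <- "MKVLITAGPTRE"
  al <- global_protein_align(p, p)
  sub <- paranome:::.aln_alphabet()$sub
  ii <- paranome:::pep_to_int(p)
  expect_equal(al$score, sum(sub[cbind(ii, ii)]))
  expect_identical(al$aligned_a, p)
  expect_identical(al$aligned_b, p)
  expect_error(global_protein_align("A", ""))
})

test_that("progressive MSA reduces to pairwise alignment and degaps cleanly", {
  set.seed(71)
  nt <- random_cds(60)
  pep <- translate_cds(nt)
  two <- setNames(c(pep, pep), c("x", "y"))
  msa2 <- progressive_msa(two)
  al <- global_protein_align(pep, pep)
  expect_identical(unname(msa2), c(al$aligned_a, al$aligned_b))

  three <- setNames(rep(pep, 3), c("x", "y", "z"))
  msa3 <- progressive_msa(three)
  expect_true(all(!grepl("-", msa3)))

  one <- progressive_msa(setNames(pep, "solo"))
  expect_identical(unname(one), pep)
})

test_that("gappy families degap to their inputs after progressive alignment", {
  set.seed(72)
  for (k in 1:5) {
    root <- random_cds(80)
    nts <- c(root,
             drop_codons(evolve_to_ks(root, 0.2), 10:12),
             drop_codons(evolve_to_ks(root, 0.3), 40),
             evolve_to_ks(root, 0.4))
    ids <- paste0("m", 1:4)
    peps <- setNames(vapply(nts, translate_cds, character(1),
                            USE.NAMES = FALSE), ids)
    msa <- progressive_msa(peps)
    expect_length(unique(nchar(msa)), 1L)
    for (i in seq_along(ids)) {
      expect_identical(gsub("-", "", msa[[ids[i]]]), unname(peps[ids[i]]))
    }
  }
})

test_that("MSA sum-of-pairs score is no worse than reverse-order merging", {
  sp_score <- function(rows) {
    sub <- paranome:::.aln_alphabet()$sub
    chars <- do.call(rbind, strsplit(rows, ""))
    total <- 0
    for (i in 1:(nrow(chars) - 1)) for (j in (i + 1):nrow(chars)) {
      both <- chars[i, ] != "-" & chars[j, ] != "-"
      if (any(both)) {
        total <- total + sum(sub[cbind(paranome:::pep_to_int(paste(chars[i, both], collapse = "")),
                                       paranome:::pep_to_int(paste(chars[j, both], collapse = "")))])
      }
    }
    total
  }
  set.seed(73)
  delta <- numeric(0)
  for (k in 1:10) {
    root <- random_cds(60)
    nts <- c(root, drop_codons(evolve_to_ks(root, 0.3), 5:6),
             evolve_to_ks(root, 0.5), drop_codons(evolve_to_ks(root, 0.8), 30))
    peps <- setNames(vapply(nts, translate_cds, character(1),
                            USE.NAMES = FALSE), paste0("s", 1:4))
    msa <- progressive_msa(peps)
    # naive alternative: merge profiles in reverse input order
    blocks <- lapply(rev(seq_along(peps)), function(i) {
      matrix(strsplit(peps[[i]], "")[[1]], nrow = 1,
             dimnames = list(names(peps)[i], NULL))
    })
    acc <- blocks[[1]]
    for (b in blocks[-1]) acc <- paranome:::.merge_profiles(acc, b, 11, 1)
    rev_rows <- apply(acc, 1, paste, collapse = "")
    delta <- c(delta, sp_score(unname(msa)) - sp_score(unname(rev_rows)))
  }
  # sanity, not optimality: guide-tree ordering wins in aggregate
  expect_gte(sum(delta), 0)
  expect_gte(mean(delta >= 0), 0.7)
})

test_that("back-translation maps residues to source codons and checks identity", {
  cds <- paranome:::new_cds_set(c("a", "b"), c("ATGTTT", "ATGGCGTTT"),
                                c("MF", "MAF"))
  msa <- setNames(c("M-F", "MAF"), c("a", "b"))
  ca <- backtranslate(msa, cds)
  expect_identical(ca$codons["a", ], c("ATG", "---", "TTT"))
  expect_identical(ca$codons["b", ], c("ATG", "GCG", "TTT"))
  bad <- setNames(c("M-W", "MAF"), c("a", "b"))
  expect_error(backtranslate(bad, cds), "gene a")
})

test_that("the pairwise codon view drops exactly the gapped columns", {
  set.seed(74)
  root <- random_cds(100)
  nts <- c(root, drop_codons(evolve_to_ks(root, 0.3), c(3:5, 60:63)))
  peps <- setNames(vapply(nts, translate_cds, character(1),
                          USE.NAMES = FALSE), c("a", "b"))
  ca <- backtranslate(progressive_msa(peps), paranome:::new_cds_set(
    c("a", "b"), nts, unname(peps)))
  view <- pairwise_codon_view(ca, "a", "b")
  n_gapped <- sum(ca$codons["a", ] == "---" | ca$codons["b", ] == "---")
  expect_equal(nrow(view), ncol(ca$codons) - n_gapped)
  # symmetry up to element order
  view_rev <- pairwise_codon_view(ca, "b", "a")
  expect_identical(view$codon_a, view_rev$codon_b)
  expect_identical(view$codon_b, view_rev$codon_a)
  # identical rows keep everything
  ca2 <- backtranslate(progressive_msa(setNames(c(peps["a"], peps["a"]),
                                                c("x", "y"))),
                       paranome:::new_cds_set(c("x", "y"), c(root, root),
                                              rep(unname(peps["a"]), 2)))
  expect_equal(nrow(pairwise_codon_view(ca2, "x", "y")), 100L)
  expect_error(pairwise_codon_view(ca, "a", "nope"))
})
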