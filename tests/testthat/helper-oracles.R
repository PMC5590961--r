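# Independent oracles: deliberately simple, written against the problem
# definition rather than the package internals, so they can arbitrate.

options(paranome.verbose = FALSE)

.STD_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_pep <- function(n) paste(sample(.STD_AA, n, replace = TRUE), collapse = "")

# brute-force affine-gap DP, full matrices, scores only
bf_align_score <- function(a, b, gap_open = 11, gap_extend = 1, local = TRUE) {
  sub <- paranome:::.aln_alphabet()$sub
  ia <- paranome:::pep_to_int(a)
  ib <- paranome:::pep_to_int(b)
  la <- length(ia); lb <- length(ib); NEG <- -1e9
  H <- matrix(NEG, la + 1, lb + 1)
  E <- matrix(NEG, la + 1, lb + 1)
  F <- matrix(NEG, la + 1, lb + 1)
  H[1, 1] <- 0
  for (i in 2:(la + 1)) {
    F[i, 1] <- -(gap_open + gap_extend * (i - 1))
    H[i, 1] <- if (local) 0 else F[i, 1]
  }
  for (j in 2:(lb + 1)) {
    E[1, j] <- -(gap_open + gap_extend * (j - 1))
    H[1, j] <- if (local) 0 else E[1, j]
  }
  best <- 0
  for (i in 2:(la + 1)) {
    for (j in 2:(lb + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_extend, H[i, j - 1] - gap_open - gap_extend)
      F[i, j] <- max(F[i - 1, j] - gap_extend, H[i - 1, j] - gap_open - gap_extend)
      h <- max(H[i - 1, j - 1] + sub[ia[i - 1], ib[j - 1]], E[i, j], F[i, j])
      if (local) h <- max(h, 0)
      H[i, j] <- h
      if (h > best) best <- h
    }
  }
  if (local) best else H[la + 1, lb + 1]
}

# NG86 site count of one codon by direct enumeration of the nine mutations
oracle_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  s <- 0
  for (p in 1:3) {
    syn <- 0; sense <- 0
    for (nuc in c("A", "C", "G", "T")) {
      if (substr(codon, p, p) == nuc) next
      mut <- codon
      substr(mut, p, p) <- nuc
      if (gc[[mut]] != "*") {
        sense <- sense + 1
        if (gc[[mut]] == gc[[codon]]) syn <- syn + 1
      }
    }
    if (sense > 0) s <- s + syn / sense
  }
  s
}

# NG86 pathway decomposition by exhaustive recursive enumeration
oracle_diffs <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  if (a == b) return(c(0, 0))
  paths <- list()
  recurse <- function(cur, sd, nd, hit_stop) {
    if (cur == b) {
      paths[[length(paths) + 1L]] <<- c(sd, nd, hit_stop)
      return(invisible(NULL))
    }
    for (p in 1:3) {
      if (substr(cur, p, p) != substr(b, p, p)) {
        nxt <- cur
        substr(nxt, p, p) <- substr(b, p, p)
        syn <- gc[[cur]] != "*" && gc[[nxt]] != "*" && gc[[cur]] == gc[[nxt]]
        recurse(nxt, sd + syn, nd + !syn, hit_stop || gc[[nxt]] == "*")
      }
    }
  }
  recurse(a, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  keep <- m[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  c(mean(m[keep, 1]), mean(m[keep, 2]))
}

# minimal dense MCL: no pruning, cluster readout as connected components
# of the limit matrix's support
mcl_reference <- function(A, inflation = 2, n_iter = 80) {
  ids <- rownames(A)
  diag(A) <- 0
  diag(A) <- pmax(1, apply(A, 1, max))
  M <- sweep(A, 2, colSums(A), "/")
  for (k in seq_len(n_iter)) {
    M <- M %*% M
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
  }
  adj <- (M > 1e-6) | t(M > 1e-6)
  n <- nrow(A)
  comp <- integer(n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      cid <- cid + 1L
      q <- v
      while (length(q)) {
        u <- q[1]; q <- q[-1]
        if (comp[u]) next
        comp[u] <- cid
        q <- c(q, which(adj[u, ] & comp == 0L))
      }
    }
  }
  unname(lapply(split(ids, comp), sort))
}

# canonical form of a partition (list of member vectors) for comparison
canon_partition <- function(p) {
  p <- lapply(p, sort)
  unname(p[order(vapply(p, `[`, character(1), 1))])
}

# split an in-frame CDS string into codons (test-side convenience)
codons_of <- function(nt) paranome:::split_codons(nt)
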