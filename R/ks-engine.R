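# Pairwise synonymous-distance estimation. The default estimator is
# Nei-Gojobori (1986) counting with Jukes-Cantor multiple-hit correction;
# a pairwise maximum-likelihood estimator under a GY94 codon model with
# F3x4 frequencies is available as an alternative.

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each codon position, the fraction of the possible single-nucleotide
#' changes leading to sense codons that are synonymous; changes to stop
#' codons are excluded from the denominator at that position. The codon's
#' synonymous site count `s` is the sum over the three positions and
#' `n = 3 - s`.
#'
#' @param codon A sense codon string.
#' @return Named numeric vector `c(s =, n =)`.
#' @examples
#' ng86_sites("GGG")  # third position fully synonymous: s = 1
#' @export
ng86_sites <- function(codon) {
  gc <- .genetic_code()
  codon <- toupper(codon)
  if (!codon %in% sense_codons()) stop("not a sense codon: ", codon)
  aa <- gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    muts <- vapply(setdiff(.nucs, ref), function(b) {
      x <- codon; substr(x, pos, pos) <- b; x
    }, character(1))
    maa <- gc[muts]
    sense <- maa != "*"
    if (any(sense)) s <- s + sum(maa[sense] == aa) / sum(sense)
  }
  c(s = s, n = 3 - s)
}

# permutations of a small index vector (codon positions, <= 3 elements)
.perms <- function(x) {
  k <- length(x)
  if (k == 1L) return(list(x))
  if (k == 2L) return(list(x, x[2:1]))
  list(x[c(1, 2, 3)], x[c(1, 3, 2)], x[c(2, 1, 3)],
       x[c(2, 3, 1)], x[c(3, 1, 2)], x[c(3, 2, 1)])
}

#' Synonymous and nonsynonymous differences between two codons (NG86)
#'
#' Decomposes the nucleotide differences between two sense codons into
#' synonymous and nonsynonymous changes by averaging, with equal weight,
#' over all minimal mutational pathways between them. Pathways passing
#' through a stop codon are excluded; if every pathway does, all pathways
#' are used (steps into or out of a stop count as nonsynonymous).
#'
#' @param codon_a,codon_b Sense codon strings.
#' @return Named numeric vector `c(sd =, nd =)`; `sd + nd` equals the
#'   Hamming distance of the pair.
#' @examples
#' ng86_diffs("TTT", "TTC")  # one synonymous difference
#' @export
ng86_diffs <- function(codon_a, codon_b) {
  gc <- .genetic_code()
  a <- toupper(codon_a); b <- toupper(codon_b)
  if (!a %in% sense_codons() || !b %in% sense_codons()) {
    stop("both codons must be sense codons")
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  pos <- which(av != bv)
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  res <- lapply(.perms(pos), function(ord) {
    cur <- a; sd <- 0; nd <- 0; through_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (gc[[nxt]] == "*") through_stop <- TRUE
      syn <- gc[[cur]] != "*" && gc[[nxt]] != "*" && gc[[cur]] == gc[[nxt]]
      if (syn) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, through_stop)
  })
  m <- do.call(rbind, res)
  keep <- m[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  c(sd = mean(m[keep, 1]), nd = mean(m[keep, 2]))
}

# Cached per-codon site counts and 61x61 pathway-difference matrices.
ng86_tables <- function() {
  if (!is.null(.paranome_cache$ng86)) return(.paranome_cache$ng86)
  sense <- sense_codons()
  nS <- length(sense)
  sites <- vapply(sense, function(cod) ng86_sites(cod)[["s"]], numeric(1))
  SD <- matrix(0, nS, nS, dimnames = list(sense, sense))
  ND <- SD
  for (i in seq_len(nS - 1L)) {
    for (j in seq.int(i + 1L, nS)) {
      d <- ng86_diffs(sense[i], sense[j])
      SD[i, j] <- SD[j, i] <- d[["sd"]]
      ND[i, j] <- ND[j, i] <- d[["nd"]]
    }
  }
  .paranome_cache$ng86 <- list(sense = sense, sites = sites, SD = SD, ND = ND)
  .paranome_cache$ng86
}

.as_codon_pairs <- function(codon_pairs) {
  if (is.data.frame(codon_pairs)) {
    a <- codon_pairs[[1]]; b <- codon_pairs[[2]]
  } else if (is.list(codon_pairs) && length(codon_pairs) >= 2L) {
    a <- codon_pairs[[1]]; b <- codon_pairs[[2]]
  } else stop("codon_pairs must be a data frame or list of two codon vectors")
  if (length(a) != length(b)) stop("codon vectors differ in length")
  list(a = toupper(a), b = toupper(b))
}

#' Pairwise Ks/Ka by Nei-Gojobori (1986) counting
#'
#' Counts synonymous and nonsynonymous sites and differences over a
#' gap-free list of aligned codon pairs (see [pairwise_codon_view()]) and
#' applies the Jukes-Cantor correction
#' `Ks = -(3/4) * log(1 - (4/3) * pS)`, with `pS = sum(sd) / S` and `S`
#' the mean of the two sequences' synonymous site sums. When `pS >= 3/4`
#' the correction is undefined: the estimate is flagged `saturated` and
#' `ks` is `Inf`. Estimates from fewer than 10 codon pairs are flagged
#' `unreliable`.
#'
#' @param codon_pairs Data frame or list with two parallel vectors of
#'   sense codons.
#' @param gene_a,gene_b Optional gene identifiers carried into the result.
#' @return A list of class `ks_estimate` with fields `ks`, `ka`, `omega`,
#'   `S`, `N`, `codons_used`, `method`, `saturated`, `unreliable`, `pS`,
#'   `pN`, `sd`, `nd`.
#' @export
estimate_ks_ng86 <- function(codon_pairs, gene_a = NA_character_,
                             gene_b = NA_character_) {
  cp <- .as_codon_pairs(codon_pairs)
  if (length(cp$a) == 0L) stop("empty codon pair list")
  tab <- ng86_tables()
  ia <- match(cp$a, tab$sense); ib <- match(cp$b, tab$sense)
  if (anyNA(ia) || anyNA(ib)) stop("non-sense codon in pair list")
  ncod <- length(ia)
  s_a <- sum(tab$sites[ia]); s_b <- sum(tab$sites[ib])
  S <- (s_a + s_b) / 2
  N <- 3 * ncod - S
  idx <- cbind(ia, ib)
  sd <- sum(tab$SD[idx]); nd <- sum(tab$ND[idx])
  pS <- if (S > 0) sd / S else 0
  pN <- if (N > 0) nd / N else 0
  sat <- pS >= 0.75
  ks <- if (sat) Inf else -0.75 * log(1 - 4 / 3 * pS)
  ka <- if (pN >= 0.75) Inf else -0.75 * log(1 - 4 / 3 * pN)
  structure(list(gene_a = gene_a, gene_b = gene_b, ks = ks, ka = ka,
                 omega = if (is.finite(ks) && ks > 0 && is.finite(ka)) ka / ks else NA_real_,
                 S = S, N = N, codons_used = ncod, method = "NG86",
                 saturated = sat, unreliable = ncod < 10L,
                 pS = pS, pN = pN, sd = sd, nd = nd),
            class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("ks_estimate [%s]: ks = %.4f, ka = %.4f (%d codons, S = %.1f, N = %.1f)%s\n",
              x$method, x$ks, x$ka, x$codons_used, x$S, x$N,
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

# ---- GY94 pairwise maximum likelihood -------------------------------------

# F3x4 codon frequencies from the two sequences of a pair (Laplace
# smoothing keeps every sense codon at positive frequency)
.f3x4_freqs <- function(ia, ib, sense) {
  mat <- do.call(rbind, strsplit(c(sense[ia], sense[ib]), ""))
  pos_freq <- lapply(1:3, function(p) {
    cnt <- table(factor(mat[, p], levels = .nucs)) + 1
    as.numeric(cnt / sum(cnt))
  })
  sm <- do.call(rbind, strsplit(sense, ""))
  pi_c <- pos_freq[[1]][match(sm[, 1], .nucs)] *
    pos_freq[[2]][match(sm[, 2], .nucs)] *
    pos_freq[[3]][match(sm[, 3], .nucs)]
  pi_c / sum(pi_c)
}

# GY94 rate matrix over the 61 sense codons for given frequencies;
# scaled so the expected number of substitutions per codon per unit t is 1
.gy94_q <- function(pi_c, kappa, omega, scale = TRUE) {
  tab <- ng86_tables()
  sense <- tab$sense
  nS <- length(sense)
  if (is.null(.paranome_cache$nbr)) {
    # neighbour structure: single-nucleotide changes among sense codons
    ii <- integer(0); jj <- integer(0); ts <- logical(0); syn <- logical(0)
    gc <- .genetic_code()
    for (i in seq_len(nS)) {
      nb <- codon_neighbours(sense[i])
      nb <- nb[nb %in% sense]
      j <- match(nb, sense)
      ii <- c(ii, rep.int(i, length(j))); jj <- c(jj, j)
      pos <- mapply(function(a, b) which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                    sense[i], nb)
      ts <- c(ts, mapply(function(a, b, p) {
        is_transition(substr(a, p, p), substr(b, p, p))
      }, sense[i], nb, pos))
      syn <- c(syn, gc[sense[i]] == gc[nb])
    }
    .paranome_cache$nbr <- list(i = ii, j = jj, ts = ts, syn = syn)
  }
  nbr <- .paranome_cache$nbr
  Q <- matrix(0, nS, nS)
  rate <- pi_c[nbr$j] * ifelse(nbr$ts, kappa, 1) * ifelse(nbr$syn, 1, omega)
  Q[cbind(nbr$i, nbr$j)] <- rate
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi_c * diag(Q))
    Q <- Q / mu
  }
  Q
}

# transition probabilities exp(Qt) via symmetrization of the reversible Q
.gy94_pt <- function(eig, t) {
  P <- eig$inv_sqrt_pi * (eig$U %*% (exp(eig$values * t) * t(eig$U))) *
    rep(eig$sqrt_pi, each = length(eig$sqrt_pi))
  P[P < 0] <- 0
  P / rowSums(P)
}

.gy94_eigen <- function(Q, pi_c) {
  sp <- sqrt(pi_c)
  B <- Q * rep(sp, each = length(sp)) / sp  # diag(sp) %*% Q %*% diag(1/sp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values, U = e$vectors, sqrt_pi = sp, inv_sqrt_pi = 1 / sp)
}

.gy94_loglik <- function(counts, pi_c, kappa, omega, t) {
  Q <- .gy94_q(pi_c, kappa, omega)
  P <- .gy94_pt(.gy94_eigen(Q, pi_c), t)
  L <- pi_c * P
  L[L < 1e-300] <- 1e-300
  sum(counts * log(L))
}

# flux-based decomposition of total divergence t into dS and dN
.gy94_decompose <- function(pi_c, kappa, omega, t) {
  tab <- ng86_tables()
  nbr <- .paranome_cache$nbr
  Q <- .gy94_q(pi_c, kappa, omega)
  flux <- pi_c[nbr$i] * Q[cbind(nbr$i, nbr$j)]
  rho_s <- sum(flux[nbr$syn]) / sum(flux)
  # mutational-opportunity site proportion: same mutation process, no selection
  Q1 <- .gy94_q(pi_c, kappa, 1, scale = FALSE)
  flux1 <- pi_c[nbr$i] * Q1[cbind(nbr$i, nbr$j)]
  s_prop <- sum(flux1[nbr$syn]) / sum(flux1)
  list(ds = t * rho_s / (3 * s_prop),
       dn = t * (1 - rho_s) / (3 * (1 - s_prop)),
       s_prop = s_prop)
}

#' Pairwise Ks/Ka by maximum likelihood under a GY94 codon model
#'
#' Fits divergence `t`, transition/transversion ratio `kappa` and
#' selection ratio `omega` to a pair of aligned coding sequences by
#' maximizing the two-sequence likelihood under a GY94 codon substitution
#' model with F3x4 frequencies estimated from the pair. The fitted `t` is
#' decomposed into `ks` and `ka` using the synonymous flux proportion of
#' the fitted rate matrix and mutational-opportunity site proportions
#' (selection switched off). If the optimizer fails, the NG86 estimate is
#' returned with `method` `"NG86"` and `ml_fallback` set.
#'
#' @inheritParams estimate_ks_ng86
#' @param kappa_init,omega_init Optimizer starting values.
#' @return A `ks_estimate` with `method = "ML"` plus fields `t`, `kappa`,
#'   `omega_ml` and `loglik`.
#' @export
estimate_ks_ml <- function(codon_pairs, kappa_init = 2, omega_init = 0.2,
                           gene_a = NA_character_, gene_b = NA_character_) {
  cp <- .as_codon_pairs(codon_pairs)
  if (length(cp$a) < 30L) {
    stop("ML estimation requires at least 30 codon pairs")
  }
  tab <- ng86_tables()
  ia <- match(cp$a, tab$sense); ib <- match(cp$b, tab$sense)
  if (anyNA(ia) || anyNA(ib)) stop("non-sense codon in pair list")
  ng <- estimate_ks_ng86(codon_pairs, gene_a, gene_b)
  nS <- length(tab$sense)
  counts <- matrix(0, nS, nS)
  for (k in seq_along(ia)) counts[ia[k], ib[k]] <- counts[ia[k], ib[k]] + 1
  pi_c <- .f3x4_freqs(ia, ib, tab$sense)
  if (all(ia == ib)) {
    out <- ng
    out$method <- "ML"
    out$t <- 0; out$kappa <- kappa_init; out$omega_ml <- omega_init
    out$loglik <- .gy94_loglik(counts, pi_c, kappa_init, omega_init, 1e-8)
    out$ks <- 0; out$ka <- 0
    return(out)
  }
  t0 <- if (is.finite(ng$ks)) {
    max(0.01, (ng$ks * ng$S + min(ng$ka, 5) * ng$N) / (3 * ng$codons_used) * 3)
  } else 3
  nll <- function(par) {
    -.gy94_loglik(counts, pi_c, exp(par[2]), exp(par[3]), exp(par[1]))
  }
  fit <- tryCatch(
    optim(c(log(t0), log(kappa_init), log(max(omega_init, 1e-3))), nll,
          method = "Nelder-Mead",
          control = list(maxit = 500, reltol = 1e-9)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) {
    out <- ng
    out$ml_fallback <- TRUE
    return(out)
  }
  t_hat <- exp(fit$par[1]); kappa <- exp(fit$par[2]); omega <- exp(fit$par[3])
  dec <- .gy94_decompose(pi_c, kappa, omega, t_hat)
  out <- ng
  out$method <- "ML"
  out$ks <- dec$ds
  out$ka <- dec$dn
  out$omega <- omega
  out$t <- t_hat
  out$kappa <- kappa
  out$omega_ml <- omega
  out$loglik <- -fit$value
  out$saturated <- out$ks > 10
  out
}
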