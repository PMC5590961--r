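# Forward simulation of transcriptomes with known duplication histories:
# a planted whole-genome duplication with partial retention, a background
# of small-scale duplications, and optionally a two-species split younger
# than the WGD. Sequences evolve under a GY94-style codon substitution
# process with uniform codon frequencies; branch durations are measured
# directly in one-sided Ks units, so that a pair whose lineages diverged
# at time t carries an expected synonymous divergence of 2t.

#' Simulation configuration
#'
#' Parameters of the synthetic transcriptome generator. Defaults emulate
#' an ancient WGD at Ks 0.8 with 60 percent duplicate retention over a
#' background of small-scale duplications (0.3 expected per gene, ages
#' uniform on Ks 0.05-3).
#'
#' @param n_base_genes Number of ancestral genes.
#' @param gene_len_codons Gene length in codons (default 300).
#' @param wgd_ks Synonymous divergence of the planted WGD pairs.
#' @param wgd_retention Probability that a gene keeps its WGD duplicate.
#' @param ssd_rate Expected small-scale duplications per gene (Poisson).
#' @param ssd_ks_range Interval from which SSD pair ages are drawn
#'   uniformly.
#' @param speciation_ks Ortholog divergence of the two-species scenario;
#'   must be younger than `wgd_ks` when set.
#' @param omega Nonsynonymous/synonymous rate ratio of the substitution
#'   process (default 0.2, purifying selection).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param seed Integer RNG seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_base_genes = 300L, gene_len_codons = 300L,
                              wgd_ks = 0.8, wgd_retention = 0.6,
                              ssd_rate = 0.3, ssd_ks_range = c(0.05, 3.0),
                              speciation_ks = NULL, omega = 0.2, kappa = 2.0,
                              seed = 1L) {
  cfg <- list(n_base_genes = as.integer(n_base_genes),
              gene_len_codons = as.integer(gene_len_codons),
              wgd_ks = wgd_ks, wgd_retention = wgd_retention,
              ssd_rate = ssd_rate, ssd_ks_range = ssd_ks_range,
              speciation_ks = speciation_ks, omega = omega, kappa = kappa,
              seed = as.integer(seed))
  stopifnot(cfg$n_base_genes >= 1, cfg$gene_len_codons >= 3,
            cfg$wgd_ks > 0, cfg$wgd_retention >= 0, cfg$wgd_retention <= 1,
            cfg$ssd_rate >= 0, length(cfg$ssd_ks_range) == 2,
            cfg$ssd_ks_range[1] > 0,
            cfg$ssd_ks_range[2] >= cfg$ssd_ks_range[1],
            cfg$omega > 0, cfg$kappa > 0)
  if (!is.null(cfg$speciation_ks)) {
    if (!(cfg$speciation_ks > 0 && cfg$speciation_ks < cfg$wgd_ks)) {
      stop("speciation_ks must satisfy 0 < speciation_ks < wgd_ks")
    }
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Draw a random coding sequence
#'
#' Codons are drawn uniformly from the 61 sense codons, which is also the
#' stationary distribution of the simulator's substitution process.
#'
#' @param length_codons Number of codons (>= 3).
#' @return A single nucleotide string.
#' @export
random_cds <- function(length_codons) {
  stopifnot(length_codons >= 3)
  paste(sample(sense_codons(), length_codons, replace = TRUE), collapse = "")
}

# Eigendecomposition of the simulator's scaled rate matrix, cached per
# (kappa, omega). Rates are symmetric under uniform codon frequencies,
# and the matrix is scaled so one unit of time produces one expected
# synonymous substitution per NG86 synonymous site.
.sim_eigen <- function(kappa, omega) {
  key <- paste0("sim_", kappa, "_", omega)
  if (!is.null(.paranome_cache[[key]])) return(.paranome_cache[[key]])
  tab <- ng86_tables()
  nS <- length(tab$sense)
  pi_u <- rep(1 / nS, nS)
  Q <- .gy94_q(pi_u, kappa, omega, scale = FALSE)
  nbr <- .paranome_cache$nbr
  syn_flux <- sum((pi_u[nbr$i] * Q[cbind(nbr$i, nbr$j)])[nbr$syn])
  mean_sites <- mean(tab$sites)
  Q <- Q * mean_sites / syn_flux
  e <- eigen((Q + t(Q)) / 2, symmetric = TRUE)
  .paranome_cache[[key]] <- list(values = e$values, U = e$vectors, n = nS)
  .paranome_cache[[key]]
}

# codon transition probabilities after time t (one-sided Ks units)
.sim_pt <- function(eig, t) {
  P <- eig$U %*% (exp(eig$values * t) * t(eig$U))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Evolve a coding sequence to a target synonymous divergence
#'
#' Substitutes codons under a GY94-style process (transition/transversion
#' ratio `kappa`, nonsynonymous/synonymous ratio `omega`, stop codons
#' inaccessible) for a total time scaled such that the expected number of
#' synonymous substitutions per synonymous site between input and output
#' equals `target_ks`. Sites are counted in the NG86 sense, matching the
#' downstream estimator's denominator.
#'
#' @param nt In-frame, stop-free coding sequence.
#' @param target_ks Expected synonymous divergence (>= 0).
#' @param omega,kappa Substitution process parameters.
#' @return The evolved nucleotide string (same length).
#' @export
evolve_to_ks <- function(nt, target_ks, omega = 0.2, kappa = 2.0) {
  if (target_ks < 0) stop("target_ks must be >= 0")
  if (target_ks == 0) return(nt)
  tab <- ng86_tables()
  idx <- match(split_codons(nt), tab$sense)
  if (anyNA(idx)) stop("sequence contains stop or invalid codons")
  P <- .sim_pt(.sim_eigen(kappa, omega), target_ks)
  out <- integer(length(idx))
  for (s in unique(idx)) {
    sel <- which(idx == s)
    out[sel] <- sample.int(tab$sense |> length(), length(sel),
                           replace = TRUE, prob = P[s, ])
  }
  paste(tab$sense[out], collapse = "")
}

# ---- gene-family tree construction ----------------------------------------

# A family's history is built by splitting lineages at event times
# (measured backwards from the present in one-sided Ks units, so a pair
# coalescing at time t has pairwise Ks 2t). Events are processed in
# decreasing time order; every current tip is alive at the next, younger
# event. The WGD always duplicates the founding lineage; SSDs duplicate a
# uniformly chosen tip.
#
# Returns tips (id, species), the per-pair MRCA time/class, and sequences.
.grow_family <- function(fam_label, root_nt, events, speciation_t = NULL,
                         young_events_a = NULL, young_events_b = NULL,
                         omega, kappa) {
  # events: data.frame(t, class) with t = age/2, descending, all > speciation_t
  split_tip <- function(state, k, t, cls) {
    n <- length(state$ids)
    new_id <- n + 1L
    state$mrca_t <- rbind(cbind(state$mrca_t, state$mrca_t[, k]),
                          c(state$mrca_t[k, ], 0))
    state$mrca_c <- rbind(cbind(state$mrca_c, state$mrca_c[, k]),
                          c(state$mrca_c[k, ], NA))
    state$mrca_t[new_id, k] <- state$mrca_t[k, new_id] <- t
    state$mrca_c[new_id, k] <- state$mrca_c[k, new_id] <- cls
    state$ids <- c(state$ids, new_id)
    state$seq <- c(state$seq, state$seq[k])
    state$time <- c(state$time, state$time[k])
    state$species <- c(state$species, state$species[k])
    state
  }
  evolve_tip <- function(state, k, to_t) {
    dt <- state$time[k] - to_t
    if (dt > 0) {
      state$seq[k] <- evolve_to_ks(state$seq[k], dt, omega, kappa)
      state$time[k] <- to_t
    }
    state
  }
  t_root <- max(c(events$t, speciation_t,
                  young_events_a$t, young_events_b$t, 0))
  state <- list(ids = 1L, seq = root_nt, time = t_root,
                species = "A",
                mrca_t = matrix(0, 1, 1), mrca_c = matrix(NA_character_, 1, 1))
  if (nrow(events)) {
    for (r in seq_len(nrow(events))) {
      t <- events$t[r]; cls <- events$class[r]
      k <- if (cls == "WGD") 1L else sample.int(length(state$ids), 1L)
      state <- evolve_tip(state, k, t)
      state <- split_tip(state, k, t, cls)
    }
  }
  if (!is.null(speciation_t)) {
    # every lineage splits into an A and a B copy
    n0 <- length(state$ids)
    for (k in seq_len(n0)) {
      state <- evolve_tip(state, k, speciation_t)
      state <- split_tip(state, k, speciation_t, "SPECIATION")
      state$species[length(state$ids)] <- "B"
    }
    for (sp in c("A", "B")) {
      young <- if (sp == "A") young_events_a else young_events_b
      if (is.null(young) || !nrow(young)) next
      for (r in seq_len(nrow(young))) {
        t <- young$t[r]
        cand <- which(state$species == sp)
        k <- cand[sample.int(length(cand), 1L)]
        state <- evolve_tip(state, k, t)
        state <- split_tip(state, k, t, "SSD")
      }
    }
  }
  for (k in seq_along(state$ids)) state <- evolve_tip(state, k, 0)
  state$fam <- fam_label
  state
}

# truth-table rows for all tip pairs of one grown family
.family_truth <- function(state, names) {
  n <- length(state$ids)
  if (n < 2L) return(NULL)
  pr <- combn(n, 2)
  data.frame(gene_a = names[pr[1, ]], gene_b = names[pr[2, ]],
             true_ks = 2 * state$mrca_t[cbind(pr[1, ], pr[2, ])],
             event_class = state$mrca_c[cbind(pr[1, ], pr[2, ])],
             family_id = state$fam, stringsAsFactors = FALSE)
}

#' Simulate a single-species paranome with a planted WGD
#'
#' For each base gene a WGD duplicate is retained with probability
#' `wgd_retention` (the pair diverged by `wgd_ks`, split evenly across the
#' two branches), and `Poisson(ssd_rate)` small-scale duplicates are added
#' at pair ages drawn uniformly from `ssd_ks_range`, duplicating a
#' uniformly chosen lineage alive at that age. The truth table lists every
#' within-family pair with its true path Ks and the event class of the
#' pair's most recent common ancestor.
#'
#' @param config A [simulation_config()].
#' @return `list(transcriptome = cds_set, truth = data.frame)`.
#' @export
simulate_paranome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ids <- character(0); nts <- character(0); truth <- list()
  for (g in seq_len(config$n_base_genes)) {
    fam <- sprintf("f%04d", g)
    retained <- runif(1) < config$wgd_retention
    n_ssd <- rpois(1, config$ssd_rate)
    ev <- data.frame(t = numeric(0), class = character(0))
    if (retained) ev <- rbind(ev, data.frame(t = config$wgd_ks / 2, class = "WGD"))
    if (n_ssd > 0) {
      ages <- runif(n_ssd, config$ssd_ks_range[1], config$ssd_ks_range[2])
      ev <- rbind(ev, data.frame(t = ages / 2, class = "SSD"))
    }
    ev <- ev[order(-ev$t), , drop = FALSE]
    st <- .grow_family(fam, random_cds(config$gene_len_codons), ev,
                       omega = config$omega, kappa = config$kappa)
    nm <- sprintf("%s_c%d", fam, seq_along(st$ids))
    ids <- c(ids, nm); nts <- c(nts, st$seq)
    truth[[g]] <- .family_truth(st, nm)
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(gene_a = character(0), gene_b = character(0),
                        true_ks = numeric(0), event_class = character(0),
                        family_id = character(0))
  }
  peps <- vapply(nts, translate_cds, character(1), USE.NAMES = FALSE)
  list(transcriptome = new_cds_set(ids, nts, peps), truth = truth)
}

#' Simulate a two-species transcriptome pair sharing an ancestral WGD
#'
#' The WGD (and any small-scale duplications older than the speciation)
#' occur in the common ancestor; every lineage then splits into one copy
#' per species at `speciation_ks`, after which younger SSDs arise
#' independently within each species. Expected SSD counts are partitioned
#' between the ancestral and per-species phases in proportion to the
#' corresponding fractions of `ssd_ks_range`, so each species' lineage
#' still carries `ssd_rate` expected duplications. Cross-species pairs
#' descending from the same ancestral lineage are orthologs at
#' `speciation_ks`; cross-species pairs spanning the WGD date to `wgd_ks`.
#'
#' @param config A [simulation_config()] with `speciation_ks` set.
#' @return `list(transcriptome_a =, transcriptome_b =, truth =)`.
#' @export
simulate_species_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$speciation_ks)) stop("speciation_ks must be set")
  if (config$speciation_ks >= config$wgd_ks) {
    stop("speciation_ks must be younger (smaller) than wgd_ks")
  }
  set.seed(config$seed + 1L)
  t_spec <- config$speciation_ks / 2
  lo <- config$ssd_ks_range[1]; hi <- config$ssd_ks_range[2]
  p_old <- if (hi > lo) max(0, hi - max(lo, config$speciation_ks)) / (hi - lo) else 0
  p_young <- max(0, min(hi, config$speciation_ks) - lo) /
    if (hi > lo) (hi - lo) else 1
  ids_a <- character(0); nts_a <- character(0)
  ids_b <- character(0); nts_b <- character(0)
  truth <- list()
  for (g in seq_len(config$n_base_genes)) {
    fam <- sprintf("f%04d", g)
    ev <- data.frame(t = numeric(0), class = character(0))
    if (runif(1) < config$wgd_retention) {
      ev <- rbind(ev, data.frame(t = config$wgd_ks / 2, class = "WGD"))
    }
    n_old <- rpois(1, config$ssd_rate * p_old)
    if (n_old > 0) {
      ages <- runif(n_old, max(lo, config$speciation_ks), hi)
      ev <- rbind(ev, data.frame(t = ages / 2, class = "SSD"))
    }
    ev <- ev[order(-ev$t), , drop = FALSE]
    young <- lapply(c(a = 1, b = 2), function(i) {
      n <- rpois(1, config$ssd_rate * p_young)
      if (n == 0) return(data.frame(t = numeric(0)))
      data.frame(t = sort(runif(n, lo, min(hi, config$speciation_ks)) / 2,
                          decreasing = TRUE))
    })
    st <- .grow_family(fam, random_cds(config$gene_len_codons), ev,
                       speciation_t = t_spec,
                       young_events_a = young$a, young_events_b = young$b,
                       omega = config$omega, kappa = config$kappa)
    cnt <- c(A = 0L, B = 0L)
    nm <- character(length(st$ids))
    for (k in seq_along(st$ids)) {
      sp <- st$species[k]
      cnt[sp] <- cnt[sp] + 1L
      nm[k] <- sprintf("%s_%s_c%d", tolower(sp), fam, cnt[sp])
    }
    sel_a <- st$species == "A"
    ids_a <- c(ids_a, nm[sel_a]); nts_a <- c(nts_a, st$seq[sel_a])
    ids_b <- c(ids_b, nm[!sel_a]); nts_b <- c(nts_b, st$seq[!sel_a])
    truth[[g]] <- .family_truth(st, nm)
  }
  truth <- do.call(rbind, truth)
  list(transcriptome_a = new_cds_set(
         ids_a, nts_a, vapply(nts_a, translate_cds, character(1), USE.NAMES = FALSE)),
       transcriptome_b = new_cds_set(
         ids_b, nts_b, vapply(nts_b, translate_cds, character(1), USE.NAMES = FALSE)),
       truth = truth)
}
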