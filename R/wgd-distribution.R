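# The redundancy-corrected Ks age distribution: families are split into
# subfamilies at a Ks ceiling, a tree is built per subfamily, and every
# duplication node contributes its m cross-clade Ks estimates at weight
# 1/m, so that each duplication event carries unit mass regardless of
# how many surviving descendant pairs date it. A fully resolved
# subfamily of n members therefore contributes total mass n - 1 from its
# n(n-1)/2 pairwise estimates.

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Split a gene family into subfamilies at a Ks ceiling
#'
#' Subfamilies are the connected components (single linkage) of the graph
#' on family members whose edges are pairs with a finite Ks estimate not
#' exceeding `ks_max`. Pairs that are saturated, missing, or above the
#' ceiling never link two subfamilies.
#'
#' @param members Character vector of family member ids.
#' @param ks_table Data frame with columns `gene_a`, `gene_b`, `ks`
#'   covering the family's pairs (extra rows are ignored).
#' @param ks_max Ks ceiling (default 5).
#' @return List of character vectors (members of each subfamily,
#'   singletons included), ordered by smallest member id.
#' @export
split_subfamilies <- function(members, ks_table, ks_max = 5) {
  keep <- ks_table$gene_a %in% members & ks_table$gene_b %in% members &
    is.finite(ks_table$ks) & ks_table$ks <= ks_max
  parent <- seq_along(members)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ia <- match(ks_table$gene_a[keep], members)
  ib <- match(ks_table$gene_b[keep], members)
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(members), find, integer(1))
  subs <- unname(split(members, roots))
  subs <- lapply(subs, sort)
  subs[order(vapply(subs, `[`, character(1), 1))]
}

#' Neighbor-joining tree from a pairwise distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}); additive distance matrices
#' are recovered exactly. Negative branch lengths are clamped to zero
#' with a warning. Two taxa yield the single-edge tree with the distance
#' split evenly.
#'
#' @param D Symmetric non-negative distance matrix with dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n >= 2, !is.null(rownames(D)))
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
               edge.length = rep(D[1, 2] / 2, 2),
               tip.label = rownames(D), Nnode = 1L)
    class(tr) <- "phylo"
    attr(tr, "order") <- "cladewise"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(D))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Midpoint-root a subfamily tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path and
#' resolves any remaining polytomy deterministically, so that an n-leaf
#' tree has exactly n - 1 internal (duplication) nodes.
#'
#' @param tree An unrooted `phylo` tree from [nj_tree()].
#' @return A rooted binary `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  n <- length(tree$tip.label)
  if (n == 2L) return(tree)  # the 2-leaf tree is already its rooted form
  tr <- phangorn::midpoint(tree)
  if (!ape::is.binary(tr)) tr <- ape::multi2di(tr, random = FALSE)
  if (!ape::is.rooted(tr)) tr <- phangorn::midpoint(tr)
  stopifnot(tr$Nnode == n - 1L)
  tr
}

#' Weight the duplication nodes of a rooted subfamily tree
#'
#' Applies the redundancy correction: for each internal (duplication)
#' node, all m available Ks estimates between its two child clades enter
#' the distribution with weight 1/m, so the weights of a single
#' duplication event sum to one. Cross-clade pairs with saturated
#' estimates keep their weight but carry `ks = Inf` (they are excluded
#' from densities downstream); pairs with no estimate at all reduce m.
#'
#' @param tree Rooted binary `phylo` over the subfamily members.
#' @param ks_table Data frame with `gene_a`, `gene_b`, `ks` for the
#'   subfamily's pairs.
#' @param subfamily_id,family_id Identifiers carried into the entries.
#' @return Data frame of distribution entries: `gene_a`, `gene_b`, `ks`,
#'   `weight`, `node_id`, `node_consensus_ks`, `subfamily_id`,
#'   `family_id`.
#' @export
weight_duplication_nodes <- function(tree, ks_table, subfamily_id = "S1",
                                     family_id = NA_character_) {
  n <- length(tree$tip.label)
  lookup <- setNames(ks_table$ks, .pair_key(ks_table$gene_a, ks_table$gene_b))
  rows <- list()
  for (node in seq.int(n + 1L, n + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) != 2L) next
    tips_of <- lapply(kids, function(k) {
      tree$tip.label[phangorn::Descendants(tree, k, "tips")[[1]]]
    })
    ga <- rep(tips_of[[1]], each = length(tips_of[[2]]))
    gb <- rep(tips_of[[2]], times = length(tips_of[[1]]))
    ks <- unname(lookup[.pair_key(ga, gb)])
    avail <- !is.na(ks)
    m <- sum(avail)
    if (m == 0L) {
      pk_log("duplication node %s:%d has no cross-clade Ks estimates",
             subfamily_id, node - n)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = pmin(ga[avail], gb[avail]),
      gene_b = pmax(ga[avail], gb[avail]),
      ks = ks[avail],
      weight = 1 / m,
      node_id = sprintf("%s_n%d", subfamily_id, node - n),
      node_consensus_ks = if (any(is.finite(ks[avail])))
        mean(ks[avail][is.finite(ks[avail])]) else NA_real_,
      subfamily_id = subfamily_id,
      family_id = family_id,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.empty_distribution())
  do.call(rbind, rows)
}

.empty_distribution <- function() {
  data.frame(gene_a = character(0), gene_b = character(0), ks = numeric(0),
             weight = numeric(0), node_id = character(0),
             node_consensus_ks = numeric(0), subfamily_id = character(0),
             family_id = character(0))
}

# pairwise Ks estimates for every member pair of one family
.family_ks_table <- function(members, cds, config) {
  peps <- setNames(cds$pep[match(members, cds$id)], members)
  msa <- progressive_msa(peps, config$gap_open, config$gap_extend)
  ca <- backtranslate(msa, cds)
  pr <- combn(sort(members), 2)
  rows <- vector("list", ncol(pr))
  for (k in seq_len(ncol(pr))) {
    view <- pairwise_codon_view(ca, pr[1, k], pr[2, k])
    if (nrow(view) == 0L) next
    est <- if (config$ks_method == "ML" && nrow(view) >= 30L) {
      estimate_ks_ml(view, gene_a = pr[1, k], gene_b = pr[2, k])
    } else {
      estimate_ks_ng86(view, gene_a = pr[1, k], gene_b = pr[2, k])
    }
    rows[[k]] <- data.frame(gene_a = pr[1, k], gene_b = pr[2, k],
                            ks = est$ks, ka = est$ka, omega = est$omega,
                            S = est$S, N = est$N,
                            codons_used = est$codons_used,
                            method = est$method, saturated = est$saturated,
                            unreliable = est$unreliable,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# distance used for tree building: saturated / missing estimates are
# capped at twice the subfamily ceiling so NJ still sees a finite matrix
.subfamily_distance <- function(members, ks_table, ks_max) {
  D <- matrix(2 * ks_max, length(members), length(members),
              dimnames = list(members, members))
  diag(D) <- 0
  lookup <- setNames(ks_table$ks, .pair_key(ks_table$gene_a, ks_table$gene_b))
  for (i in seq_along(members)) {
    for (j in seq_along(members)) {
      if (i < j) {
        ks <- lookup[.pair_key(members[i], members[j])]
        if (!is.na(ks) && is.finite(ks)) {
          D[i, j] <- D[j, i] <- min(ks, 2 * ks_max)
        }
      }
    }
  }
  D
}

# corrected distribution entries for one family
.family_distribution <- function(family_id, members, ks_table, config) {
  subs <- split_subfamilies(members, ks_table, config$ks_max)
  out <- list()
  si <- 0L
  for (sub in subs) {
    if (length(sub) < 2L) next
    si <- si + 1L
    sub_id <- sprintf("%s_s%d", family_id, si)
    if (length(sub) == 2L) {
      lookup <- setNames(ks_table$ks,
                         .pair_key(ks_table$gene_a, ks_table$gene_b))
      ks <- unname(lookup[.pair_key(sub[1], sub[2])])
      if (is.na(ks)) next
      out[[length(out) + 1L]] <- data.frame(
        gene_a = sub[1], gene_b = sub[2], ks = ks, weight = 1,
        node_id = paste0(sub_id, "_n1"), node_consensus_ks = ks,
        subfamily_id = sub_id, family_id = family_id,
        stringsAsFactors = FALSE)
      next
    }
    D <- .subfamily_distance(sub, ks_table, config$ks_max)
    tr <- midpoint_root(nj_tree(D))
    out[[length(out) + 1L]] <-
      weight_duplication_nodes(tr, ks_table, sub_id, family_id)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Build the redundancy-corrected paranome Ks distribution
#'
#' Runs the full within-species pipeline: all-against-all local
#' alignment, similarity graph, Markov clustering into families,
#' protein-guided codon alignment, pairwise Ks estimation, subfamily
#' splitting at `ks_max`, per-subfamily neighbor-joining trees with
#' midpoint rooting, and 1/m duplication-node weighting.
#'
#' @param transcriptome A `cds_set` (one CDS per gene).
#' @param config A [pipeline_config()].
#' @return Data frame of weighted distribution entries (see
#'   [weight_duplication_nodes()]) with attribute `detail`: a list with
#'   the hit table, families, family-size spectrum and Ks table.
#' @export
build_paranome_distribution <- function(transcriptome, config = pipeline_config()) {
  if (length(transcriptome) == 0L) stop("empty transcriptome")
  set.seed(config$rng_seed)
  pk_log("all-vs-all alignment of %d proteins", length(transcriptome))
  hits <- all_vs_all(transcriptome, config = config)
  pk_log("%d directed hits at E <= %g", nrow(hits), config$evalue_cutoff)
  g <- build_similarity_graph(hits, transcriptome$id)
  fams <- mcl_cluster(g, inflation = config$mcl_inflation)
  pk_log("%d families (%d non-singleton)", length(fams),
         sum(lengths(fams) > 1))
  ks_tables <- list()
  dist_rows <- list()
  for (fid in names(fams)) {
    members <- fams[[fid]]
    if (length(members) < 2L) next
    kt <- .family_ks_table(members, transcriptome, config)
    if (is.null(kt)) next
    kt$family_id <- fid
    ks_tables[[fid]] <- kt
    fd <- .family_distribution(fid, members, kt, config)
    if (!is.null(fd)) dist_rows[[fid]] <- fd
  }
  dist <- if (length(dist_rows)) do.call(rbind, dist_rows) else .empty_distribution()
  rownames(dist) <- NULL
  ks_table <- if (length(ks_tables)) do.call(rbind, ks_tables) else NULL
  pk_log("distribution: %d entries, total weight %.1f", nrow(dist),
         sum(dist$weight))
  attr(dist, "detail") <- list(n_genes = length(transcriptome),
                               hits = hits, families = fams,
                               spectrum = family_size_spectrum(fams),
                               ks_table = ks_table)
  class(dist) <- c("ks_distribution", "data.frame")
  dist
}

#' Weighted Gaussian kernel density of a Ks distribution
#'
#' Renders a weighted multiset of Ks values as a density curve on
#' `[0, ks_max]`. Entries below `min_ks` (default 0.05) are excluded:
#' very young pairs mostly reflect thresholds for calling genes distinct
#' rather than duplication events. Saturated (infinite) and
#' above-ceiling entries are excluded likewise. The kernel is reflected
#' at both boundaries so the curve integrates to the retained total
#' weight; the default bandwidth is Silverman's rule on the weighted
#' sample.
#'
#' @param distribution Data frame with columns `ks` and `weight` (e.g.
#'   from [build_paranome_distribution()] or
#'   [ortholog_ks_distribution()]).
#' @param bandwidth Positive numeric, or `"auto"` for Silverman's rule.
#' @param ks_max Upper limit of the support.
#' @param n_grid Grid resolution.
#' @param min_ks Lower exclusion threshold.
#' @return Data frame `(ks, density)` of class `ks_density`, with
#'   attributes `bw` and `total_weight`.
#' @export
kde_density <- function(distribution, bandwidth = "auto", ks_max = 5,
                        n_grid = 512L, min_ks = 0.05) {
  keep <- is.finite(distribution$ks) & distribution$ks >= min_ks &
    distribution$ks <= ks_max
  x <- distribution$ks[keep]
  w <- distribution$weight[keep]
  if (length(x) == 0L) stop("no finite Ks entries in [min_ks, ks_max]")
  if (identical(bandwidth, "auto")) {
    bw <- .silverman_weighted(x, w)
  } else {
    if (!is.numeric(bandwidth) || bandwidth <= 0) stop("bandwidth must be > 0")
    bw <- bandwidth
  }
  grid <- seq(0, ks_max, length.out = n_grid)
  y <- numeric(n_grid)
  for (i in seq_along(x)) {
    y <- y + w[i] * (stats::dnorm(grid, x[i], bw) +
                     stats::dnorm(grid, -x[i], bw) +
                     stats::dnorm(grid, 2 * ks_max - x[i], bw))
  }
  out <- data.frame(ks = grid, density = y)
  attr(out, "bw") <- bw
  attr(out, "total_weight") <- sum(w)
  attr(out, "entries") <- data.frame(ks = x, weight = w)
  class(out) <- c("ks_density", "data.frame")
  out
}

# Silverman's rule of thumb on a weighted sample, using the effective
# sample size (sum w)^2 / sum w^2
.silverman_weighted <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sdw <- sqrt(sum(w * (x - mu)^2))
  cw <- cumsum(w[order(x)])
  xs <- sort(x)
  qf <- function(p) xs[which(cw >= p)[1]]
  iqr <- qf(0.75) - qf(0.25)
  spread <- min(sdw, iqr / 1.34)
  if (spread <= 0) spread <- max(sdw, 0.05)
  n_eff <- 1 / sum(w^2)
  max(0.9 * spread * n_eff^(-1 / 5), 1e-3)
}

.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Detect peaks in a Ks age-distribution density
#'
#' Peaks are local maxima of the density exceeding 1.5 times the median
#' density level over the curve's support. Each peak is delimited by its
#' half-height interval, clipped at the nearest valley so neighbouring
#' peaks stay separated; the peak's mass is the summed weight of
#' distribution entries inside the interval and its representative age
#' is their weighted median.
#'
#' @param density A [kde_density()] result.
#' @param distribution The distribution the density was built from
#'   (defaults to the entries stored in `density`).
#' @param threshold_factor Peak height threshold as a multiple of the
#'   median density (default 1.5).
#' @return Data frame of peak calls sorted by height: `mode_ks`,
#'   `weighted_median_ks`, `mass`, `lo`, `hi`, `height`. Zero rows when
#'   nothing qualifies (no duplication burst detected).
#' @export
detect_peaks <- function(density, distribution = NULL, threshold_factor = 1.5) {
  y <- density$density
  g <- density$ks
  entries <- if (is.null(distribution)) {
    attr(density, "entries")
  } else {
    keep <- is.finite(distribution$ks)
    data.frame(ks = distribution$ks[keep], weight = distribution$weight[keep])
  }
  # median level over the curve's support (grid cells carrying density),
  # so empty stretches of the Ks axis do not drag the threshold down
  support <- y > 0.01 * max(y)
  thr <- threshold_factor * median(y[support])
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  cand <- which(is_max & y > thr)
  if (!length(cand)) {
    return(data.frame(mode_ks = numeric(0), weighted_median_ks = numeric(0),
                      mass = numeric(0), lo = numeric(0), hi = numeric(0),
                      height = numeric(0)))
  }
  rows <- lapply(cand, function(i) {
    # half-height bounds, clipped at the first valley so a peak never
    # swallows its neighbours
    half <- y[i] / 2
    li <- i; while (li > 1 && y[li] > half && y[li - 1] <= y[li]) li <- li - 1
    ri <- i; while (ri < n && y[ri] > half && y[ri + 1] <= y[ri]) ri <- ri + 1
    lo <- g[li]; hi <- g[ri]
    inside <- entries$ks >= lo & entries$ks <= hi
    data.frame(mode_ks = g[i],
               weighted_median_ks = if (any(inside))
                 .weighted_median(entries$ks[inside], entries$weight[inside])
               else NA_real_,
               mass = sum(entries$weight[inside]),
               lo = lo, hi = hi, height = y[i])
  })
  out <- do.call(rbind, rows)
  out[order(-out$height), , drop = FALSE]
}
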