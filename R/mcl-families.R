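# Markov clustering of the similarity graph into gene families.
# Dense-matrix implementation of the MCL algorithm: self-loop
# regularization, column normalization, then alternating expansion
# (matrix squaring) and inflation (entrywise power + renormalization)
# with pruning of small entries, iterated to a fixed point.

#' Markov clustering of a weighted similarity graph
#'
#' Adds a self-loop to every node (weight = its maximum incident edge
#' weight, at least 1), column-normalizes the adjacency matrix into a
#' column-stochastic flow matrix, and iterates expansion (`M %*% M`) and
#' inflation (entrywise power `inflation`, renormalize), pruning entries
#' below `prune_threshold`, until the largest entrywise change falls
#' below `1e-8` or `max_iter` is reached (the latter warns and reads
#' clusters from the current matrix). Clusters are read off the limit
#' matrix as attractor systems; a node supported by several systems is
#' assigned to the one carrying the most flow, ties broken by smallest
#' member id.
#'
#' @param graph An undirected weighted `igraph` graph (as built by
#'   [build_similarity_graph()]), or a symmetric non-negative adjacency
#'   matrix with dimnames.
#' @param inflation Inflation parameter (> 1, default 2).
#' @param max_iter Iteration cap (default 200).
#' @param prune_threshold Entries below this are zeroed each iteration.
#' @return Named list of gene families: each element a sorted character
#'   vector of member ids; names are `F0001`, `F0002`, ... assigned after
#'   sorting families by their smallest member id. The families partition
#'   the node set.
#' @export
mcl_cluster <- function(graph, inflation = 2.0, max_iter = 200L,
                        prune_threshold = 1e-5) {
  stopifnot(inflation > 1)
  if (inherits(graph, "igraph")) {
    A <- igraph::as_adjacency_matrix(graph, attr = if ("weight" %in%
      igraph::edge_attr_names(graph)) "weight" else NULL, sparse = FALSE)
  } else {
    A <- as.matrix(graph)
  }
  ids <- rownames(A)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(A)))
  n <- nrow(A)
  if (n == 0L) return(list())
  if (any(A < 0)) stop("negative edge weights")
  if (max(abs(A - t(A))) > 1e-12) stop("adjacency matrix must be symmetric")
  diag(A) <- 0
  loop <- pmax(1, apply(A, 1, max))
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2 <- M2^inflation                 # inflation
    M2[M2 < prune_threshold] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < 1e-8) break
    if (it == max_iter) {
      warning("MCL did not converge in ", max_iter,
              " iterations; reading clusters from current matrix")
    }
  }
  .mcl_read_clusters(M, ids)
}

# interpret the (near-)limit flow matrix: rows of attractors define
# clusters; attractors sharing any supported node are merged into one
# attractor system; remaining overlaps resolve by flow mass
.mcl_read_clusters <- function(M, ids) {
  n <- nrow(M)
  eps <- 1e-9
  attr_nodes <- which(diag(M) > eps)
  if (length(attr_nodes) == 0L) attr_nodes <- seq_len(n)
  # merge attractors whose rows overlap on any column
  sys_id <- seq_along(attr_nodes)
  support <- M[attr_nodes, , drop = FALSE] > eps
  repeat {
    changed <- FALSE
    for (a in seq_along(attr_nodes)) {
      ov <- which(sys_id != sys_id[a] &
                    (support %*% support[a, ] > 0))
      if (length(ov)) {
        sys_id[sys_id %in% sys_id[ov]] <- sys_id[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  systems <- split(attr_nodes, sys_id)
  assign <- integer(n)
  for (j in seq_len(n)) {
    mass <- vapply(systems, function(s) sum(M[s, j]), numeric(1))
    if (all(mass <= eps)) {
      # unsupported node (numerical edge case): follow its largest outflow
      owner <- which.max(M[, j])
      mass <- vapply(systems, function(s) as.numeric(owner %in% s), numeric(1))
    }
    best <- which(mass == max(mass))
    if (length(best) > 1L) {
      first_member <- vapply(systems[best], function(s) min(ids[s]), character(1))
      best <- best[order(first_member)][1]
    }
    assign[j] <- best[1]
  }
  fams <- split(ids, assign)
  fams <- lapply(fams, function(x) sort(x))
  fams <- fams[order(vapply(fams, `[`, character(1), 1))]
  names(fams) <- sprintf("F%04d", seq_along(fams))
  fams
}

#' Family-size spectrum
#'
#' @param families Named list of member-id vectors from [mcl_cluster()].
#' @return Data frame `(n, count)`: number of families of each size;
#'   counts sum to the number of families.
#' @export
family_size_spectrum <- function(families) {
  sizes <- lengths(families)
  tab <- table(sizes)
  data.frame(n = as.integer(names(tab)), count = as.integer(tab))
}

#' Write families as a TSV (one row per member)
#'
#' @param families Named list from [mcl_cluster()].
#' @param path Output TSV path.
#' @export
write_families_tsv <- function(families, path) {
  df <- data.frame(family_id = rep(names(families), lengths(families)),
                   gene_id = unlist(families, use.names = FALSE))
  write_tsv(df, path)
}
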