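# All-against-all local protein alignment with Karlin-Altschul E-values,
# thresholded into the weighted similarity graph that seeds gene-family
# clustering. Alignment is exact affine-gap Smith-Waterman-Gotoh with
# BLOSUM62 (open 11, extend 1); no heuristic seeding is used.

# gapped BLOSUM62/11/1 Karlin-Altschul constants
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

.aln_alphabet <- function() {
  if (is.null(.paranome_cache$aln)) {
    b62 <- NULL
    utils::data("BLOSUM62", package = "Biostrings", envir = environment())
    b62 <- get("BLOSUM62", envir = environment())
    std <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    sub <- matrix(-4L, 21L, 21L,
                  dimnames = list(c(std, "?"), c(std, "?")))
    sub[std, std] <- b62[std, std]
    .paranome_cache$aln <- list(alphabet = std, sub = sub)
  }
  .paranome_cache$aln
}

# peptide string -> 1-based integer codes; non-standard residues map to
# the catch-all class scoring -4 against everything
pep_to_int <- function(pep) {
  aln <- .aln_alphabet()
  i <- match(strsplit(pep, "")[[1]], aln$alphabet)
  i[is.na(i)] <- 21L
  i
}

#' Karlin-Altschul bit score and E-value
#'
#' Converts a raw alignment score into a bit score and expected hit count
#' using the gapped BLOSUM62/11/1 constants `lambda = 0.267`,
#' `K = 0.041`: `bits = (lambda * S - log(K)) / log(2)` and
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n`
#' the total database length.
#'
#' @param raw_score Raw alignment score (>= 0).
#' @param len_query Query length in residues.
#' @param len_db_total Summed length of the search database.
#' @return `list(bit_score =, e_value =)`.
#' @export
karlin_altschul_evalue <- function(raw_score, len_query, len_db_total) {
  stopifnot(raw_score >= 0, len_query >= 1, len_db_total >= 1)
  list(bit_score = (.KA_LAMBDA * raw_score - log(.KA_K)) / log(2),
       e_value = .KA_K * len_query * len_db_total * exp(-.KA_LAMBDA * raw_score))
}

# summarize an alignment traceback into hit statistics
.aln_stats <- function(al, chars_a, chars_b) {
  a_idx <- al$a_idx; b_idx <- al$b_idx
  ncol <- length(a_idx)
  both <- !is.na(a_idx) & !is.na(b_idx)
  n_ident <- sum(chars_a[a_idx[both]] == chars_b[b_idx[both]])
  list(raw_score = al$score,
       percent_identity = 100 * n_ident / ncol,
       aln_len = ncol,
       n_ident = n_ident,
       n_mismatch = sum(both) - n_ident,
       gap_opens = sum(diff(c(FALSE, is.na(a_idx))) == 1L) +
         sum(diff(c(FALSE, is.na(b_idx))) == 1L),
       query_span = c(min(a_idx, na.rm = TRUE) - 1L, max(a_idx, na.rm = TRUE)),
       subject_span = c(min(b_idx, na.rm = TRUE) - 1L, max(b_idx, na.rm = TRUE)))
}

#' Optimal local protein alignment (Smith-Waterman-Gotoh)
#'
#' Exact affine-gap local alignment of two peptides under BLOSUM62.
#' Identity is counted as identical residue pairs over all aligned
#' columns, gap columns included; spans are half-open 0-based intervals.
#'
#' @param pep_a,pep_b Non-empty peptide strings.
#' @param gap_open,gap_extend Affine gap penalties (a gap of length L
#'   costs `gap_open + gap_extend * L`).
#' @return A list with `raw_score`, `percent_identity`, `aln_len`,
#'   `query_span`, `subject_span` and the aligned index vectors, or
#'   `NULL` when no positive-scoring local alignment exists.
#' @export
local_align <- function(pep_a, pep_b, gap_open = 11, gap_extend = 1) {
  if (nchar(pep_a) == 0 || nchar(pep_b) == 0) stop("empty peptide")
  aln <- .aln_alphabet()
  ia <- pep_to_int(pep_a); ib <- pep_to_int(pep_b)
  Sm <- aln$sub[ia, ib, drop = FALSE]
  al <- affine_align_cpp(Sm, gap_open, gap_extend, TRUE)
  if (al$score <= 0) return(NULL)
  ca <- strsplit(pep_a, "")[[1]]; cb <- strsplit(pep_b, "")[[1]]
  st <- .aln_stats(al, ca, cb)
  c(st, list(a_idx = al$a_idx, b_idx = al$b_idx))
}

.hit_row <- function(query_id, subject_id, st, bit, ev) {
  data.frame(query_id = query_id, subject_id = subject_id,
             raw_score = st$raw_score, bit_score = bit, e_value = ev,
             percent_identity = st$percent_identity, aln_len = st$aln_len,
             n_mismatch = st$n_mismatch, gap_opens = st$gap_opens,
             q_start = st$query_span[1], q_end = st$query_span[2],
             s_start = st$subject_span[1], s_end = st$subject_span[2],
             stringsAsFactors = FALSE)
}

#' All-against-all local alignment search
#'
#' Aligns every ordered pair of peptides (one set, excluding self-hits)
#' or every cross-set pair in both directions (two sets) and retains
#' directed hits with `e_value <= evalue_cutoff`. E-values use the query
#' length and the summed length of the searched set.
#'
#' @param cds_a A `cds_set` (the only set, for a within-set search).
#' @param cds_b Optional second `cds_set`; if given, the search is
#'   cross-set in both directions (for reciprocal-best-hit orthology).
#' @param config A [pipeline_config()].
#' @return Data frame of directed `AlignmentHit` rows: `query_id`,
#'   `subject_id`, `raw_score`, `bit_score`, `e_value`,
#'   `percent_identity`, `aln_len`, `n_mismatch`, `gap_opens` and
#'   half-open 0-based spans.
#' @export
all_vs_all <- function(cds_a, cds_b = NULL, config = pipeline_config()) {
  aln <- .aln_alphabet()
  symmetric <- is.null(cds_b)
  if (symmetric && length(cds_a) < 2) stop("need at least 2 sequences")
  ints_a <- lapply(cds_a$pep, pep_to_int)
  ints_b <- if (symmetric) ints_a else lapply(cds_b$pep, pep_to_int)
  scores <- sw_score_all_cpp(ints_a, if (symmetric) list() else ints_b,
                             aln$sub, config$gap_open, config$gap_extend,
                             symmetric)
  len_a <- nchar(cds_a$pep)
  len_b <- if (symmetric) len_a else nchar(cds_b$pep)
  db_a <- sum(len_a); db_b <- sum(len_b)
  # database searched from each direction: the subject set
  n_for_a_query <- if (symmetric) db_a else db_b
  n_for_b_query <- db_a
  rows <- vector("list", 0)
  idx <- which(if (symmetric) upper.tri(scores) else scores >= 0, arr.ind = TRUE)
  sc <- scores[idx]
  e_ab <- .KA_K * len_a[idx[, 1]] * n_for_a_query * exp(-.KA_LAMBDA * sc)
  e_ba <- .KA_K * len_b[idx[, 2]] * n_for_b_query * exp(-.KA_LAMBDA * sc)
  keep <- (e_ab <= config$evalue_cutoff) | (e_ba <= config$evalue_cutoff)
  idx <- idx[keep, , drop = FALSE]
  e_ab <- e_ab[keep]; e_ba <- e_ba[keep]; sc <- sc[keep]
  set_b <- if (symmetric) cds_a else cds_b
  out <- vector("list", nrow(idx) * 2L)
  nout <- 0L
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    al <- local_align(cds_a$pep[i], set_b$pep[j],
                      config$gap_open, config$gap_extend)
    if (is.null(al)) next
    bits <- (.KA_LAMBDA * al$raw_score - log(.KA_K)) / log(2)
    if (e_ab[r] <= config$evalue_cutoff) {
      nout <- nout + 1L
      out[[nout]] <- .hit_row(cds_a$id[i], set_b$id[j], al, bits, e_ab[r])
    }
    if (e_ba[r] <= config$evalue_cutoff) {
      st_rev <- al
      st_rev$query_span <- al$subject_span
      st_rev$subject_span <- al$query_span
      nout <- nout + 1L
      out[[nout]] <- .hit_row(set_b$id[j], cds_a$id[i], st_rev, bits, e_ba[r])
    }
  }
  if (nout == 0L) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      raw_score = numeric(0), bit_score = numeric(0),
                      e_value = numeric(0), percent_identity = numeric(0),
                      aln_len = integer(0), n_mismatch = integer(0),
                      gap_opens = integer(0), q_start = integer(0),
                      q_end = integer(0), s_start = integer(0),
                      s_end = integer(0)))
  }
  do.call(rbind, out[seq_len(nout)])
}

#' Write a hit table in 12-column tabular search format
#'
#' Columns: query, subject, percent identity, alignment length,
#' mismatches, gap opens, query start/end, subject start/end (1-based
#' inclusive), E-value, bit score.
#'
#' @param hits Hit table from [all_vs_all()].
#' @param path Output TSV path.
#' @export
write_hits_tsv <- function(hits, path) {
  tab <- data.frame(query = hits$query_id, subject = hits$subject_id,
                    pident = hits$percent_identity, length = hits$aln_len,
                    mismatch = hits$n_mismatch, gapopen = hits$gap_opens,
                    qstart = hits$q_start + 1L, qend = hits$q_end,
                    sstart = hits$s_start + 1L, send = hits$s_end,
                    evalue = hits$e_value, bitscore = hits$bit_score)
  write_tsv(tab, path)
}

#' Build the weighted similarity graph
#'
#' Nodes are all genes (singletons included); an undirected edge joins
#' two genes if at least one direction of their alignment passed the
#' E-value cutoff, weighted by `min(200, -log10(E))` averaged over the
#' available directions (an E-value of zero maps to 200).
#'
#' @param hits Directed hit table from [all_vs_all()].
#' @param all_ids Character vector of every gene id (to retain
#'   singletons as isolated nodes).
#' @return An `igraph` undirected weighted graph.
#' @export
build_similarity_graph <- function(hits, all_ids) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_ids), name = all_ids)
  if (nrow(hits) == 0L) return(g)
  w <- pmin(200, -log10(hits$e_value))
  a <- pmin(hits$query_id, hits$subject_id)
  b <- pmax(hits$query_id, hits$subject_id)
  key <- paste(a, b, sep = "\r")
  agg <- tapply(w, key, mean)
  pairs <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  if (length(agg)) {
    g <- igraph::add_edges(g, t(cbind(match(pairs[, 1], all_ids),
                                      match(pairs[, 2], all_ids))),
                           weight = as.numeric(agg))
  }
  g
}
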