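# One-to-one ortholog identification between two species by reciprocal
# best hits, identity/length filtering, and the ortholog Ks divergence
# distribution that dates the speciation relative to the WGD peaks.

# best subject per query: highest bit score, then lowest E-value, then
# lexicographically smallest subject id
.best_hits <- function(hits) {
  if (!nrow(hits)) {
    return(hits[integer(0), ])
  }
  o <- order(hits$query_id, -hits$bit_score, hits$e_value, hits$subject_id)
  h <- hits[o, ]
  h[!duplicated(h$query_id), ]
}

#' Reciprocal best hits between two proteomes
#'
#' For each gene the best cross-species hit is taken by bit score (ties:
#' lower E-value, then lexicographic subject id); a pair is kept iff the
#' choice is mutual, which guarantees a one-to-one mapping.
#'
#' @param hits_a_to_b,hits_b_to_a Directed hit tables from
#'   [all_vs_all()] restricted to the respective direction.
#' @return Data frame `(gene_a, gene_b, bit_score, percent_identity,
#'   aln_len)` with the alignment statistics of the A-to-B hit.
#' @export
reciprocal_best_hits <- function(hits_a_to_b, hits_b_to_a) {
  ba <- .best_hits(hits_a_to_b)
  bb <- .best_hits(hits_b_to_a)
  back <- setNames(bb$subject_id, bb$query_id)
  mutual <- !is.na(back[ba$subject_id]) & back[ba$subject_id] == ba$query_id
  kept <- ba[mutual, , drop = FALSE]
  data.frame(gene_a = kept$query_id, gene_b = kept$subject_id,
             bit_score = kept$bit_score,
             percent_identity = kept$percent_identity,
             aln_len = kept$aln_len, stringsAsFactors = FALSE)
}

#' Filter ortholog pairs by identity and alignment length
#'
#' Valid ortholog pairs must reach at least `min_identity` percent
#' identity over at least `min_len` aligned amino acids (both thresholds
#' inclusive; identity is counted over all alignment columns, gaps
#' included). Rejection counts are logged by reason.
#'
#' @param pairs Data frame from [reciprocal_best_hits()].
#' @param min_identity Minimum percent identity (default 30).
#' @param min_len Minimum alignment length in amino acids (default 150).
#' @return The retained subset of `pairs`.
#' @export
filter_ortholog_pairs <- function(pairs, min_identity = 30, min_len = 150) {
  ok_id <- pairs$percent_identity >= min_identity
  ok_len <- pairs$aln_len >= min_len
  pk_log("ortholog filter: %d/%d retained (%d below identity, %d below length)",
         sum(ok_id & ok_len), nrow(pairs), sum(!ok_id), sum(!ok_len))
  pairs[ok_id & ok_len, , drop = FALSE]
}

#' Ortholog Ks divergence distribution
#'
#' Estimates one Ks per ortholog pair from a direct pairwise codon
#' alignment of the two CDS. Orthologs date a single event (the
#' speciation), so no redundancy correction applies: every pair enters
#' at weight 1. Saturated estimates are kept with `ks = Inf` and drop
#' out of densities via the same exclusions as the paranome.
#'
#' @param pairs Filtered ortholog pairs ([filter_ortholog_pairs()]).
#' @param cds_a,cds_b The two species' `cds_set`s.
#' @param config A [pipeline_config()].
#' @return Data frame `(gene_a, gene_b, ks, ka, weight, codons_used,
#'   method)`.
#' @export
ortholog_ks_distribution <- function(pairs, cds_a, cds_b,
                                     config = pipeline_config()) {
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ia <- match(pairs$gene_a[k], cds_a$id)
    ib <- match(pairs$gene_b[k], cds_b$id)
    if (is.na(ia) || is.na(ib)) stop("CDS missing for ortholog pair")
    al <- global_protein_align(cds_a$pep[ia], cds_b$pep[ib],
                               config$gap_open, config$gap_extend)
    ra <- strsplit(al$aligned_a, "")[[1]]
    rb <- strsplit(al$aligned_b, "")[[1]]
    keep <- ra != "-" & rb != "-"
    ca <- split_codons(cds_a$nt[ia])[cumsum(ra != "-")[keep]]
    cb <- split_codons(cds_b$nt[ib])[cumsum(rb != "-")[keep]]
    if (!length(ca)) next
    est <- if (config$ks_method == "ML" && length(ca) >= 30L) {
      estimate_ks_ml(list(ca, cb), gene_a = pairs$gene_a[k],
                     gene_b = pairs$gene_b[k])
    } else {
      estimate_ks_ng86(list(ca, cb), gene_a = pairs$gene_a[k],
                       gene_b = pairs$gene_b[k])
    }
    rows[[k]] <- data.frame(gene_a = pairs$gene_a[k], gene_b = pairs$gene_b[k],
                            ks = est$ks, ka = est$ka, weight = 1,
                            codons_used = est$codons_used,
                            method = est$method, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      ks = numeric(0), ka = numeric(0), weight = numeric(0),
                      codons_used = integer(0), method = character(0)))
  }
  do.call(rbind, rows)
}
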