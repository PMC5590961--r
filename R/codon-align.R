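# Protein-guided codon alignment of gene families: global pairwise
# alignment (Needleman-Wunsch-Gotoh), progressive multiple alignment
# along a neighbor-joining guide tree with profile-profile alignment,
# and back-translation of the protein alignment to codons.

#' Optimal global protein alignment (Needleman-Wunsch-Gotoh)
#'
#' Affine-gap global alignment under BLOSUM62, end gaps penalized.
#' Traceback ties resolve deterministically (match, then gap in `a`,
#' then gap in `b`).
#'
#' @inheritParams local_align
#' @return `list(score, aligned_a, aligned_b)` where the aligned strings
#'   contain `-` for gaps and degap to their inputs.
#' @export
global_protein_align <- function(pep_a, pep_b, gap_open = 11, gap_extend = 1) {
  if (nchar(pep_a) == 0 || nchar(pep_b) == 0) stop("empty peptide")
  aln <- .aln_alphabet()
  ia <- pep_to_int(pep_a); ib <- pep_to_int(pep_b)
  Sm <- aln$sub[ia, ib, drop = FALSE]
  al <- affine_align_cpp(Sm, gap_open, gap_extend, FALSE)
  ca <- strsplit(pep_a, "")[[1]]; cb <- strsplit(pep_b, "")[[1]]
  list(score = al$score,
       aligned_a = paste(ifelse(is.na(al$a_idx), "-", ca[al$a_idx]), collapse = ""),
       aligned_b = paste(ifelse(is.na(al$b_idx), "-", cb[al$b_idx]), collapse = ""))
}

# residue-frequency profile of an aligned block (rows x columns matrix
# of single characters); gaps contribute nothing to a column
.profile_freq <- function(block) {
  aln <- .aln_alphabet()
  nres <- 21L
  L <- ncol(block)
  F <- matrix(0, L, nres)
  nrow_b <- nrow(block)
  for (r in seq_len(nrow_b)) {
    i <- match(block[r, ], aln$alphabet)
    i[block[r, ] == "-"] <- NA
    i[is.na(i) & block[r, ] != "-"] <- 21L
    ok <- !is.na(i)
    F[cbind(which(ok), i[ok])] <- F[cbind(which(ok), i[ok])] + 1
  }
  F / nrow_b
}

# align two aligned blocks by profile-profile NW with mean-of-pairs
# column scores (gap residues score 0 in the average)
.merge_profiles <- function(block_a, block_b, gap_open, gap_extend) {
  aln <- .aln_alphabet()
  Fa <- .profile_freq(block_a)
  Fb <- .profile_freq(block_b)
  Sm <- Fa %*% aln$sub %*% t(Fb)
  al <- affine_align_cpp(Sm, gap_open, gap_extend, FALSE)
  L <- length(al$a_idx)
  out <- matrix("-", nrow(block_a) + nrow(block_b), L)
  ok_a <- !is.na(al$a_idx)
  out[seq_len(nrow(block_a)), ok_a] <- block_a[, al$a_idx[ok_a], drop = FALSE]
  ok_b <- !is.na(al$b_idx)
  out[nrow(block_a) + seq_len(nrow(block_b)), ok_b] <-
    block_b[, al$b_idx[ok_b], drop = FALSE]
  rownames(out) <- c(rownames(block_a), rownames(block_b))
  out
}

#' Progressive multiple protein alignment
#'
#' Aligns a family of peptides progressively: the guide tree is
#' neighbor-joining on Poisson-corrected p-distances from all pairwise
#' global alignments, midpoint-rooted; profiles are merged bottom-up by
#' profile-profile Needleman-Wunsch with mean-of-pairs column scores.
#'
#' @param peptides Named character vector of peptides (>= 1).
#' @param gap_open,gap_extend Affine gap penalties.
#' @return Named character vector of equal-length aligned rows; each row
#'   degaps to its input.
#' @export
progressive_msa <- function(peptides, gap_open = 11, gap_extend = 1) {
  n <- length(peptides)
  if (is.null(names(peptides)) || anyDuplicated(names(peptides))) {
    stop("peptides must have unique names")
  }
  if (n == 1L) return(peptides)
  if (n == 2L) {
    al <- global_protein_align(peptides[1], peptides[2], gap_open, gap_extend)
    return(setNames(c(al$aligned_a, al$aligned_b), names(peptides)))
  }
  ids <- names(peptides)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      al <- global_protein_align(peptides[i], peptides[j], gap_open, gap_extend)
      a <- strsplit(al$aligned_a, "")[[1]]
      b <- strsplit(al$aligned_b, "")[[1]]
      both <- a != "-" & b != "-"
      p <- if (any(both)) mean(a[both] != b[both]) else 1
      D[i, j] <- D[j, i] <- -log(1 - min(p, 0.95))
    }
  }
  guide <- midpoint_root(nj_tree(D))
  blocks <- lapply(seq_len(n), function(i) {
    matrix(strsplit(peptides[i], "")[[1]], nrow = 1,
           dimnames = list(ids[i], NULL))
  })
  names(blocks) <- ids
  merge_node <- function(node) {
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    sub <- lapply(kids, function(k) {
      if (k <= length(guide$tip.label)) blocks[[guide$tip.label[k]]]
      else merge_node(k)
    })
    out <- sub[[1]]
    for (s in sub[-1]) out <- .merge_profiles(out, s, gap_open, gap_extend)
    out
  }
  res <- merge_node(length(guide$tip.label) + 1L)
  rows <- apply(res, 1, paste, collapse = "")
  rows[ids]
}

#' Back-translate a protein alignment to codons
#'
#' Replaces each aligned residue by its source codon and each gap by
#' `---`, after checking that every peptide row degaps to the
#' translation of its CDS.
#'
#' @param msa Named character vector of aligned peptide rows.
#' @param cds A `cds_set` containing every member.
#' @return A `codon_alignment`: list with `member_ids` and `codons`, a
#'   members x columns character matrix of codons (`---` for gaps).
#' @export
backtranslate <- function(msa, cds) {
  ids <- names(msa)
  pos <- match(ids, cds$id)
  if (anyNA(pos)) stop("CDS missing for: ", paste(ids[is.na(pos)], collapse = ", "))
  ncol_aln <- unique(nchar(msa))
  if (length(ncol_aln) != 1L) stop("alignment rows differ in length")
  codons <- matrix("---", length(ids), ncol_aln, dimnames = list(ids, NULL))
  for (k in seq_along(ids)) {
    row <- strsplit(msa[[k]], "")[[1]]
    res <- row != "-"
    src <- split_codons(cds$nt[pos[k]])
    if (paste(row[res], collapse = "") != cds$pep[pos[k]]) {
      stop("peptide row does not match translated CDS for gene ", ids[k])
    }
    codons[k, res] <- src
  }
  structure(list(member_ids = ids, codons = codons), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d members x %d codon columns\n",
              length(x$member_ids), ncol(x$codons)))
  invisible(x)
}

#' Gap-free pairwise codon view of a family alignment
#'
#' Extracts the columns of a codon alignment where neither of two members
#' has a gap; this is the codon-pair list consumed by the Ks estimators
#' (gap columns are excluded per pair, not alignment-wide).
#'
#' @param codon_alignment A [backtranslate()] result.
#' @param id_a,id_b Member ids.
#' @return Data frame `(codon_a, codon_b)`; zero rows if the members
#'   never overlap.
#' @export
pairwise_codon_view <- function(codon_alignment, id_a, id_b) {
  ca <- codon_alignment$codons
  if (!id_a %in% rownames(ca) || !id_b %in% rownames(ca)) {
    stop("both ids must be alignment members")
  }
  a <- ca[id_a, ]; b <- ca[id_b, ]
  keep <- a != "---" & b != "---"
  data.frame(codon_a = a[keep], codon_b = b[keep], stringsAsFactors = FALSE)
}
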