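# FASTA input/output, CDS validation and translation, configuration and
# result-table plumbing shared by all pipeline stages.

#' Translate an in-frame coding sequence
#'
#' Translates a nucleotide CDS under the standard genetic code. The input
#' must be stop-free: records read through [read_cds_fasta()] have their
#' terminal stop codon removed before translation, and any remaining stop
#' codon invalidates the record.
#'
#' @param nt Nucleotide string over `A`, `C`, `G`, `T` whose length is a
#'   multiple of 3.
#' @return The amino-acid string.
#' @examples
#' translate_cds("ATGTTT")
#' @export
translate_cds <- function(nt) {
  if (length(nt) != 1L || !is.character(nt)) stop("nt must be a single string")
  codons <- split_codons(toupper(nt))
  bad <- !codons %in% names(.genetic_code())
  if (any(bad)) stop("invalid codon(s): ", paste(unique(codons[bad]), collapse = ", "))
  aa <- codon_aa(codons)
  if (any(aa == "*")) stop("CDS contains a stop codon")
  paste(aa, collapse = "")
}

# Validate one CDS record against the pipeline's invariants.
# Returns list(ok, nt, pep, reason); the terminal stop codon, if present,
# is stripped before storing. The minimum-length rule (>= 9 nt) applies to
# the input as given, so a 3-codon ORF ending in a stop is still accepted.
validate_cds <- function(nt) {
  nt <- toupper(nt)
  if (grepl("[^ACGT]", nt)) {
    return(list(ok = FALSE, reason = "ambiguous or non-ACGT base"))
  }
  if (nchar(nt) %% 3L != 0L) {
    return(list(ok = FALSE, reason = "length not a multiple of 3"))
  }
  if (nchar(nt) < 9L) {
    return(list(ok = FALSE, reason = "shorter than 9 nt"))
  }
  codons <- split_codons(nt)
  aa <- codon_aa(codons)
  n <- length(codons)
  if (aa[n] == "*") {
    codons <- codons[-n]
    aa <- aa[-n]
    n <- n - 1L
  }
  if (any(aa == "*")) {
    return(list(ok = FALSE, reason = "internal stop codon"))
  }
  list(ok = TRUE, nt = paste(codons, collapse = ""), pep = paste(aa, collapse = ""))
}

# light container for a set of coding sequences: parallel character
# vectors id / nt / pep
new_cds_set <- function(id, nt, pep) {
  stopifnot(length(id) == length(nt), length(nt) == length(pep))
  structure(list(id = as.character(id), nt = as.character(nt),
                 pep = as.character(pep)),
            class = "cds_set")
}

#' @export
length.cds_set <- function(x) length(x$id)

#' @export
print.cds_set <- function(x, ...) {
  cat(sprintf("cds_set with %d coding sequences (mean length %.0f nt)\n",
              length(x), if (length(x)) mean(nchar(x$nt)) else 0))
  invisible(x)
}

# subset a cds_set by index or id
cds_subset <- function(x, i) {
  if (is.character(i)) i <- match(i, x$id)
  new_cds_set(x$id[i], x$nt[i], x$pep[i])
}

#' Read a coding-sequence FASTA file
#'
#' Reads one in-frame CDS per FASTA entry, strips terminal stop codons,
#' derives the peptide and drops records that violate the CDS invariants
#' (ambiguous bases, length not a multiple of 3, internal stops, input
#' shorter than 9 nt). Skipped records are reported with a warning;
#' duplicate identifiers and files with no valid record are errors.
#'
#' @param path Path to a nucleotide FASTA file.
#' @return A `cds_set`: parallel vectors `id`, `nt` (stop-trimmed CDS) and
#'   `pep` (translation).
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  nts <- as.character(seqs)
  res <- lapply(nts, validate_cds)
  ok <- vapply(res, `[[`, logical(1), "ok")
  if (any(!ok)) {
    reasons <- vapply(res[!ok], `[[`, character(1), "reason")
    warning(sprintf("skipped %d of %d records failing CDS validation (%s)",
                    sum(!ok), length(ok),
                    paste(sprintf("%s: %d", names(table(reasons)), table(reasons)),
                          collapse = "; ")))
  }
  if (!any(ok)) stop("no valid CDS records in ", path)
  new_cds_set(ids[ok],
              vapply(res[ok], `[[`, character(1), "nt"),
              vapply(res[ok], `[[`, character(1), "pep"))
}

#' Write a coding-sequence set to FASTA
#'
#' @param cds A `cds_set`.
#' @param path Output file.
#' @param what `"nt"` for the nucleotide CDS, `"pep"` for the peptides.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path, what = c("nt", "pep")) {
  what <- match.arg(what)
  x <- if (what == "nt") Biostrings::DNAStringSet(setNames(cds$nt, cds$id))
       else Biostrings::AAStringSet(setNames(cds$pep, cds$id))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Writes a data frame tab-separated with a header row, numeric columns at
#' 6 significant digits and rows sorted by the leading columns, so that
#' re-running a pipeline stage produces a byte-identical file.
#'
#' @param records Data frame of results.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    warning("writing header-only TSV: no records")
  } else {
    ord <- do.call(order, unname(as.list(records)))
    records <- records[ord, , drop = FALSE]
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the thresholds used across the pipeline: the similarity-search
#' E-value cutoff (default 1e-10), the Ks saturation ceiling used to split
#' families into subfamilies (default 5), the reciprocal-best-hit ortholog
#' filters (at least 30 percent identity over at least 150 aligned amino
#' acids), the Markov-clustering inflation (default 2), affine gap
#' penalties for BLOSUM62 alignment (open 11, extend 1), the kernel
#' bandwidth for the age-distribution density, and the RNG seed from which
#' all stochastic stages draw.
#'
#' @param evalue_cutoff Maximum E-value for a similarity hit to be kept.
#' @param ks_max Subfamily Ks ceiling; pairwise estimates above it are
#'   treated as saturated when assembling the age distribution.
#' @param rbh_min_identity Minimum percent identity for a valid ortholog pair.
#' @param rbh_min_aln_len Minimum alignment length (amino acids, gap
#'   columns included) for a valid ortholog pair.
#' @param mcl_inflation Markov-clustering inflation parameter (> 1).
#' @param gap_open,gap_extend Affine gap penalties (positive integers).
#' @param kde_bandwidth Gaussian kernel bandwidth for [kde_density()], or
#'   `"auto"` for Silverman's rule on the weighted sample.
#' @param ks_method `"NG86"` (counting, default) or `"ML"` (codon-model
#'   maximum likelihood) for pairwise Ks estimation.
#' @param rng_seed Integer seed governing every stochastic stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(evalue_cutoff = 1e-10, ks_max = 5.0,
                            rbh_min_identity = 30, rbh_min_aln_len = 150,
                            mcl_inflation = 2.0, gap_open = 11L,
                            gap_extend = 1L, kde_bandwidth = "auto",
                            ks_method = c("NG86", "ML"), rng_seed = 1L) {
  ks_method <- match.arg(ks_method)
  cfg <- list(evalue_cutoff = evalue_cutoff, ks_max = ks_max,
              rbh_min_identity = rbh_min_identity,
              rbh_min_aln_len = rbh_min_aln_len,
              mcl_inflation = mcl_inflation,
              gap_open = as.integer(gap_open),
              gap_extend = as.integer(gap_extend),
              kde_bandwidth = kde_bandwidth,
              ks_method = ks_method,
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$evalue_cutoff > 0, cfg$ks_max > 0,
            cfg$rbh_min_identity > 0, cfg$rbh_min_identity <= 100,
            cfg$rbh_min_aln_len >= 1, cfg$mcl_inflation > 1,
            cfg$gap_open >= 0, cfg$gap_extend >= 1)
  if (!identical(cfg$kde_bandwidth, "auto")) {
    stopifnot(is.numeric(cfg$kde_bandwidth), cfg$kde_bandwidth > 0)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read or write a structured configuration file
#'
#' Configuration files are YAML with top-level sections `pipeline` and
#' (optionally) `simulation`, mirroring [pipeline_config()] and
#' [simulation_config()].
#'
#' @param path YAML file path.
#' @return `read_config()` returns `list(pipeline =, simulation =)`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list(pipeline = do.call(pipeline_config, raw$pipeline %||% list()))
  if (!is.null(raw$simulation)) {
    out$simulation <- do.call(simulation_config, raw$simulation)
  }
  out
}

#' @rdname read_config
#' @param pipeline A `pipeline_config`.
#' @param simulation Optional `simulation_config`.
#' @export
write_config <- function(path, pipeline = pipeline_config(), simulation = NULL) {
  x <- list(pipeline = unclass(pipeline))
  if (!is.null(simulation)) x$simulation <- unclass(simulation)
  yaml::write_yaml(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stage logging: timestamped messages, silenced via options(paranome.verbose)
pk_log <- function(fmt, ...) {
  if (isFALSE(getOption("paranome.verbose", TRUE))) return(invisible(NULL))
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}
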