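# Codon machinery shared by the simulator and the Ks estimators.
# Everything is derived from the standard genetic code as shipped with
# Biostrings; lookup tables are built lazily and cached per session.

.nucs <- c("A", "C", "G", "T")

.genetic_code <- function() {
  if (is.null(.paranome_cache$gc)) {
    gc <- Biostrings::GENETIC_CODE
    .paranome_cache$gc <- gc
    .paranome_cache$codons <- names(gc)
    .paranome_cache$sense <- names(gc)[gc != "*"]
  }
  .paranome_cache$gc
}

sense_codons <- function() {
  .genetic_code()
  .paranome_cache$sense
}

codon_aa <- function(codon) {
  unname(.genetic_code()[codon])
}

is_transition <- function(x, y) {
  (x %in% c("A", "G") & y %in% c("A", "G")) |
    (x %in% c("C", "T") & y %in% c("C", "T"))
}

# split an in-frame nucleotide string into codons
split_codons <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length is not a multiple of 3")
  substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# single-nucleotide neighbours of a codon (9 codons, may include stops)
codon_neighbours <- function(codon) {
  out <- character(0)
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (b in setdiff(.nucs, ref)) {
      x <- codon
      substr(x, pos, pos) <- b
      out <- c(out, x)
    }
  }
  out
}
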