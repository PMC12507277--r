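#' @import data.table
#' @importFrom stats rbinom runif setNames chisq.test pbinom dbinom
#' @importFrom utils head tail
NULL

# Standard genetic code (NCBI translation table 1; identical to the
# bacterial table 11 at the codon -> amino-acid level). A plain-text copy
# ships in inst/extdata/standard_genetic_code.tsv for cross-checking.
STANDARD_GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' The 20 standard amino-acid one-letter codes
#' @keywords internal
AA_ALPHABET <- sort(unique(unname(
  STANDARD_GENETIC_CODE[STANDARD_GENETIC_CODE != "*"]
)))

# amino acid -> character vector of its codons (stops excluded)
AA_CODONS <- split(
  names(STANDARD_GENETIC_CODE)[STANDARD_GENETIC_CODE != "*"],
  STANDARD_GENETIC_CODE[STANDARD_GENETIC_CODE != "*"]
)

#' Canonicalize a nucleotide sequence
#'
#' Upper-cases, maps U to T, and validates the alphabet `{A,C,G,T,N}`.
#'
#' @param seq Character scalar, nucleotide sequence.
#' @return Canonicalized sequence string.
#' @keywords internal
canonicalize_nt <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- chartr("U", "T", toupper(seq))
  bad <- regexpr("[^ACGTN]", s)
  if (bad != -1L) {
    stop(sprintf(
      "invalid nucleotide '%s' at position %d",
      substring(s, bad, bad), bad
    ), call. = FALSE)
  }
  s
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}` (case-insensitive,
#'   `U` accepted as `T`). `N` is its own complement.
#' @return The reverse-complemented string, upper case.
#' @examples
#' reverse_complement("ATGC") # "GCAT"
#' @export
reverse_complement <- function(seq) {
  s <- canonicalize_nt(seq)
  if (nchar(s) == 0L) return(s)
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Translate one reading frame of a nucleotide sequence
#'
#' Codons are read from `offset` (0-based) in steps of three under the
#' standard genetic code; 1-2 trailing nucleotides are dropped. Any codon
#' containing `N` translates to `'X'`; stop codons translate to `'*'`.
#'
#' @param seq Nucleotide string.
#' @param offset Integer 0, 1 or 2.
#' @return Amino-acid string, possibly containing `'*'` and `'X'`.
#' @examples
#' translate_frame("ATGGCC", 0) # "MA"
#' translate_frame("ATGTAA", 0) # "M*"
#' @export
translate_frame <- function(seq, offset = 0L) {
  stopifnot(length(offset) == 1L, offset %in% 0:2)
  s <- canonicalize_nt(seq)
  n_codons <- (nchar(s) - offset) %/% 3L
  if (n_codons <= 0L) return("")
  starts <- offset + 1L + 3L * (seq_len(n_codons) - 1L)
  aa <- STANDARD_GENETIC_CODE[substring(s, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"  # codons with N
  paste(aa, collapse = "")
}

#' Six-frame translation with stop-frame validity flags
#'
#' Produces the six amino-acid readings of a nucleotide sequence in the
#' fixed order (forward offsets 0,1,2; reverse-complement offsets 0,1,2).
#' A frame is valid iff its translation contains no stop codon; frames
#' containing a stop ("truncated" frames) are discarded downstream before
#' k-mer extraction. `'X'` residues (from `N` bases) do not invalidate a
#' frame, but k-mers containing them are never emitted.
#'
#' @param seq Nucleotide string.
#' @return A list of class `six_frames` with elements `frames` (character
#'   vector of 6 amino-acid strings) and `valid` (logical vector of 6).
#' @export
six_frame_translate <- function(seq) {
  s <- canonicalize_nt(seq)
  rc <- if (nchar(s) > 0L) reverse_complement(s) else s
  frames <- c(
    vapply(0:2, function(o) translate_frame(s, o), character(1)),
    vapply(0:2, function(o) translate_frame(rc, o), character(1))
  )
  structure(
    list(frames = frames, valid = !grepl("*", frames, fixed = TRUE)),
    class = "six_frames"
  )
}

#' Extract overlapping k-mers from an amino-acid string
#'
#' All length-`k` substrings at step 1, in order. Windows containing
#' `'X'` (masked residues) or `'*'` (stop) are excluded.
#'
#' @param seq Amino-acid string.
#' @param k Window length, `>= 1`.
#' @return Character vector of k-mers (possibly empty).
#' @examples
#' extract_kmers("MAAAAK", 5) # c("MAAAA", "AAAAK")
#' @export
extract_kmers <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1L)
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  kmers <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  kmers[!grepl("[X*]", kmers)]
}

# Vectorized k-mer extraction for many equal-or-varying-length sequences.
# Returns a data.table(idx, kmer) where idx indexes into `seqs`; windows
# containing X or * are dropped. Hot path for model building and scoring.
extract_kmers_dt <- function(seqs, k) {
  lens <- nchar(seqs)
  nwin <- pmax(lens - k + 1L, 0L)
  keep <- which(nwin > 0L)
  if (length(keep) == 0L) {
    return(data.table(idx = integer(0), kmer = character(0)))
  }
  seqs <- seqs[keep]
  nwin <- nwin[keep]
  maxw <- max(nwin)
  # position-major sweep: one vectorized substring() call per window start
  parts <- vector("list", maxw)
  for (j in seq_len(maxw)) {
    sel <- nwin >= j
    parts[[j]] <- data.table(
      idx = keep[sel],
      kmer = substring(seqs[sel], j, j + k - 1L)
    )
  }
  out <- rbindlist(parts)
  out <- out[!grepl("[X*]", kmer)]
  setorder(out, idx)
  out
}

#' Reverse translate an amino-acid sequence
#'
#' Maps each residue to one of its codons chosen uniformly at random
#' (standard genetic code; stop codons can never be produced). Unique-codon
#' residues (`M`, `W`) are deterministic.
#'
#' @param aa Amino-acid string over the 20 standard letters (no `'*'`,
#'   no `'X'`).
#' @param seed Optional integer; when given, the draw is a pure function
#'   of `(aa, seed)` and the caller's RNG state is left untouched.
#' @return Nucleotide string of length `3 * nchar(aa)`.
#' @examples
#' reverse_translate("MW") # "ATGTGG"
#' @export
reverse_translate <- function(aa, seed = NULL) {
  stopifnot(is.character(aa), length(aa) == 1L, !is.na(aa))
  if (nchar(aa) == 0L) return("")
  res <- strsplit(aa, "", fixed = TRUE)[[1L]]
  bad <- which(!res %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-standard amino acid '%s' at position %d", res[bad[1L]], bad[1L]
    ), call. = FALSE)
  }
  draw <- function() {
    codons <- AA_CODONS[res]
    nc <- lengths(codons)
    pick <- floor(runif(length(res)) * nc) + 1L
    paste(mapply(`[`, codons, pick, USE.NAMES = FALSE), collapse = "")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's
# .Random.seed afterwards so seeded helpers do not perturb global state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
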