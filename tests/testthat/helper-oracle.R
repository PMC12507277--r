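# Independent oracles. These deliberately avoid the package's own
# translation and model code paths: translation goes through Biostrings,
# k-mer counting through plain substring enumeration.

oracle_translate <- function(seq, offset = 0L) {
  s <- Biostrings::DNAString(chartr("Uu", "TT", toupper(seq)))
  n <- length(s) - offset
  n <- n - (n %% 3L)
  if (n <= 0L) return("")
  as.character(suppressWarnings(Biostrings::translate(
    Biostrings::subseq(s, offset + 1L, offset + n),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  )))
}

oracle_six_frames <- function(seq) {
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
  fr <- c(
    vapply(0:2, function(o) oracle_translate(seq, o), character(1)),
    vapply(0:2, function(o) oracle_translate(rc, o), character(1))
  )
  list(frames = fr, valid = !grepl("*", fr, fixed = TRUE))
}

# all overlapping windows of length k (no exclusions)
oracle_windows <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  substring(seq, seq_len(n), seq_len(n) + k - 1L)
}

# brute-force score of a read against every cluster of a raw database:
# re-translate, re-extract, count occurrences by window enumeration,
# divide by cluster size, sum over k-mer occurrences of the read.
oracle_score_read <- function(read, db, k) {
  sf <- oracle_six_frames(read)
  kmers <- unlist(lapply(sf$frames[sf$valid], function(f) {
    w <- oracle_windows(f, k)
    w[!grepl("[X*]", w)]
  }), use.names = FALSE)
  p2c <- protein_to_cluster(db)
  sizes <- cluster_sizes(db)
  scores <- setNames(numeric(length(sizes)), names(sizes))
  if (length(kmers) == 0L) return(scores[scores > 0])
  occ <- table(kmers)
  for (pid in names(db$seqs)) {
    wins <- table(oracle_windows(db$seqs[[pid]], k))
    cid <- p2c[[pid]]
    shared <- intersect(names(occ), names(wins))
    if (length(shared) > 0L) {
      scores[[cid]] <- scores[[cid]] +
        sum(as.numeric(occ[shared]) * as.numeric(wins[shared])) /
          unname(sizes[[cid]])
    }
  }
  scores[scores > 0]
}

# total occurrence count of every k-mer over all proteins of a database
# (pure window enumeration; includes no model code)
oracle_total_counts <- function(db, k) {
  wins <- unlist(lapply(unname(db$seqs), oracle_windows, k = k),
                 use.names = FALSE)
  tab <- table(wins)
  setNames(as.integer(tab), names(tab))
}

# all-pairs AUROC with half-credit ties
oracle_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}
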