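# Fixtures are built in code at test time; helpers here are shared across
# test files. RNG use is always wrapped in withr::local_seed-style blocks
# via explicit seeds so files are order-independent.

AA20 <- clustkmer:::AA_ALPHABET

random_aa <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

random_nt <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Build a cluster_db from a named list cluster_id -> character vector of
# sequences; first member of each cluster is the representative.
make_db <- function(clusters, annotations = NULL) {
  seqs <- character(0)
  memb <- list()
  for (cid in names(clusters)) {
    pids <- sprintf("%s_p%d", cid, seq_along(clusters[[cid]]))
    seqs[pids] <- clusters[[cid]]
    ann <- if (is.null(annotations)) paste(cid, "representative")
           else annotations[[cid]]
    memb[[cid]] <- data.frame(
      cluster_id = cid, protein_id = pids,
      is_representative = seq_along(pids) == 1L,
      annotation = ann
    )
  }
  cluster_db(seqs, do.call(rbind, memb))
}

# 20 clusters x 5 proteins of 100 aa at 80% intra-cluster identity --
# the oracle-equivalence fixture.
fixture_sim20 <- function(seed = 101L) {
  generate_cluster_db(synthetic_db_spec(
    n_clusters = 20L, proteins_per_cluster = 5L, protein_length = 100L,
    intra_cluster_identity = 0.8, seed = seed
  ))
}

# Clusters drawn over pairwise-disjoint residue alphabets: every k-mer
# (k <= 5) of a cluster is guaranteed absent from all other clusters.
disjoint_alphabet_db <- function(n_clusters = 4L, proteins_per_cluster = 3L,
                                 protein_length = 60L, seed = 11L) {
  stopifnot(n_clusters * 5L <= 20L)
  withr::with_seed(seed, {
    clusters <- list()
    for (ci in seq_len(n_clusters)) {
      alpha <- AA20[(5L * (ci - 1L) + 1L):(5L * ci)]
      clusters[[sprintf("D%02d", ci)]] <- vapply(
        seq_len(proteins_per_cluster),
        function(i) paste(sample(alpha, protein_length, replace = TRUE),
                          collapse = ""),
        character(1)
      )
    }
    make_db(clusters)
  })
}

# CDS for every protein of a cluster_db, deterministic given seed.
db_cds <- function(db, seed = 5L) {
  withr::with_seed(seed, {
    vapply(db$seqs, function(aa) reverse_translate(aa), character(1))
  })
}
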