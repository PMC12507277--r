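# Synthetic clustered databases and truth-labeled reads.
#
# Every generator is a pure function of its inputs and seed, and leaves
# the caller's RNG state untouched. The database generator emulates the
# statistical structure the classifier assumes: clusters of homologous
# proteins whose members diverge from a common ancestor by independent
# residue substitution, with independent ancestors across clusters so
# inter-cluster identity sits at the ~1/20 background.

#' Specification for a synthetic clustered protein database
#'
#' Defaults describe the standard evaluation fixture: 50 clusters of 20
#' proteins, 300 residues each, 80% intra-cluster identity.
#'
#' @param n_clusters Number of clusters.
#' @param proteins_per_cluster Members per cluster.
#' @param protein_length Residues per protein.
#' @param intra_cluster_identity Expected member-to-ancestor identity in
#'   (0, 1]; each residue is independently substituted (to a uniformly
#'   chosen different amino acid) with probability `1 - identity`.
#' @param seed Integer seed; same seed, same database.
#' @return An object of class `synthetic_db_spec`.
#' @export
synthetic_db_spec <- function(n_clusters = 50L, proteins_per_cluster = 20L,
                              protein_length = 300L,
                              intra_cluster_identity = 0.8, seed = 1L) {
  stopifnot(n_clusters >= 1L, proteins_per_cluster >= 1L,
            protein_length >= 1L,
            intra_cluster_identity > 0, intra_cluster_identity <= 1)
  structure(
    list(n_clusters = as.integer(n_clusters),
         proteins_per_cluster = as.integer(proteins_per_cluster),
         protein_length = as.integer(protein_length),
         intra_cluster_identity = intra_cluster_identity,
         seed = as.integer(seed)),
    class = "synthetic_db_spec"
  )
}

# substitute each position of `res` (character vector of residues /
# bases) with probability p, drawing uniformly among the other letters
mutate_letters <- function(res, p, alphabet) {
  hit <- which(runif(length(res)) < p)
  if (length(hit) > 0L) {
    cur <- res[hit]
    pick <- vapply(cur, function(x) {
      others <- alphabet[alphabet != x]
      others[[floor(runif(1L) * length(others)) + 1L]]
    }, character(1), USE.NAMES = FALSE)
    res[hit] <- pick
  }
  res
}

#' Generate a synthetic clustered protein database
#'
#' Each cluster is founded by a uniformly random amino-acid ancestor;
#' members are independent resubstitutions of the ancestor at rate
#' `1 - intra_cluster_identity`. A nucleotide coding sequence is attached
#' to every protein by stop-avoiding reverse translation. The first
#' member of each cluster is its representative; annotations carry a
#' cluster-specific family keyword so keyword-homogeneity statistics are
#' exercised.
#'
#' @param spec A [synthetic_db_spec()].
#' @return A list of class `synthetic_db`: `db` (a [cluster_db()]),
#'   `cds` (named character vector protein id -> nucleotide CDS), and
#'   `protein_to_cluster` (named character vector).
#' @export
generate_cluster_db <- function(spec) {
  stopifnot(inherits(spec, "synthetic_db_spec"))
  with_seed(spec$seed, {
    p_sub <- 1 - spec$intra_cluster_identity
    ids <- character(0)
    seqs <- character(0)
    cds <- character(0)
    membership <- vector("list", spec$n_clusters)
    for (ci in seq_len(spec$n_clusters)) {
      cid <- sprintf("C%04d", ci)
      ancestor <- AA_ALPHABET[
        floor(runif(spec$protein_length) * 20L) + 1L]
      pids <- sprintf("%s_P%03d", cid, seq_len(spec$proteins_per_cluster))
      for (pi in seq_len(spec$proteins_per_cluster)) {
        member <- mutate_letters(ancestor, p_sub, AA_ALPHABET)
        aa <- paste(member, collapse = "")
        seqs[[pids[pi]]] <- aa
        cds[[pids[pi]]] <- reverse_translate(aa)
      }
      membership[[ci]] <- data.table(
        cluster_id = cid,
        protein_id = pids,
        is_representative = seq_along(pids) == 1L,
        annotation = sprintf("family%04d domain protein", ci)
      )
    }
    db <- cluster_db(seqs, rbindlist(membership))
    structure(
      list(db = db, cds = cds, protein_to_cluster = protein_to_cluster(db)),
      class = "synthetic_db"
    )
  })
}

#' Simulate reads with a binomial per-base mutation rate
#'
#' For each read: a source CDS is chosen uniformly; the number of
#' mutations `m` is drawn from `Binomial(L, rate)` over the full source of
#' length `L`; `m` positions are chosen uniformly without replacement and
#' each is substituted with a uniformly random different base; finally a
#' window of `read_length` is cut at a uniform start `x` with
#' `x + read_length - 1 <= L`. Mutation happens before windowing, so
#' `n_mutations` counts mutations over the whole source, of which only
#' those inside the window affect the read.
#'
#' @param cds Named character vector, protein id -> nucleotide CDS.
#' @param p2c Named character vector, protein id -> cluster id.
#' @param rate Per-base mutation probability in `[0, 1]`.
#' @param read_length Read length `l` in nucleotides.
#' @param n_reads Number of reads to draw.
#' @param seed Integer seed.
#' @return data.table with columns `read_id`, `seq`, `true_cluster`,
#'   `true_protein`, `n_mutations`, `mutation_kind` ("rate"), `start`,
#'   `length`. Sources shorter than `read_length` are skipped; the number
#'   skipped is attached as attribute `n_skipped_sources` (with a warning
#'   when positive).
#' @export
simulate_reads_rate <- function(cds, p2c, rate, read_length, n_reads,
                                seed = 1L) {
  stopifnot(rate >= 0, rate <= 1, read_length >= 1L, n_reads >= 0L)
  read_length <- as.integer(read_length)
  lens <- nchar(cds)
  usable <- names(cds)[lens >= read_length]
  n_skipped <- length(cds) - length(usable)
  if (n_skipped > 0L) {
    warning(sprintf("%d source(s) shorter than read length skipped",
                    n_skipped), call. = FALSE)
  }
  if (length(usable) == 0L) stop("no usable source sequence", call. = FALSE)
  out <- with_seed(seed, {
    src <- usable[floor(runif(n_reads) * length(usable)) + 1L]
    rows <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      s <- cds[[src[i]]]
      L <- nchar(s)
      m <- rbinom(1L, L, rate)
      if (m > 0L) {
        res <- strsplit(s, "", fixed = TRUE)[[1L]]
        pos <- sample.int(L, m)
        res[pos] <- vapply(res[pos], function(x) {
          others <- c("A", "C", "G", "T")[c("A", "C", "G", "T") != x]
          others[[floor(runif(1L) * 3L) + 1L]]
        }, character(1), USE.NAMES = FALSE)
        s <- paste(res, collapse = "")
      }
      x <- floor(runif(1L) * (L - read_length + 1L)) + 1L
      rows[[i]] <- data.table(
        read_id = sprintf("simr%06d", i),
        seq = substring(s, x, x + read_length - 1L),
        true_cluster = unname(p2c[[src[i]]]),
        true_protein = src[i],
        n_mutations = m,
        mutation_kind = "rate",
        start = x,
        length = read_length
      )
    }
    rbindlist(rows)
  })
  setattr(out, "n_skipped_sources", n_skipped)
  out
}

#' Simulate reads with a guaranteed number of amino-acid changes
#'
#' Cuts a frame-aligned window of `read_length` nucleotides from a source
#' CDS (so frame 0 of the read is coding), then replaces the codons at
#' `m` distinct residue positions, each with a uniformly chosen codon of
#' a uniformly chosen *different* amino acid. By construction the
#' translated mutated window differs from the original translation at
#' exactly `m` residues.
#'
#' @inheritParams simulate_reads_rate
#' @param m Number of guaranteed amino-acid changes (typically 1-4).
#' @return data.table as in [simulate_reads_rate()] with
#'   `mutation_kind = "fixed_aa"` and `n_mutations = m`.
#' @export
simulate_reads_fixed_aa <- function(cds, p2c, m, read_length, n_reads,
                                    seed = 1L) {
  stopifnot(m >= 1L, n_reads >= 0L)
  read_length <- as.integer(read_length)
  m <- as.integer(m)
  n_codons <- read_length %/% 3L
  if (n_codons < m) {
    stop(sprintf("read length %d holds %d codons; cannot place %d changes",
                 read_length, n_codons, m), call. = FALSE)
  }
  lens <- nchar(cds)
  usable <- names(cds)[lens >= read_length]
  if (length(usable) == 0L) stop("no usable source sequence", call. = FALSE)
  out <- with_seed(seed, {
    src <- usable[floor(runif(n_reads) * length(usable)) + 1L]
    rows <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      s <- cds[[src[i]]]
      L <- nchar(s)
      starts <- seq(1L, L - read_length + 1L, by = 3L)  # frame-aligned
      x <- starts[[floor(runif(1L) * length(starts)) + 1L]]
      window <- substring(s, x, x + read_length - 1L)
      aa <- translate_frame(window, 0L)
      res <- strsplit(aa, "", fixed = TRUE)[[1L]]
      pos <- sample.int(n_codons, m)
      for (p in pos) {
        old_aa <- res[[p]]
        others <- AA_ALPHABET[AA_ALPHABET != old_aa]
        new_aa <- others[[floor(runif(1L) * length(others)) + 1L]]
        codons <- AA_CODONS[[new_aa]]
        new_codon <- codons[[floor(runif(1L) * length(codons)) + 1L]]
        substr(window, 3L * p - 2L, 3L * p) <- new_codon
      }
      rows[[i]] <- data.table(
        read_id = sprintf("simf%06d", i),
        seq = window,
        true_cluster = unname(p2c[[src[i]]]),
        true_protein = src[i],
        n_mutations = m,
        mutation_kind = "fixed_aa",
        start = x,
        length = read_length
      )
    }
    rbindlist(rows)
  })
  out
}

#' Segment unseen proteins into reverse-translated nucleotide reads
#'
#' Emulates evaluating the classifier on proteins absent from the model:
#' each protein is reverse translated (random synonymous codons, no
#' stops) and one random substring per (protein, length, seed)
#' combination is cut.
#'
#' @param proteins Named character vector of amino-acid sequences
#'   (standard alphabet).
#' @param lengths Integer vector of substring lengths in nucleotides
#'   (default `c(125, 150, 200)`).
#' @param seeds Integer vector of seeds (default `1:10`); reverse
#'   translation and cut position are redrawn per seed.
#' @return data.table with `read_id`, `seq`, `true_protein`, `length`,
#'   `seed`, `start`. Proteins too short for a requested length are
#'   skipped; counts attached as attribute `n_skipped`.
#' @export
segment_unseen_proteins <- function(proteins, lengths = c(125L, 150L, 200L),
                                    seeds = 1:10) {
  stopifnot(is.character(proteins), !is.null(names(proteins)),
            all(lengths >= 1L))
  rows <- list()
  n_skipped <- 0L
  for (sd in seeds) {
    chunk <- with_seed(sd, {
      sub_rows <- list()
      for (pid in names(proteins)) {
        nt <- reverse_translate(proteins[[pid]])
        L <- nchar(nt)
        for (len in lengths) {
          if (L < len) {
            n_skipped <- n_skipped + 1L
            next
          }
          x <- floor(runif(1L) * (L - len + 1L)) + 1L
          sub_rows[[length(sub_rows) + 1L]] <- data.table(
            read_id = sprintf("%s_len%d_seed%d", pid, len, sd),
            seq = substring(nt, x, x + len - 1L),
            true_protein = pid,
            length = as.integer(len),
            seed = as.integer(sd),
            start = x
          )
        }
      }
      rbindlist(sub_rows)
    })
    rows[[length(rows) + 1L]] <- chunk
  }
  out <- rbindlist(rows)
  setattr(out, "n_skipped", n_skipped)
  out
}

#' Write simulated reads as FASTA plus a truth sidecar TSV
#'
#' @param reads A data.table from one of the read simulators.
#' @param fasta_path Output FASTA of read sequences.
#' @param truth_path Output TSV
#'   `read_id  true_cluster  true_protein  n_mutations  start  length`.
#' @return Invisibly, `fasta_path`.
#' @export
write_simulated_reads <- function(reads, fasta_path, truth_path) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  write_fasta(setNames(reads$seq, reads$read_id), fasta_path)
  cols <- intersect(
    c("read_id", "true_cluster", "true_protein", "n_mutations",
      "start", "length"),
    names(reads)
  )
  fwrite(as.data.table(reads)[, cols, with = FALSE], truth_path,
         sep = "\t", quote = FALSE)
  invisible(fasta_path)
}
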