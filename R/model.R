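# The k-mer frequency cluster model.
#
# The model is conceptually a nested map: k-mer w -> (cluster C ->
# frequency of w in C), where the frequency is the total occurrence count
# of w across all proteins of C divided by the number of proteins in C
# (so it can exceed 1 for motifs repeated within proteins). Internally the
# map is a keyed data.table of integer counts with cluster sizes held
# separately; frequencies are formed by division on demand, which keeps
# the representation exact and serialization bit-stable.

MODEL_MAGIC <- "clustkmer-model"
MODEL_FORMAT_VERSION <- 1L

#' Build a k-mer frequency cluster model
#'
#' For every k-mer `w` occurring in any protein of cluster `C`, stores
#' `frequency_C(w) = count(w in C) / |C|`, where the count includes
#' multiple occurrences within a protein and `|C|` is the number of
#' proteins in the cluster. Absent pairs have frequency 0 by contract and
#' are not stored. Proteins shorter than `k` contribute nothing.
#'
#' @param db A [cluster_db()].
#' @param k k-mer length in amino acids (default 5).
#' @return An object of class `kmer_model` with fields `k`, `table` (a
#'   keyed data.table `kmer, cluster_id, count`), `cluster_size`, and
#'   `annotations`.
#' @export
build_model <- function(db, k = 5L) {
  stopifnot(inherits(db, "cluster_db"), k >= 1L)
  k <- as.integer(k)
  if (length(db$seqs) == 0L) stop("empty database", call. = FALSE)
  p2c <- protein_to_cluster(db)
  km <- extract_kmers_dt(unname(db$seqs), k)
  km[, cluster_id := unname(p2c[names(db$seqs)])[idx]]
  tab <- km[, .(count = .N), by = .(kmer, cluster_id)]
  setkey(tab, kmer, cluster_id)
  new_kmer_model(k, tab, cluster_sizes(db), cluster_annotations(db))
}

new_kmer_model <- function(k, table, cluster_size, annotations) {
  stopifnot(all(c("kmer", "cluster_id", "count") %in% names(table)))
  structure(
    list(k = as.integer(k), table = table,
         cluster_size = cluster_size, annotations = annotations),
    class = "kmer_model"
  )
}

#' @export
print.kmer_model <- function(x, ...) {
  cat(sprintf(
    "<kmer_model> k=%d  %d distinct k-mers  %d clusters  %d entries\n",
    x$k, n_distinct_kmers(x), length(x$cluster_size), nrow(x$table)
  ))
  invisible(x)
}

#' Number of distinct k-mers in a model
#' @param model A `kmer_model`.
#' @return Integer count of distinct k-mer keys.
#' @export
n_distinct_kmers <- function(model) {
  stopifnot(inherits(model, "kmer_model"))
  uniqueN(model$table$kmer)
}

#' Query a single model frequency
#'
#' @param model A `kmer_model`.
#' @param kmer k-mer string of length `model$k`.
#' @param cluster Cluster id.
#' @return `frequency_C(w)`; 0 when the pair is absent.
#' @export
model_frequency <- function(model, kmer, cluster) {
  stopifnot(inherits(model, "kmer_model"))
  key <- data.table(kmer = kmer, cluster_id = cluster)
  row <- model$table[key, on = c("kmer", "cluster_id"), nomatch = NULL]
  if (nrow(row) == 0L) return(0)
  row$count / unname(model$cluster_size[[cluster]])
}

#' Save a k-mer model to a versioned text container
#'
#' The format is line-oriented and self-describing: a magic/version header
#' carrying `k` and record counts (so truncation is detectable), one
#' `C<TAB>id<TAB>size<TAB>annotation` line per cluster, and one
#' `K<TAB>kmer<TAB>cluster<TAB>count` line per stored entry, sorted by
#' (kmer, cluster). Counts are integers, so [load_model()] reproduces the
#' model exactly, including frequencies greater than 1.
#'
#' @param model A `kmer_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "kmer_model"))
  con <- file(path, "wt")
  on.exit(close(con))
  tab <- copy(model$table)
  setkey(tab, kmer, cluster_id)
  writeLines(sprintf("#%s\tversion=%d\tk=%d\tn_clusters=%d\tn_records=%d",
                     MODEL_MAGIC, MODEL_FORMAT_VERSION, model$k,
                     length(model$cluster_size), nrow(tab)), con)
  cl <- names(model$cluster_size)
  writeLines(sprintf("C\t%s\t%d\t%s", cl,
                     unname(model$cluster_size[cl]),
                     unname(model$annotations[cl])), con)
  writeLines(sprintf("K\t%s\t%s\t%d", tab$kmer, tab$cluster_id, tab$count),
             con)
  invisible(path)
}

#' Load a k-mer model saved by [save_model()]
#'
#' @param path Path to a model file.
#' @return A `kmer_model`; identical key sets and bit-identical
#'   frequencies to the saved model.
#' @export
load_model <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], paste0("#", MODEL_MAGIC))) {
    stop("not a clustkmer model file (bad magic)", call. = FALSE)
  }
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  hdr <- setNames(
    sub("^[^=]*=", "", hdr),
    sub("=.*$", "", hdr)
  )
  if (as.integer(hdr[["version"]]) != MODEL_FORMAT_VERSION) {
    stop(sprintf("unsupported model format version %s", hdr[["version"]]),
         call. = FALSE)
  }
  k <- as.integer(hdr[["k"]])
  n_clusters <- as.integer(hdr[["n_clusters"]])
  n_records <- as.integer(hdr[["n_records"]])
  if (length(lines) != 1L + n_clusters + n_records) {
    stop("truncated or corrupt model file", call. = FALSE)
  }
  cl_lines <- lines[1L + seq_len(n_clusters)]
  k_lines <- lines[1L + n_clusters + seq_len(n_records)]
  if (any(!startsWith(cl_lines, "C\t")) ||
      (n_records > 0L && any(!startsWith(k_lines, "K\t")))) {
    stop("truncated or corrupt model file", call. = FALSE)
  }
  # fread keeps trailing empty fields (empty annotations) intact
  cl <- fread(text = cl_lines, sep = "\t", header = FALSE, quote = "",
              colClasses = list(character = c(1L, 2L, 4L), integer = 3L))
  if (ncol(cl) != 4L) stop("truncated or corrupt model file", call. = FALSE)
  cluster_size <- setNames(cl[[3L]], cl[[2L]])
  annotations <- setNames(cl[[4L]], cl[[2L]])
  if (n_records > 0L) {
    kk <- tstrsplit(k_lines, "\t", fixed = TRUE)
    tab <- data.table(kmer = kk[[2L]], cluster_id = kk[[3L]],
                      count = as.integer(kk[[4L]]))
  } else {
    tab <- data.table(kmer = character(0), cluster_id = character(0),
                      count = integer(0))
  }
  if (nrow(tab) > 0L && any(nchar(tab$kmer) != k)) {
    stop("truncated or corrupt model file", call. = FALSE)
  }
  setkey(tab, kmer, cluster_id)
  new_kmer_model(k, tab, cluster_size, annotations)
}

#' Export model entries as a debugging TSV
#'
#' @param model A `kmer_model`.
#' @param path Output path for a `kmer  cluster_id  count` TSV.
#' @return Invisibly, `path`.
#' @export
export_model_tsv <- function(model, path) {
  stopifnot(inherits(model, "kmer_model"))
  tab <- copy(model$table)
  setkey(tab, kmer, cluster_id)
  fwrite(tab, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Select k by the protein-truncation protocol
#'
#' For each candidate k, builds the model and classifies simulated
#' truncations of every database protein: `segments_per_protein` evenly
#' spaced overlapping amino-acid segments of `segment_length` residues,
#' scored directly at the amino-acid level (no translation) and assigned
#' to the arg-max cluster (lexicographic tie-break). Accuracy is the
#' fraction of segments assigned to their protein's true cluster. The
#' distinct k-mer count is reported so the accuracy/model-size trade-off
#' is visible; in practice accuracy saturates while the k-mer count keeps
#' growing sharply with k.
#'
#' @param db A [cluster_db()].
#' @param candidates Integer vector of k values to evaluate (default 3:6).
#' @param segments_per_protein Number of truncation segments per protein
#'   (default 50).
#' @param segment_length Segment length in amino acids (default 50,
#'   the residue span of a 150-nt read).
#' @return A data.frame with one row per candidate: `k`, `accuracy`,
#'   `n_kmers`, `n_segments`, `n_skipped` (proteins shorter than
#'   `segment_length`).
#' @export
select_k <- function(db, candidates = 3:6, segments_per_protein = 50L,
                     segment_length = 50L) {
  stopifnot(inherits(db, "cluster_db"), all(candidates >= 1L),
            segments_per_protein >= 1L, segment_length >= 1L)
  p2c <- protein_to_cluster(db)
  lens <- nchar(db$seqs)
  usable <- lens >= segment_length
  n_skipped <- sum(!usable)
  if (n_skipped > 0L) {
    message(sprintf("select_k: skipped %d protein(s) shorter than %d aa",
                    n_skipped, segment_length))
  }
  if (!any(usable)) stop("no protein long enough to segment", call. = FALSE)
  seqs <- db$seqs[usable]
  segs <- character(0)
  seg_cluster <- character(0)
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[[i]])
    starts <- unique(round(seq(1L, L - segment_length + 1L,
                               length.out = segments_per_protein)))
    segs <- c(segs, substring(seqs[[i]], starts,
                              starts + segment_length - 1L))
    seg_cluster <- c(seg_cluster,
                     rep(unname(p2c[[names(seqs)[i]]]), length(starts)))
  }
  res <- lapply(as.integer(candidates), function(k) {
    model <- build_model(db, k)
    best <- score_aa_batch(segs, model)
    correct <- !is.na(best$cluster_id) & best$cluster_id == seg_cluster
    data.frame(k = k, accuracy = mean(correct),
               n_kmers = n_distinct_kmers(model),
               n_segments = length(segs), n_skipped = n_skipped)
  })
  do.call(rbind, res)
}

# Arg-max cluster per amino-acid sequence, by direct k-mer scoring.
# Returns data.table(cluster_id, score) aligned with `seqs`; NA cluster
# when no k-mer of the sequence is in the model.
score_aa_batch <- function(seqs, model) {
  km <- extract_kmers_dt(seqs, model$k)
  out <- data.table(idx = seq_along(seqs))
  if (nrow(km) == 0L) {
    out[, `:=`(cluster_id = NA_character_, score = 0)]
    return(out)
  }
  hits <- model$table[km, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) {
    out[, `:=`(cluster_id = NA_character_, score = 0)]
    return(out)
  }
  hits[, freq := count / unname(model$cluster_size[cluster_id])]
  sc <- hits[, .(score = sum(freq)), by = .(idx, cluster_id)]
  setorder(sc, idx, -score, cluster_id)  # lexicographic tie-break
  best <- unique(sc, by = "idx")
  out <- merge(out, best, by = "idx", all.x = TRUE)
  out[is.na(score), score := 0]
  setorder(out, idx)
  out
}
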