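# Read -> cluster assignment.
#
# A read is six-frame translated; frames containing a stop codon are
# discarded; all overlapping amino-acid k-mers of the remaining frames are
# pooled (with multiplicity) and each occurrence adds its model frequency
# to every cluster containing it. The read is assigned to the cluster with
# the global maximum cumulative score, provided that score exceeds the
# threshold (strictly; default 3, tuned to short reads). Ties are broken
# by the lexicographically smallest cluster id so output is reproducible.

#' Score a read against every cluster
#'
#' @param read Nucleotide string (or a length-1 named character vector).
#' @param model A `kmer_model`.
#' @param distinct_kmers If `TRUE`, each distinct k-mer of the pooled
#'   frames contributes once regardless of multiplicity. Default `FALSE`:
#'   every occurrence contributes.
#' @return Named numeric vector, cluster id -> score, containing only
#'   clusters with a positive score (absent means 0). Empty when the read
#'   has no valid frame or no in-model k-mer.
#' @export
score_read <- function(read, model, distinct_kmers = FALSE) {
  stopifnot(inherits(model, "kmer_model"))
  sf <- six_frame_translate(read)
  kmers <- unlist(lapply(sf$frames[sf$valid], extract_kmers, k = model$k),
                  use.names = FALSE)
  if (distinct_kmers) kmers <- unique(kmers)
  if (length(kmers) == 0L) return(setNames(numeric(0), character(0)))
  hits <- model$table[data.table(kmer = kmers), on = "kmer",
                      nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(setNames(numeric(0), character(0)))
  hits[, freq := count / unname(model$cluster_size[cluster_id])]
  sc <- hits[, .(score = sum(freq)), by = cluster_id]
  setorder(sc, cluster_id)
  setNames(sc$score, sc$cluster_id)
}

#' Assign a read to a single cluster
#'
#' @inheritParams score_read
#' @param threshold Classification threshold; the read is classified only
#'   if the maximum score is strictly greater than it (default 3).
#' @param read_id Identifier carried into the result.
#' @return One-row data.frame with columns `read_id`, `cluster_id` (NA if
#'   unclassified), `score` (maximum score; 0 when nothing matched),
#'   `classified`, `n_kmers_scored` (k-mer occurrences pooled from valid
#'   frames), `annotation` (cluster representative name, "" if
#'   unclassified).
#' @export
assign_read <- function(read, model, threshold = 3, read_id = "read",
                        distinct_kmers = FALSE) {
  stopifnot(threshold >= 0)
  sf <- six_frame_translate(read)
  kmers <- unlist(lapply(sf$frames[sf$valid], extract_kmers, k = model$k),
                  use.names = FALSE)
  if (distinct_kmers) kmers <- unique(kmers)
  scores <- score_read(read, model, distinct_kmers = distinct_kmers)
  finish_assignment(read_id, scores, length(kmers), model, threshold)
}

finish_assignment <- function(read_id, scores, n_kmers, model, threshold) {
  if (length(scores) == 0L) {
    return(data.frame(
      read_id = read_id, cluster_id = NA_character_, score = 0,
      classified = FALSE, n_kmers_scored = n_kmers, annotation = "",
      stringsAsFactors = FALSE
    ))
  }
  ord <- order(-scores, names(scores))
  best <- names(scores)[ord[1L]]
  best_score <- unname(scores[[best]])
  classified <- best_score > threshold
  data.frame(
    read_id = read_id,
    cluster_id = if (classified) best else NA_character_,
    score = best_score,
    classified = classified,
    n_kmers_scored = n_kmers,
    annotation = if (classified) unname(model$annotations[[best]]) else "",
    stringsAsFactors = FALSE
  )
}

#' Classify a batch of reads held in memory
#'
#' Vectorized equivalent of calling [assign_read()] on each element;
#' classification of a read never depends on the other reads in the batch.
#'
#' @param reads Named character vector of nucleotide sequences.
#' @param model A `kmer_model`.
#' @inheritParams assign_read
#' @return data.table with one row per read, in input order, with the
#'   columns of [assign_read()].
#' @export
classify_reads <- function(reads, model, threshold = 3,
                           distinct_kmers = FALSE) {
  stopifnot(inherits(model, "kmer_model"), threshold >= 0)
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read%06d", seq_along(reads))
  }
  out <- data.table(read_id = names(reads))
  if (length(reads) == 0L) {
    return(out[, `:=`(cluster_id = character(0), score = numeric(0),
                      classified = logical(0), n_kmers_scored = integer(0),
                      annotation = character(0))][])
  }
  # pooled valid-frame translations per read
  frame_tabs <- lapply(seq_along(reads), function(i) {
    sf <- six_frame_translate(reads[[i]])
    fr <- sf$frames[sf$valid]
    if (length(fr) == 0L) return(NULL)
    data.table(idx = i, frame = fr)
  })
  frames <- rbindlist(frame_tabs)
  n_kmers <- integer(length(reads))
  sc <- NULL
  if (nrow(frames) > 0L) {
    km <- extract_kmers_dt(frames$frame, model$k)
    if (nrow(km) > 0L) {
      km[, idx := frames$idx[idx]]
      if (distinct_kmers) km <- unique(km, by = c("idx", "kmer"))
      cnt <- km[, .N, by = idx]
      n_kmers[cnt$idx] <- cnt$N
      hits <- model$table[km, on = "kmer", nomatch = NULL,
                          allow.cartesian = TRUE]
      if (nrow(hits) > 0L) {
        hits[, freq := count / unname(model$cluster_size[cluster_id])]
        sc <- hits[, .(score = sum(freq)), by = .(idx, cluster_id)]
      }
    }
  }
  if (is.null(sc) || nrow(sc) == 0L) {
    out[, `:=`(cluster_id = NA_character_, score = 0, classified = FALSE,
               n_kmers_scored = n_kmers, annotation = "")]
    return(out[])
  }
  setorder(sc, idx, -score, cluster_id)
  best <- unique(sc, by = "idx")
  full <- data.table(idx = seq_along(reads))
  best <- best[full, on = "idx"]
  setorder(best, idx)
  best[is.na(score), score := 0]
  best[, classified := score > threshold]
  out[, `:=`(
    cluster_id = fifelse(best$classified, best$cluster_id, NA_character_),
    score = best$score,
    classified = best$classified,
    n_kmers_scored = n_kmers,
    annotation = fifelse(best$classified,
                         unname(model$annotations[best$cluster_id]), "")
  )]
  out[]
}

#' Stream-classify a FASTA/FASTQ file
#'
#' Single pass over the input in bounded chunks: memory is governed by the
#' loaded model and the chunk size, not by the input file. Writes one TSV
#' row per input read, in input order, with header
#' `read_id  cluster_id  score  classified  annotation`, and returns (and
#' optionally writes) a run summary. Deterministic: re-running on the
#' same model and input is byte-identical.
#'
#' @param input Path to a FASTA or FASTQ file (`.gz` transparent; format
#'   sniffed from the first record).
#' @param model A `kmer_model` (or a path to a saved model).
#' @param output Path for the per-read TSV.
#' @inheritParams assign_read
#' @param summary_json Optional path; when given, the summary is written
#'   there as JSON.
#' @param chunk_size Records scored per chunk (default 5000).
#' @return Invisibly, a list `n_input`, `n_classified`, `coverage`.
#' @export
classify_stream <- function(input, model, output, threshold = 3,
                            distinct_kmers = FALSE, summary_json = NULL,
                            chunk_size = 5000L) {
  if (is.character(model)) model <- load_model(model)
  stopifnot(inherits(model, "kmer_model"))
  h <- fastx_open(input)
  on.exit(fastx_close(h))
  con <- file(output, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("read_id", "cluster_id", "score", "classified",
                     "annotation"), collapse = "\t"), con)
  n_input <- 0L
  n_classified <- 0L
  repeat {
    chunk <- fastx_read_chunk(h, chunk_size)
    if (is.null(chunk)) break
    res <- classify_reads(setNames(chunk$seq, chunk$id), model,
                          threshold = threshold,
                          distinct_kmers = distinct_kmers)
    n_input <- n_input + nrow(res)
    n_classified <- n_classified + sum(res$classified)
    writeLines(sprintf(
      "%s\t%s\t%s\t%s\t%s",
      res$read_id,
      fifelse(res$classified, res$cluster_id, "NA"),
      formatC(res$score, format = "g", digits = 12),
      ifelse(res$classified, "TRUE", "FALSE"),
      res$annotation
    ), con)
  }
  summary <- list(
    n_input = n_input, n_classified = n_classified,
    coverage = if (n_input > 0L) n_classified / n_input else 0
  )
  if (!is.null(summary_json)) {
    jsonlite::write_json(summary, summary_json, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(summary)
}
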