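# Evaluation statistics: truth-based accuracy/coverage, hit-table-based
# agreement statistics, keyword homogeneity of cluster annotations, and
# ROC-based score thresholding.

#' Accuracy among classified reads, and coverage
#'
#' @param assignments data.frame with `read_id`, `cluster_id`,
#'   `classified` (one row per input read, as produced by
#'   [classify_reads()]).
#' @param truth data.frame with `read_id`, `true_cluster`.
#' @return List: `accuracy_classified` (correct/classified; `NA` when
#'   nothing was classified), `coverage` (classified/input), `n_input`,
#'   `n_classified`, `n_correct`.
#' @export
accuracy_and_coverage <- function(assignments, truth) {
  a <- as.data.table(assignments)
  t <- as.data.table(truth)
  stopifnot(all(c("read_id", "cluster_id", "classified") %in% names(a)),
            all(c("read_id", "true_cluster") %in% names(t)))
  cl <- a[classified == TRUE]
  j <- t[cl, on = "read_id"]
  missing <- j[is.na(true_cluster), read_id]
  if (length(missing) > 0L) {
    stop("truth missing for classified read(s): ",
         paste(head(missing, 10L), collapse = ", "), call. = FALSE)
  }
  n_correct <- sum(j$cluster_id == j$true_cluster)
  list(
    accuracy_classified = if (nrow(cl) > 0L) n_correct / nrow(cl)
                          else NA_real_,
    coverage = if (nrow(a) > 0L) nrow(cl) / nrow(a) else 0,
    n_input = nrow(a),
    n_classified = nrow(cl),
    n_correct = n_correct
  )
}

check_hits <- function(hits, p2c) {
  h <- as.data.table(hits)
  stopifnot(all(c("read_id", "protein_id") %in% names(h)))
  unmapped <- setdiff(unique(h$protein_id), names(p2c))
  if (length(unmapped) > 0L) {
    stop("hit protein(s) missing from the protein->cluster map: ",
         paste(head(unmapped, 10L), collapse = ", "), call. = FALSE)
  }
  h[, hit_cluster := unname(p2c[protein_id])]
  h
}

#' Fraction of multi-hit reads resolved to a single cluster
#'
#' Restricted to reads hitting at least two distinct proteins in the hit
#' table; such a read is "resolved" when all its hit proteins belong to
#' one cluster, i.e. the cluster level removes the multi-mapping
#' ambiguity.
#'
#' @param hits data.frame of aligner hits with `read_id`, `protein_id`
#'   (many rows per read allowed).
#' @param p2c Named character vector, protein id -> cluster id, covering
#'   every hit protein.
#' @return List: `resolution` (resolved/multi-hit; `NA` if no multi-hit
#'   read), `n_multi`, `n_resolved`, and `per_read` (data.table
#'   `read_id`, `resolved`).
#' @export
multimap_resolution <- function(hits, p2c) {
  h <- check_hits(hits, p2c)
  per <- h[, .(n_proteins = uniqueN(protein_id),
               n_clusters = uniqueN(hit_cluster)), by = read_id]
  multi <- per[n_proteins >= 2L]
  multi[, resolved := n_clusters == 1L]
  list(
    resolution = if (nrow(multi) > 0L) mean(multi$resolved) else NA_real_,
    n_multi = nrow(multi),
    n_resolved = sum(multi$resolved),
    per_read = multi[, .(read_id, resolved)]
  )
}

#' Agreement between cluster assignments and an external hit table
#'
#' A read (classified by the model and carrying at least one surviving
#' hit) "agrees" when any of its hit proteins belongs to the assigned
#' cluster — a non-empty overlap between hit proteins and the cluster.
#'
#' @param assignments data.frame with `read_id`, `cluster_id`,
#'   `classified`.
#' @param hits data.frame with `read_id`, `protein_id` and, if
#'   `identity_floor` is used, `percent_identity`.
#' @param p2c Named character vector protein id -> cluster id.
#' @param identity_floor Optional percent-identity cutoff; hits below it
#'   are dropped first, and reads whose every hit is dropped leave the
#'   denominator.
#' @return List: `agreement` (agree / evaluated), `sensitivity`
#'   (agreeing / reads with surviving hits), `n_evaluated`, `n_agree`,
#'   `n_hit_reads`, and `per_read` (data.table `read_id`, `agree`).
#' @export
agreement <- function(assignments, hits, p2c, identity_floor = NULL) {
  a <- as.data.table(assignments)[classified == TRUE,
                                  .(read_id, cluster_id)]
  h <- check_hits(hits, p2c)
  if (!is.null(identity_floor)) {
    stopifnot("percent_identity" %in% names(h))
    h <- h[percent_identity >= identity_floor]
  }
  hit_reads <- unique(h$read_id)
  j <- h[a, on = "read_id", nomatch = NULL]
  per <- j[, .(agree = any(hit_cluster == cluster_id)), by = read_id]
  setorder(per, read_id)
  n_agree <- sum(per$agree)
  list(
    agreement = if (nrow(per) > 0L) n_agree / nrow(per) else NA_real_,
    sensitivity = if (length(hit_reads) > 0L) n_agree / length(hit_reads)
                  else NA_real_,
    n_evaluated = nrow(per),
    n_agree = n_agree,
    n_hit_reads = length(hit_reads),
    per_read = per
  )
}

#' Per-cluster concordance with an external hit table
#'
#' For each cluster with at least one evaluated read, the ratio of reads
#' assigned to it that agree with the hit table (per [agreement()]) out
#' of all evaluated reads assigned to it.
#'
#' @inheritParams agreement
#' @return data.table with `cluster_id`, `n_reads`, `concordance`,
#'   ordered by cluster id; clusters with no evaluated reads are absent.
#' @export
per_cluster_concordance <- function(assignments, hits, p2c,
                                    identity_floor = NULL) {
  a <- as.data.table(assignments)[classified == TRUE,
                                  .(read_id, cluster_id)]
  res <- agreement(assignments, hits, p2c, identity_floor)
  per <- res$per_read[a, on = "read_id", nomatch = NULL]
  out <- per[, .(n_reads = .N, concordance = mean(agree)),
             by = cluster_id]
  setorder(out, cluster_id)
  out[]
}

#' Default annotation stopword list
#'
#' Generic tokens stripped before keyword statistics; shipped as
#' `extdata/annotation_stopwords.txt`.
#'
#' @return Character vector of lower-case stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "annotation_stopwords.txt",
                      package = "clustkmer")
  readLines(path)
}

tokenize_annotation <- function(x, stopwords) {
  toks <- strsplit(gsub("[^a-z0-9 ]", " ", tolower(x)), "\\s+")[[1L]]
  setdiff(unique(toks[nzchar(toks)]), stopwords)
}

#' Within-cluster keyword homogeneity
#'
#' For each cluster, tokenizes member protein names (lower-case,
#' punctuation stripped, whole tokens), drops stopwords, finds the modal
#' token by member presence (ties broken by the lexicographically
#' smallest token), and reports the fraction of members whose name
#' contains it. Clusters whose members have no tokens left are skipped.
#'
#' @param cluster_names Named list: cluster id -> character vector of
#'   member protein names.
#' @param stopwords Character vector (default [default_stopwords()]).
#' @return data.table `cluster_id`, `keyword`, `frequency`, `n_members`;
#'   skipped-cluster count attached as attribute `n_skipped`.
#' @export
keyword_homogeneity <- function(cluster_names,
                                stopwords = default_stopwords()) {
  stopifnot(is.list(cluster_names), !is.null(names(cluster_names)))
  stopwords <- tolower(stopwords)
  rows <- list()
  n_skipped <- 0L
  for (cid in names(cluster_names)) {
    members <- cluster_names[[cid]]
    token_sets <- lapply(members, tokenize_annotation, stopwords = stopwords)
    counts <- table(unlist(token_sets))
    if (length(counts) == 0L) {
      n_skipped <- n_skipped + 1L
      next
    }
    modal <- sort(names(counts)[counts == max(counts)])[1L]
    frac <- mean(vapply(token_sets, function(s) modal %in% s, logical(1)))
    rows[[length(rows) + 1L]] <- data.table(
      cluster_id = cid, keyword = modal, frequency = frac,
      n_members = length(members)
    )
  }
  out <- if (length(rows) > 0L) rbindlist(rows) else
    data.table(cluster_id = character(0), keyword = character(0),
               frequency = numeric(0), n_members = integer(0))
  setattr(out, "n_skipped", n_skipped)
  out
}

#' AUROC and FPR-capped score threshold
#'
#' AUROC is computed by the rank (Mann-Whitney) statistic with midrank
#' ties. The threshold is the smallest score cutoff `t` (scanning the
#' unique observed scores) for which the empirical false positive rate of
#' the rule "positive iff score >= t" is at most `fpr_cap`; `Inf` (with
#' zero TPR) if even the largest score fails, which can only happen when
#' the top score is negative-labelled.
#'
#' @param scores Numeric vector of classifier scores.
#' @param labels Logical (or 0/1) vector; `TRUE` = positive class. Both
#'   classes must be present.
#' @param fpr_cap Maximum tolerated false positive rate (default 0.05).
#' @return List: `auroc`, `threshold`, `tpr`, `fpr` (the latter two at
#'   the returned threshold), `n_pos`, `n_neg`.
#' @export
roc_threshold <- function(scores, labels, fpr_cap = 0.05) {
  stopifnot(length(scores) == length(labels), fpr_cap >= 0, fpr_cap <= 1)
  labels <- as.logical(labels)
  stopifnot(!anyNA(labels), !anyNA(scores))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both label classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # midranks for ties
  auroc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  cand <- sort(unique(scores))
  threshold <- Inf
  tpr <- 0
  fpr <- 0
  for (t in cand) {
    f <- sum(scores[!labels] >= t) / n_neg
    if (f <= fpr_cap) {
      threshold <- t
      fpr <- f
      tpr <- sum(scores[labels] >= t) / n_pos
      break
    }
  }
  list(auroc = auroc, threshold = threshold, tpr = tpr, fpr = fpr,
       n_pos = n_pos, n_neg = n_neg)
}

#' Read an aligner hit table (BLAST outfmt-6-like)
#'
#' @param path TSV path. Headerless files are read positionally.
#' @param columns Character vector naming the columns of the file, which
#'   must include `qseqid`, `sseqid`, `pident`, `evalue` (the outfmt 6
#'   defaults for columns 1, 2, 3, 11 are assumed when `NULL` and the
#'   file has 12 columns).
#' @return data.table with `read_id`, `protein_id`, `percent_identity`,
#'   `e_value`.
#' @export
read_hit_table <- function(path, columns = NULL) {
  raw <- fread(path, sep = "\t", header = FALSE, quote = "")
  if (is.null(columns)) {
    if (ncol(raw) == 12L) {
      columns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")
    } else if (ncol(raw) == 4L) {
      columns <- c("qseqid", "sseqid", "pident", "evalue")
    } else {
      stop("cannot infer hit-table columns; pass `columns`", call. = FALSE)
    }
  }
  stopifnot(length(columns) == ncol(raw),
            all(c("qseqid", "sseqid", "pident", "evalue") %in% columns))
  setnames(raw, columns)
  out <- raw[, .(read_id = as.character(qseqid),
                 protein_id = as.character(sseqid),
                 percent_identity = as.numeric(pident),
                 e_value = as.numeric(evalue))]
  if (nrow(out) > 0L) {
    stopifnot(all(out$percent_identity >= 0 & out$percent_identity <= 100),
              all(out$e_value >= 0))
  }
  out[]
}
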