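#' Clustered protein database
#'
#' A light container pairing protein sequences with a cluster-membership
#' table, the input to [build_model()]. Clusters are taxa-agnostic groups
#' of homologous proteins treated as one functional unit; each cluster
#' names one member as its representative, whose annotation string labels
#' every read assigned to the cluster.
#'
#' @param seqs Named character vector: protein id -> amino-acid sequence
#'   (standard 20-letter alphabet).
#' @param membership A data.frame with columns `cluster_id`, `protein_id`,
#'   `is_representative` (logical), `annotation` (character; tab/newline
#'   free). Every protein belongs to exactly one cluster; every cluster is
#'   non-empty with exactly one representative drawn from its members.
#' @return An object of class `cluster_db`.
#' @export
cluster_db <- function(seqs, membership) {
  stopifnot(is.character(seqs))
  if (length(seqs) == 0L) names(seqs) <- character(0)
  stopifnot(!is.null(names(seqs)))
  membership <- as.data.table(membership)
  required <- c("cluster_id", "protein_id", "is_representative", "annotation")
  missing_cols <- setdiff(required, names(membership))
  if (length(missing_cols) > 0L) {
    stop("membership is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  membership <- membership[, required, with = FALSE]
  membership[, cluster_id := as.character(cluster_id)]
  membership[, protein_id := as.character(protein_id)]
  membership[, is_representative := as.logical(is_representative)]
  membership[, annotation := as.character(annotation)]

  if (anyDuplicated(names(seqs))) {
    stop("duplicate protein ids in seqs", call. = FALSE)
  }
  if (anyDuplicated(membership$protein_id)) {
    stop("a protein may belong to exactly one cluster", call. = FALSE)
  }
  if (!setequal(names(seqs), membership$protein_id)) {
    stop("seqs and membership must cover the same protein ids",
         call. = FALSE)
  }
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
  if (any(bad)) {
    stop("non-standard amino-acid letters in protein(s): ",
         paste(head(names(seqs)[bad], 5L), collapse = ", "), call. = FALSE)
  }
  reps <- membership[is_representative == TRUE]
  n_rep <- reps[, .N, by = cluster_id]
  all_cl <- unique(membership$cluster_id)
  if (nrow(n_rep) != length(all_cl) || any(n_rep$N != 1L)) {
    stop("every cluster must have exactly one representative",
         call. = FALSE)
  }
  if (any(grepl("[\t\n]", membership$annotation))) {
    stop("annotations must not contain tabs or newlines", call. = FALSE)
  }
  structure(
    list(seqs = seqs, membership = membership[]),
    class = "cluster_db"
  )
}

#' @export
print.cluster_db <- function(x, ...) {
  cat(sprintf(
    "<cluster_db> %d proteins in %d clusters\n",
    length(x$seqs), length(unique(x$membership$cluster_id))
  ))
  invisible(x)
}

#' Number of proteins per cluster
#' @param db A [cluster_db()].
#' @return Named integer vector, cluster id -> member count.
#' @export
cluster_sizes <- function(db) {
  stopifnot(inherits(db, "cluster_db"))
  tab <- db$membership[, .N, by = cluster_id]
  setorder(tab, cluster_id)
  setNames(tab$N, tab$cluster_id)
}

#' Representative annotation per cluster
#' @param db A [cluster_db()].
#' @return Named character vector, cluster id -> annotation string.
#' @export
cluster_annotations <- function(db) {
  stopifnot(inherits(db, "cluster_db"))
  reps <- db$membership[is_representative == TRUE]
  setorder(reps, cluster_id)
  setNames(reps$annotation, reps$cluster_id)
}

#' Map protein id -> cluster id
#' @param db A [cluster_db()].
#' @return Named character vector.
#' @export
protein_to_cluster <- function(db) {
  stopifnot(inherits(db, "cluster_db"))
  setNames(db$membership$cluster_id, db$membership$protein_id)
}

#' Read a clustered protein database from FASTA + membership TSV
#'
#' @param fasta_path Protein FASTA (multi-line records allowed).
#' @param membership_path TSV with header
#'   `cluster_id  protein_id  is_representative  annotation`.
#' @return A [cluster_db()].
#' @export
read_cluster_db <- function(fasta_path, membership_path) {
  seqs <- read_fasta(fasta_path)
  membership <- fread(membership_path, sep = "\t", header = TRUE,
                      colClasses = "character")
  membership$is_representative <-
    membership$is_representative %in% c("TRUE", "true", "1", "T")
  cluster_db(seqs, membership)
}

#' Write a clustered protein database to FASTA + membership TSV
#'
#' @param db A [cluster_db()].
#' @param fasta_path,membership_path Output paths.
#' @return Invisibly, `db`.
#' @export
write_cluster_db <- function(db, fasta_path, membership_path) {
  stopifnot(inherits(db, "cluster_db"))
  write_fasta(db$seqs, fasta_path)
  fwrite(db$membership, membership_path, sep = "\t", quote = FALSE)
  invisible(db)
}

#' Greedy incremental protein clustering (fixture stand-in)
#'
#' A deliberately simple longest-first greedy clusterer: each sequence
#' joins the first existing cluster whose representative shares at least
#' `similarity_threshold` of the shorter sequence's distinct word-size
#' k-mers (containment similarity), otherwise it founds a new cluster
#' with itself as representative. This exists to build fixtures and is
#' documented as NOT equivalent to CD-HIT-style clustering.
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param similarity_threshold Fraction in (0, 1].
#' @param word_size k-mer length used for the containment similarity
#'   (default 5).
#' @return A [cluster_db()]; annotations are the representative's id.
#' @export
greedy_cluster <- function(proteins, similarity_threshold, word_size = 5L) {
  stopifnot(is.numeric(similarity_threshold),
            similarity_threshold > 0, similarity_threshold <= 1)
  if (length(proteins) == 0L) {
    return(cluster_db(
      character(0),
      data.frame(cluster_id = character(0), protein_id = character(0),
                 is_representative = logical(0), annotation = character(0))
    ))
  }
  if (is.null(names(proteins))) {
    names(proteins) <- sprintf("P%04d", seq_along(proteins))
  }
  ord <- order(-nchar(proteins))  # longest first, input order breaks ties
  rep_sets <- list()
  rep_ids <- character(0)
  assignment <- character(length(proteins))
  names(assignment) <- names(proteins)
  for (i in ord) {
    kset <- unique(extract_kmers(proteins[[i]], word_size))
    joined <- NA_integer_
    for (ci in seq_along(rep_sets)) {
      denom <- min(length(kset), length(rep_sets[[ci]]))
      sim <- if (denom == 0L) 0 else
        length(intersect(kset, rep_sets[[ci]])) / denom
      if (sim >= similarity_threshold) {
        joined <- ci
        break
      }
    }
    if (is.na(joined)) {
      rep_sets[[length(rep_sets) + 1L]] <- kset
      rep_ids <- c(rep_ids, names(proteins)[i])
      joined <- length(rep_sets)
    }
    assignment[[names(proteins)[i]]] <- sprintf("GC%05d", joined)
  }
  membership <- data.table(
    cluster_id = unname(assignment[names(proteins)]),
    protein_id = names(proteins),
    is_representative = names(proteins) %in% rep_ids,
    annotation = ""
  )
  membership[, annotation := rep_ids[match(cluster_id, sprintf(
    "GC%05d", seq_along(rep_ids)))]]
  cluster_db(proteins, membership)
}
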