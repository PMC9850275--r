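#' Greedy sequence clustering by global identity
#'
#' Homology clustering of protein sequences for leakage-free
#' cross-validation splits. Sequences are processed by decreasing length
#' (ties by input order); each is assigned to the first existing cluster
#' whose centroid it matches at `identity_cutoff` or better under a
#' global Needleman-Wunsch alignment (identity = matches / alignment
#' length, gaps included), otherwise it founds a new cluster. An
#' externally computed clustering (e.g. from a dedicated clustering tool)
#' can be supplied instead via `precomputed`.
#'
#' @param sequences Character vector of one-letter protein sequences
#'   (named or not; names become sequence ids).
#' @param identity_cutoff Minimum pairwise identity to join a cluster.
#' @param precomputed Optional integer/character vector of cluster labels
#'   (same length as `sequences`) accepted verbatim.
#' @return A `family_clustering`: `data.frame` with `id`, `sequence`,
#'   `cluster`, plus the cutoff used.
#' @export
cluster_families <- function(sequences, identity_cutoff = 0.25,
                             precomputed = NULL) {
  if (any(!nzchar(sequences))) stop("empty sequence rejected")
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  if (!is.null(precomputed)) {
    stopifnot(length(precomputed) == length(sequences))
    cl <- as.integer(factor(precomputed))
  } else {
    ord <- order(-nchar(sequences), seq_along(sequences))
    cl <- integer(length(sequences))
    centroids <- character()
    centroid_cl <- integer()
    for (i in ord) {
      assigned <- 0L
      for (j in seq_along(centroids)) {
        if (global_identity(sequences[i], centroids[j]) >= identity_cutoff) {
          assigned <- centroid_cl[j]
          break
        }
      }
      if (assigned == 0L) {
        centroids <- c(centroids, sequences[i])
        assigned <- length(centroids)
        centroid_cl <- c(centroid_cl, assigned)
      }
      cl[i] <- assigned
    }
  }
  structure(list(members = data.frame(id = ids,
                                      sequence = unname(sequences),
                                      cluster = cl,
                                      stringsAsFactors = FALSE),
                 cluster = cl,
                 identity_cutoff = identity_cutoff),
            class = "family_clustering")
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) via
#' Biostrings; identity is exact matches divided by the alignment length
#' including gap columns.
#'
#' @param a,b One-letter protein sequences.
#' @return Identity in `[0, 1]`.
#' @export
global_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(p == s & p != "-") / length(p)
}

#' Cluster-disjoint k-fold splits
#'
#' Partitions records into `k` folds at the level of homology clusters:
#' all records of a cluster land in the same fold, so no fold's
#' validation set shares a family with its training set. Each repeat
#' reshuffles the cluster-to-fold assignment with a seed derived from
#' `seed`.
#'
#' @param cluster Integer cluster id per record (e.g.
#'   `family_clustering$cluster` indexed per record).
#' @param k Number of folds.
#' @param repeats Number of reshuffled repetitions.
#' @param seed Integer seed.
#' @return List of length `repeats`; each element a list of `k` folds,
#'   each fold a list with integer record-index vectors `train` and
#'   `validation`.
#' @export
make_splits <- function(cluster, k, repeats = 1L, seed = 1L) {
  ucl <- unique(cluster)
  if (k > length(ucl)) {
    stop("k = ", k, " exceeds the number of clusters (", length(ucl), ")")
  }
  lapply(seq_len(repeats), function(rep) {
    set.seed(seed + rep - 1L)
    # shuffle clusters, deal them round-robin into k folds
    shuffled <- sample(ucl)
    fold_of_cluster <- stats::setNames(
      rep_len(seq_len(k), length(shuffled)), shuffled)
    fold_of_record <- unname(fold_of_cluster[as.character(cluster)])
    lapply(seq_len(k), function(f) {
      list(train = which(fold_of_record != f),
           validation = which(fold_of_record == f))
    })
  })
}
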