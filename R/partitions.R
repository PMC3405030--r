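## Sample partitions in canonical restricted-growth form, their exhaustive
## and neighborhood enumeration, and per-module within-cluster sums of
## squares. Partitions are integer vectors of 1-based cluster labels; the
## canonical (restricted growth) form relabels clusters in order of first
## occurrence, so each set partition has exactly one representation.

#' Canonicalize a cluster assignment
#'
#' Relabels clusters by order of first occurrence (restricted growth form),
#' so two assignments describe the same set partition iff their canonical
#' forms are identical.
#'
#' @param g vector of cluster labels (any type), one per sample.
#' @return integer vector of canonical labels 1..C.
#' @export
canonicalPartition <- function(g) {
  match(g, unique(g))
}

#' Partition from phenotype labels
#'
#' @param labels named character vector sample -> phenotype.
#' @param sampleOrder order of samples; defaults to \code{names(labels)}.
#' @return canonical integer partition over \code{sampleOrder}.
#' @export
partitionFromLabels <- function(labels, sampleOrder = names(labels)) {
  missing <- setdiff(sampleOrder, names(labels))
  if (length(missing))
    stop("unlabeled sample(s): ", paste(missing, collapse = ", "))
  canonicalPartition(unname(labels[sampleOrder]))
}

#' Stirling number of the second kind
#'
#' Number of partitions of \code{m} items into exactly \code{C} non-empty
#' clusters, by the standard recurrence
#' \eqn{S(m,C) = C\,S(m-1,C) + S(m-1,C-1)}.
#'
#' @param m number of items.
#' @param C number of clusters.
#' @return numeric count (may exceed integer range).
#' @export
stirling2 <- function(m, C) {
  if (C < 0 || C > m) return(0)
  if (m == 0) return(as.numeric(C == 0))
  row <- c(1, rep(0, C))                # S(0, 0..C)
  for (i in seq_len(m)) {
    new <- numeric(C + 1)
    for (j in seq_len(min(i, C)))
      new[j + 1] <- j * row[j + 1] + row[j]
    row <- new
  }
  row[C + 1]
}

#' Enumerate all partitions of m samples into C clusters
#'
#' Generates every canonical restricted-growth string with exactly \code{C}
#' blocks, each exactly once. Refuses when the Stirling count
#' \eqn{S(m,C)} exceeds \code{cap}: at that size use
#' [neighborhoodPartitions()] around a target instead.
#'
#' @param m number of samples (>= C >= 1).
#' @param C number of clusters.
#' @param cap refusal threshold on the partition count.
#' @return list of integer partitions.
#' @examples
#' length(enumeratePartitions(4, 2))  # S(4,2) = 7
#' @export
enumeratePartitions <- function(m, C, cap = 1e6) {
  stopifnot(C >= 1L, C <= m)
  count <- stirling2(m, C)
  if (count > cap)
    stop("S(", m, ",", C, ") = ", format(count), " exceeds cap ", cap,
         "; use neighborhoodPartitions() around the target instead")
  out <- vector("list", count)
  pos <- 0L
  g <- integer(m)
  rec <- function(i, maxUsed) {
    if (i > m) {
      pos <<- pos + 1L
      out[[pos]] <<- g[seq_len(m)]
      return(invisible(NULL))
    }
    # prune: remaining slots must still allow reaching C clusters
    upper <- min(maxUsed + 1L, C)
    for (lab in seq_len(upper)) {
      newMax <- max(maxUsed, lab)
      if (newMax + (m - i) >= C) {
        g[i] <<- lab
        rec(i + 1L, newMax)
      }
    }
    invisible(NULL)
  }
  rec(1L, 0L)
  out
}

#' Partitions within a reassignment neighborhood of a target
#'
#' All distinct canonical partitions with the same number of clusters
#' obtainable from \code{target} by reassigning at most \code{d} samples to
#' different clusters, excluding the target itself and any assignment that
#' empties a cluster. This is the tractable surrogate for exhaustive
#' enumeration when \eqn{S(m,C)} is astronomically large.
#'
#' @param target canonical integer partition.
#' @param d maximum number of reassigned samples (>= 1).
#' @return list of canonical integer partitions.
#' @export
neighborhoodPartitions <- function(target, d = 2L) {
  stopifnot(d >= 1L)
  target <- canonicalPartition(target)
  m <- length(target)
  C <- max(target)
  if (C <= 1L) return(list())
  tkey <- paste(target, collapse = ",")
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (size in seq_len(min(d, m))) {
    subsets <- utils::combn(m, size)
    for (s in seq_len(ncol(subsets))) {
      idx <- subsets[, s]
      choices <- lapply(idx, function(i) setdiff(seq_len(C), target[i]))
      grid <- as.matrix(expand.grid(choices, KEEP.OUT.ATTRS = FALSE))
      for (r in seq_len(nrow(grid))) {
        cand <- target
        cand[idx] <- grid[r, ]
        if (length(unique(cand)) != C) next   # emptied a cluster
        cand <- canonicalPartition(cand)
        key <- paste(cand, collapse = ",")
        if (key == tkey || !is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  out
}

#' Per-module within-cluster sum of squares
#'
#' For each module row of the responsive matrix, the sum over clusters of
#' squared deviations of the module's responsive values from the cluster
#' mean:
#' \deqn{w_k(\pi) = \sum_{c} \sum_{j \in c} (v_{kj} - \bar v_{kc})^2.}
#' Summed over selected modules this is exactly the within-cluster SSE of
#' the samples embedded in the selected-module subspace, which is what the
#' selection program minimizes at the target partition.
#'
#' @param R responsive SummarizedExperiment or matrix, modules x samples.
#' @param p integer partition over the samples (columns).
#' @return numeric vector of length K (one WSS per module).
#' @export
perModuleWSS <- function(R, p) {
  V <- .valueMatrix(R)
  if (length(p) != ncol(V))
    stop("partition length ", length(p), " != sample count ", ncol(V))
  p <- as.integer(p)
  counts <- tabulate(p)
  S <- t(rowsum(t(V), p, reorder = TRUE))        # K x C cluster sums
  w <- rowSums(V^2) - as.vector(S^2 %*% (1 / counts[counts > 0]))
  pmax(w, 0)
}
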