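## The binary integer program at the heart of the method, its exact
## small-instance solver and the two-step greedy ranking heuristic.
##
## With per-module within-cluster SSE w_k(pi) and contribution matrix
## a_kr = w_k(pi_r) - w_k(pi_0), a binary selection x classifies the samples
## into the target partition pi_0 when every margin
## L_r(x) = sum_k x_k a_kr >= 0, i.e. the target attains the minimum
## within-cluster SSE among all considered partitions in the selected-module
## subspace. The program asks for a feasible x of minimum cardinality.
## Because x is binary (x_k^2 = x_k) the quadratic form of the SSE
## difference collapses to this linear margin.

#' Build the condition system for module selection
#'
#' Computes the per-module within-cluster SSE for the target partition and
#' every alternative, and the contribution matrix
#' \eqn{a_{kr} = w_k(\pi_r) - w_k(\pi_0)}.
#'
#' @param R responsive SummarizedExperiment or matrix, modules x samples.
#' @param target canonical integer partition of the samples (the phenotype
#'   grouping to be recovered).
#' @param alternatives non-empty list of canonical integer partitions,
#'   excluding the target.
#' @return a [ConditionSystem-class].
#' @export
buildConditions <- function(R, target, alternatives) {
  V <- .valueMatrix(R)
  if (length(alternatives) == 0L)
    stop("need at least one alternative partition")
  target <- canonicalPartition(target)
  alternatives <- lapply(alternatives, canonicalPartition)
  tkey <- paste(target, collapse = ",")
  if (tkey %in% vapply(alternatives, paste, character(1), collapse = ","))
    stop("the target partition must not appear among the alternatives")
  w0 <- perModuleWSS(V, target)
  walt <- vapply(alternatives, function(p) perModuleWSS(V, p),
                 numeric(nrow(V)))
  walt <- matrix(walt, nrow = nrow(V))           # guard K == 1
  ids <- rownames(V)
  if (is.null(ids)) ids <- paste0("M", seq_len(nrow(V)))
  new("ConditionSystem", moduleIds = ids, target = target,
      alternatives = alternatives,
      wss = cbind(target = w0, walt), A = walt - w0)
}

#' Evaluate a module selection against a condition system
#'
#' @param x binary selection vector of length K (or integer indices of the
#'   selected modules).
#' @param cs a [ConditionSystem-class].
#' @return list with \code{margins} (\eqn{L_r = \sum_{k \in M} a_{kr}}),
#'   \code{feasible} (all margins >= 0) and \code{power}
#'   (\eqn{P(M) = |M|^{-1} \sum_r \max(0, -L_r)}, the average power of
#'   classification; 0 iff feasible).
#' @export
evaluateSelection <- function(x, cs) {
  K <- nrow(cs@A)
  sel <- .asSelection(x, K)
  if (length(sel) == 0L) stop("the selection must contain at least one module")
  margins <- colSums(cs@A[sel, , drop = FALSE])
  list(margins = margins,
       feasible = all(margins >= 0),
       power = sum(pmax(0, -margins)) / length(sel))
}

.asSelection <- function(x, K) {
  if (length(x) == K && all(x %in% c(0, 1)))
    which(as.integer(x) == 1L)
  else if (all(x >= 1 & x <= K)) sort(unique(as.integer(x)))
  else stop("selection must be a binary vector of length K or module indices")
}

#' Exact minimum-cardinality selection by exhaustive search
#'
#' Searches all non-empty module subsets in order of increasing size
#' (lexicographic within a size) and returns the first feasible one, i.e. a
#' feasible selection of minimum cardinality with ties broken toward the
#' lexicographically smallest index set. The underlying program is NP-hard,
#' so the search is guarded by \code{maxK}.
#'
#' @param cs a [ConditionSystem-class].
#' @param maxK refusal threshold on the module count (default 20).
#' @return a [SelectionResult-class] with \code{method = "exact"}; when no
#'   subset is feasible, \code{feasible} is \code{FALSE} and the selection
#'   is empty.
#' @export
solveExact <- function(cs, maxK = 20L) {
  K <- nrow(cs@A)
  if (K > maxK)
    stop("K = ", K, " exceeds maxK = ", maxK,
         "; use greedySelect() for large instances")
  for (size in seq_len(K)) {
    subsets <- utils::combn(K, size)
    for (s in seq_len(ncol(subsets))) {
      idx <- subsets[, s]
      margins <- colSums(cs@A[idx, , drop = FALSE])
      if (all(margins >= 0)) {
        x <- integer(K); x[idx] <- 1L
        return(new("SelectionResult", moduleIds = cs@moduleIds, x = x,
                   selected = idx, margins = margins, feasible = TRUE,
                   method = "exact"))
      }
    }
  }
  new("SelectionResult", moduleIds = cs@moduleIds, x = integer(K),
      selected = integer(0), margins = rep(-Inf, ncol(cs@A)),
      feasible = FALSE, method = "exact")
}

#' Rank modules by individual classification power
#'
#' Step 1 of the greedy algorithm: each module is scored by its own column
#' of contributions, \eqn{s_k = -\sum_r a_{kr}}, and the modules are sorted
#' by increasing score so the module with the largest aggregate separation
#' contribution comes first. Ties keep the original module order.
#'
#' @param cs a [ConditionSystem-class].
#' @return list with \code{ordering} (integer module indices, best first)
#'   and \code{scores} (per-module \eqn{s_k}, in original module order).
#' @export
rankModules <- function(cs) {
  s <- -rowSums(cs@A)
  list(ordering = order(s, seq_along(s)), scores = s)
}

#' Greedy prefix selection by average power
#'
#' Step 2 of the greedy algorithm: following the ranking of
#' [rankModules()], modules are added one by one and the average power of
#' classification
#' \eqn{P(M_n) = |M_n|^{-1} \sum_r \max(0, -L_r(M_n))}
#' is computed for every prefix \eqn{M_n}. The selection is the shortest
#' prefix attaining the minimum of \eqn{P}; \eqn{P = 0} means every
#' condition is satisfied (feasible classification).
#'
#' @param cs a [ConditionSystem-class].
#' @return a [SelectionResult-class] with \code{method = "greedy"},
#'   including the full ranking, scores and power trace.
#' @export
greedySelect <- function(cs) {
  K <- nrow(cs@A)
  if (K < 1L) stop("no module to select from")
  rk <- rankModules(cs)
  Ar <- cs@A[rk$ordering, , drop = FALSE]
  cum <- apply(Ar, 2L, cumsum)
  cum <- matrix(cum, nrow = K)                   # guard K == 1
  power <- rowSums(pmax(-cum, 0)) / seq_len(K)
  nStar <- which.min(power)                      # first minimum: smallest n
  idx <- sort(rk$ordering[seq_len(nStar)])
  x <- integer(K); x[idx] <- 1L
  margins <- cum[nStar, ]
  new("SelectionResult", moduleIds = cs@moduleIds, x = x, selected = idx,
      margins = margins, feasible = all(margins >= 0),
      ordering = rk$ordering, scores = rk$scores, powerTrace = power,
      nStar = as.integer(nStar), method = "greedy")
}

#' End-to-end module selection on a responsive matrix
#'
#' Convenience wrapper: builds the target partition's alternatives
#' (exhaustive enumeration when \eqn{S(m,C)} is within \code{cap}, else the
#' reassignment neighborhood of radius \code{d}), assembles the condition
#' system and runs the chosen solver.
#'
#' @param R responsive SummarizedExperiment or matrix, modules x samples.
#' @param target canonical integer partition (or named phenotype labels
#'   covering the columns of \code{R}).
#' @param mode \code{"auto"} (default), \code{"exhaustive"} or
#'   \code{"neighborhood"}.
#' @param d neighborhood radius (reassigned samples) for neighborhood mode.
#' @param cap partition-count cap for exhaustive mode.
#' @param solver \code{"greedy"} (default) or \code{"exact"}.
#' @param maxK guard for the exact solver.
#' @return a [SelectionResult-class]; the \code{info} slot records the
#'   partition mode and the number of alternatives.
#' @export
selectModules <- function(R, target, mode = c("auto", "exhaustive",
                                              "neighborhood"),
                          d = 2L, cap = 1e6, solver = c("greedy", "exact"),
                          maxK = 20L) {
  mode <- match.arg(mode)
  solver <- match.arg(solver)
  V <- .valueMatrix(R)
  if (is.character(target))
    target <- partitionFromLabels(target, colnames(V))
  target <- canonicalPartition(target)
  m <- length(target)
  C <- max(target)
  if (C < 2L) stop("selection needs at least two phenotype groups")
  if (mode == "auto")
    mode <- if (stirling2(m, C) <= cap) "exhaustive" else "neighborhood"
  alternatives <- switch(mode,
    exhaustive = {
      all <- enumeratePartitions(m, C, cap = cap)
      tkey <- paste(target, collapse = ",")
      Filter(function(p) paste(p, collapse = ",") != tkey, all)
    },
    neighborhood = neighborhoodPartitions(target, d = d))
  cs <- buildConditions(V, target, alternatives)
  res <- if (solver == "greedy") greedySelect(cs) else solveExact(cs, maxK)
  res@info <- list(mode = mode, d = d, nAlternatives = length(alternatives),
                   m = m, C = C, samples = colnames(V))
  res
}
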