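## Markov Clustering (MCL) of the interaction network, implemented on the
## dense column-stochastic flow matrix. Flow through the graph is alternately
## expanded (matrix power, letting flow spread along paths) and inflated
## (element-wise power with column renormalization, sharpening strong flow),
## until the matrix stops changing; the converged matrix decomposes the graph
## into disjoint clusters read off its attractor rows.

#' Markov clustering of an interaction network
#'
#' Builds the adjacency matrix with unit self-loops, column-normalizes it to
#' a stochastic matrix, and iterates expansion (the \code{expansion}-th
#' matrix power), inflation (element-wise \code{inflation}-th power followed
#' by column renormalization) and pruning (entries below
#' \code{pruneThreshold} zeroed, then renormalization) until the maximum
#' absolute change falls below \code{tol} or \code{maxIter} is reached.
#' Attractors are rows of the converged matrix with positive diagonal; every
#' node is assigned to the attractor receiving the largest flow from it
#' (ties to the lowest attractor index), which yields a hard, disjoint
#' clustering.
#'
#' The procedure is fully deterministic: identical inputs and parameters
#' give identical modules.
#'
#' @param net undirected igraph network (non-empty).
#' @param expansion integer matrix-power exponent, >= 2.
#' @param inflation element-wise power, > 1; larger values give finer
#'   clusters.
#' @param pruneThreshold entries below this are zeroed each iteration.
#' @param maxIter iteration cap; non-convergence returns the current
#'   clustering with a warning.
#' @param tol convergence tolerance on the max absolute change.
#' @return a [ModuleSet-class]; modules are ordered by decreasing size
#'   (ties by smallest member index) and named \code{M1, M2, ...}. The
#'   \code{params} slot records the parameters plus \code{iterations},
#'   \code{converged} and \code{maxColSumDev}, the largest deviation of any
#'   column sum from 1 observed across all iterations (stochasticity
#'   diagnostic).
#' @examples
#' g <- igraph::graph_from_literal(a - b, b - c, a - c, d - e, e - f, d - f)
#' moduleMembers(mclCluster(g))
#' @export
mclCluster <- function(net, expansion = 2L, inflation = 2.0,
                       pruneThreshold = 1e-5, maxIter = 100L, tol = 1e-6) {
  stopifnot(expansion >= 2L, inflation > 1, pruneThreshold >= 0,
            maxIter >= 1L, tol > 0)
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network")
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  dimnames(A) <- list(nodes, nodes)
  diag(A) <- 1                                   # unit self-loops
  M <- .colNormalize(A)

  maxdev <- 0
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(maxIter)) {
    iterations <- it
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- .colNormalize(Mexp^inflation)
    maxdev <- max(maxdev, abs(colSums(Minf) - 1))
    Minf[Minf < pruneThreshold] <- 0
    Minf <- .colNormalize(Minf)
    maxdev <- max(maxdev, abs(colSums(Minf) - 1))
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", maxIter, " iterations")

  attractors <- which(diag(M) > 0)
  if (length(attractors) == 0L) attractors <- seq_len(n)  # cannot happen for
                                                          # a stochastic limit
  flows <- M[attractors, , drop = FALSE]
  assign_to <- attractors[apply(flows, 2L, which.max)]  # which.max: lowest
                                                        # index wins ties
  cl <- split(seq_len(n), assign_to)
  mods <- lapply(cl, function(idx) nodes[sort(idx)])
  ord <- order(-lengths(mods),
               vapply(cl, min, integer(1)))
  mods <- mods[ord]
  names(mods) <- paste0("M", seq_along(mods))
  new("ModuleSet", modules = mods,
      params = list(algorithm = "MCL", expansion = expansion,
                    inflation = inflation, pruneThreshold = pruneThreshold,
                    maxIter = maxIter, tol = tol,
                    iterations = iterations, converged = converged,
                    maxColSumDev = maxdev))
}

.colNormalize <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1
  sweep(M, 2L, cs, "/")
}

#' Filter modules by size and measured membership
#'
#' Drops module members absent from the expression object, then drops
#' modules smaller than \code{minSize}; every drop is reported with a
#' message.
#'
#' @param ms a [ModuleSet-class].
#' @param minSize minimum surviving module size (>= 1).
#' @param z optional SummarizedExperiment or matrix; members not among its
#'   row names are removed before the size check.
#' @return the filtered \code{ModuleSet} (original ids kept).
#' @export
filterModules <- function(ms, minSize = 3L, z = NULL) {
  stopifnot(minSize >= 1L)
  mods <- moduleMembers(ms)
  if (!is.null(z)) {
    measured <- rownames(.valueMatrix(z))
    trimmed <- lapply(mods, intersect, measured)
    lost <- sum(lengths(mods)) - sum(lengths(trimmed))
    if (lost > 0)
      message("dropped ", lost, " unmeasured module member(s)")
    mods <- trimmed
  }
  small <- lengths(mods) < minSize
  if (any(small))
    message("dropped ", sum(small), " module(s) below size ", minSize, ": ",
            paste(utils::head(names(mods)[small], 10), collapse = " "))
  mods <- mods[!small]
  if (length(mods) == 0L)
    stop("no module survives size filtering at minSize = ", minSize)
  new("ModuleSet", modules = mods,
      params = c(ms@params, list(minSize = minSize)))
}
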