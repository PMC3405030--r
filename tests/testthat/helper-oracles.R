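# Independent oracles and small fixture builders shared across tests.

suppressPackageStartupMessages(library(SummarizedExperiment))

# Stirling number of the second kind by inclusion-exclusion (independent of
# the package's recurrence-based stirling2()).
stirlingFormula <- function(m, C) {
  if (C < 0 || C > m) return(0)
  j <- 0:C
  sum((-1)^j * choose(C, j) * (C - j)^m) / factorial(C)
}

# Brute-force within-cluster SSE of the samples embedded in the
# selected-module subspace: straight from the definition, no per-module
# decomposition.
bruteSubspaceSSE <- function(V, selected, partition) {
  X <- V[selected, , drop = FALSE]
  sum(vapply(split(seq_along(partition), partition), function(idx) {
    sub <- X[, idx, drop = FALSE]
    sum((sub - rowMeans(sub))^2)
  }, numeric(1)))
}

partitionKey <- function(p) paste(p, collapse = ",")

# Canonical membership fingerprint of a module list (order-free both across
# and within modules).
moduleKey <- function(mods) {
  sort(unname(vapply(lapply(mods, sort), paste, character(1),
                     collapse = ",")))
}

# Minimum number of single-sample reassignments between two partitions of
# the same items into the same number of clusters: m minus the best
# label-matching agreement (exhaustive over label permutations; small C
# only).
moveDistance <- function(p, q) {
  C <- max(max(p), max(q))
  perms <- .permutations(C)
  best <- 0L
  for (i in seq_len(nrow(perms))) {
    relabeled <- perms[i, ][q]
    best <- max(best, sum(relabeled == p))
  }
  length(p) - best
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# Fabricate a ConditionSystem straight from a contribution matrix A
# (alternatives are dummies; only dimensions and the target-exclusion rule
# matter for the solvers).
csFromA <- function(A) {
  K <- nrow(A); R <- ncol(A)
  new("ConditionSystem", moduleIds = paste0("M", seq_len(K)),
      target = c(1L, 2L),
      alternatives = rep(list(c(1L, 1L)), R),
      wss = cbind(numeric(K), A), A = A)
}

# Small expression TSV on disk; returns the path.
writeToyExpression <- function(values, path = tempfile(fileext = ".tsv")) {
  writeExpression(values, path)
  path
}

# Run MCL + responsive + greedy selection on a generated study, without the
# ANOVA pre-filter (synthetic benchmarks measure the selection machinery on
# the full planted signal).
runStudySelection <- function(st, minSize = 3L) {
  ms <- suppressMessages(mclCluster(st$network))
  z <- zTransform(assay(st$expression))
  msf <- suppressMessages(filterModules(ms, minSize, z))
  V <- computeResponsive(z, msf)
  sel <- selectModules(V, st$labels[colnames(z)])
  list(modules = ms, filtered = msf, z = z, responsive = V, selection = sel)
}

# Best-overlap mapping of detected modules onto planted module ids.
mapToPlanted <- function(mods, planted) {
  vapply(mods, function(m) {
    ov <- vapply(planted, function(p) length(intersect(m, p)), integer(1))
    names(ov)[which.max(ov)]
  }, character(1))
}

# Jaccard between the planted responsive module ids and the planted ids
# best-overlapping the selected modules.
plantedJaccard <- function(st, filtered, selection) {
  mapid <- vapply(moduleMembers(filtered)[selection@selected], function(m) {
    ov <- vapply(moduleMembers(st$truth$modules), function(p)
      length(intersect(m, p)), integer(1))
    names(ov)[which.max(ov)]
  }, character(1))
  truth <- names(st$truth$plan)
  length(intersect(unique(mapid), truth)) /
    length(union(unique(mapid), truth))
}
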