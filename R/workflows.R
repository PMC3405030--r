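## Applications of the selection machinery: per-group responsive modules,
## module -> phase assignment, transition-module identification between two
## consecutive phases under a stimulus, hypergeometric gene-set enrichment,
## and validation of selected modules on an external dataset.

.splitLabel <- function(labels) {
  parts <- strsplit(labels, ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("phenotype labels must be 'condition:phase'; offending label: '",
         labels[bad][1L], "'")
  list(condition = vapply(parts, `[`, character(1), 1L),
       phase = vapply(parts, `[`, character(1), 2L))
}

#' Assign each module to the phase of its maximum mean responsive value
#'
#' For every module, responsive values are averaged within each phase group
#' (replicates averaged) and the module is assigned to the phase attaining
#' the maximum. Exact ties go to the earliest phase in the given order and
#' are flagged.
#'
#' @param R responsive SummarizedExperiment or matrix, modules x samples.
#' @param phaseGroups named character vector sample -> phase covering every
#'   column of \code{R}; phase order follows first occurrence unless the
#'   vector is a factor.
#' @return data.frame with columns \code{module}, \code{phase},
#'   \code{tied}; the module x phase mean matrix is attached as attribute
#'   \code{"phaseMeans"}.
#' @export
assignPhases <- function(R, phaseGroups) {
  V <- .valueMatrix(R)
  g <- phaseGroups[colnames(V)]
  if (anyNA(g) || anyNA(names(g)))
    stop("every sample needs a phase label")
  phases <- if (is.factor(phaseGroups)) levels(phaseGroups) else unique(unname(g))
  if (length(phases) < 2L) stop("need at least two phase groups")
  f <- factor(as.character(g), levels = phases)
  sums <- t(rowsum(t(V), f, reorder = TRUE))     # K x P
  means <- sweep(sums, 2L, as.vector(table(f)), "/")
  colnames(means) <- phases
  best <- apply(means, 1L, which.max)            # earliest phase on ties
  tied <- apply(means, 1L, function(r) sum(r == max(r)) > 1L)
  out <- data.frame(module = rownames(V), phase = phases[best], tied = tied,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "phaseMeans") <- means
  out
}

#' Identify responsive modules within one condition group
#'
#' Restricts the samples to one condition, builds the target partition from
#' the cell-cycle phases of those samples and runs the full selection
#' (responsive matrix, condition system, solver).
#'
#' @param z z-score SummarizedExperiment or matrix, genes x samples.
#' @param ms a [ModuleSet-class] (already size-filtered).
#' @param labels named character vector sample -> "condition:phase".
#' @param group the condition name to restrict to.
#' @param ... passed to [selectModules()] (mode, d, cap, solver).
#' @return a [SelectionResult-class]; \code{info} records the samples used.
#' @export
identifyGroupModules <- function(z, ms, labels, group, ...) {
  zm <- .valueMatrix(z)
  labels <- labels[colnames(zm)]
  parts <- .splitLabel(labels)
  keep <- parts$condition == group
  if (!any(keep)) stop("no sample in condition group '", group, "'")
  if (length(unique(parts$phase[keep])) < 2L)
    stop("condition group '", group, "' covers fewer than two phases")
  zs <- zm[, keep, drop = FALSE]
  V <- computeResponsive(zs, ms)
  selectModules(V, partitionFromLabels(labels[keep], colnames(zs)), ...)
}

#' Identify transition modules between two phases under a stimulus
#'
#' Classifies the samples of two consecutive phases under the stimulus and
#' the control condition: the sample subset is the four
#' (condition x phase) cells, the target partition separates those four
#' cells, and the modules selected are reported as transition modules for
#' \code{phaseA} to \code{phaseB} under the stimulus. A module that responds
#' only in (stimulus, phaseB) marks an arrest or changeover of the
#' transition.
#'
#' @param z z-score SummarizedExperiment or matrix, genes x samples.
#' @param ms a [ModuleSet-class].
#' @param labels named character vector sample -> "condition:phase".
#' @param stimulus condition name of the perturbed group.
#' @param phaseA,phaseB the two consecutive phases.
#' @param control condition name of the unperturbed group.
#' @param ... passed to [selectModules()].
#' @return a [SelectionResult-class].
#' @export
identifyTransitionModules <- function(z, ms, labels, stimulus, phaseA,
                                      phaseB, control = "control", ...) {
  zm <- .valueMatrix(z)
  labels <- labels[colnames(zm)]
  cells <- as.vector(outer(c(control, stimulus), c(phaseA, phaseB),
                           paste, sep = ":"))
  keep <- labels %in% cells
  present <- unique(labels[keep])
  missing <- setdiff(cells, present)
  if (length(missing))
    stop("empty condition x phase cell(s): ",
         paste(missing, collapse = ", "))
  zs <- zm[, keep, drop = FALSE]
  V <- computeResponsive(zs, ms)
  res <- selectModules(V, partitionFromLabels(labels[keep], colnames(zs)),
                       ...)
  res@info$transition <- list(stimulus = stimulus, control = control,
                              from = phaseA, to = phaseB)
  res
}

#' Hypergeometric gene-set enrichment of modules
#'
#' For each (module, gene set) pair, tests whether the overlap is larger
#' than expected when drawing the module's members at random from the
#' background: \eqn{p = P(X \ge \mathrm{overlap})} with
#' \eqn{X \sim} Hypergeometric(population = background size,
#' successes = term members in the background, draws = module size).
#'
#' @param ms a [ModuleSet-class]; every member must be in \code{background}.
#' @param sets a [GeneSets-class].
#' @param background character vector: the analysis universe (typically all
#'   genes surviving preprocessing).
#' @param adjust \code{"none"} (raw p-values, default) or \code{"BH"}.
#' @return data.frame with columns \code{module}, \code{term}, \code{size}
#'   (term members in background), \code{overlap}, \code{background},
#'   \code{p} (and \code{p_adj} if requested) and \code{degenerate} (term
#'   absent from the background), sorted by increasing p.
#' @export
hypergeomEnrichment <- function(ms, sets, background,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  background <- unique(background)
  N <- length(background)
  mods <- moduleMembers(ms)
  stray <- setdiff(unlist(mods), background)
  if (length(stray))
    stop("module member(s) outside the background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  rows <- list()
  for (k in seq_along(mods)) {
    draw <- mods[[k]]
    for (t in seq_along(sets@setIds)) {
      termBg <- intersect(sets@members[[t]], background)
      ov <- length(intersect(draw, termBg))
      degenerate <- length(termBg) == 0L
      p <- if (degenerate) 1 else
        stats::phyper(ov - 1L, length(termBg), N - length(termBg),
                      length(draw), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = names(mods)[k], term = sets@setIds[t],
        size = length(termBg), overlap = ov, background = N, p = p,
        degenerate = degenerate, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$module, out$term), , drop = FALSE]
}

#' Validate selected modules on an external dataset
#'
#' Computes the responsive matrix of the selected modules on an external
#' z-scored dataset, clusters its samples hierarchically (Euclidean
#' distance, average linkage by default), cuts the tree into \code{C}
#' clusters and scores the agreement with the known phases by the adjusted
#' Rand index.
#'
#' @param zExt external z-score SummarizedExperiment or matrix.
#' @param selected [ModuleSet-class] of the modules to validate; members
#'   missing from \code{zExt} are dropped with a warning, and a module is
#'   kept only if at least \code{minSize} members survive.
#' @param phases named character vector sample -> known phase.
#' @param C number of clusters to cut (usually the number of phases).
#' @param linkage hclust agglomeration method.
#' @param minSize minimum surviving module size.
#' @param datasetId label stored in the report.
#' @return a [ValidationReport-class].
#' @export
validateExternal <- function(zExt, selected, phases, C,
                             linkage = "average", minSize = 3L,
                             datasetId = "external") {
  zm <- .valueMatrix(zExt)
  mods <- moduleMembers(selected)
  trimmed <- lapply(mods, intersect, rownames(zm))
  lost <- sum(lengths(mods)) - sum(lengths(trimmed))
  if (lost > 0)
    warning(lost, " module member(s) missing from the external dataset")
  trimmed <- trimmed[lengths(trimmed) >= minSize]
  if (length(trimmed) == 0L)
    stop("no selected module retains >= ", minSize,
         " members in the external dataset")
  ms <- new("ModuleSet", modules = trimmed, params = selected@params)
  V <- .valueMatrix(computeResponsive(zm, ms))
  hc <- stats::hclust(stats::dist(t(V)), method = linkage)
  cl <- stats::cutree(hc, k = C)
  known <- phases[colnames(V)]
  if (anyNA(known)) stop("every external sample needs a phase label")
  ari <- mclust::adjustedRandIndex(cl, as.character(known))
  new("ValidationReport", datasetId = datasetId,
      modulesUsed = names(trimmed), tree = hc,
      clusters = as.integer(cl), nClusters = as.integer(C), ari = ari)
}
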