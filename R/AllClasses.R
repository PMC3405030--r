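#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Disjoint network modules
#'
#' A \code{ModuleSet} holds the disjoint node clusters ("modules") obtained by
#' decomposing an interaction network, together with the parameters that
#' produced them. Modules are named lists of member node identifiers.
#'
#' @slot modules named list; each element a character vector of member ids.
#' @slot params list recording provenance (e.g. MCL parameters).
#'
#' @seealso [mclCluster()], [filterModules()], [computeResponsive()]
#' @export
setClass("ModuleSet",
  representation(modules = "list", params = "list"),
  prototype(modules = list(), params = list())
)

setValidity("ModuleSet", function(object) {
  mods <- object@modules
  if (length(mods) == 0L) return(TRUE)
  if (is.null(names(mods)) || anyDuplicated(names(mods)))
    return("modules must be uniquely named")
  if (!all(vapply(mods, is.character, logical(1))))
    return("each module must be a character vector of member ids")
  if (any(vapply(mods, length, integer(1)) < 1L))
    return("empty module")
  all_members <- unlist(mods, use.names = FALSE)
  if (anyDuplicated(all_members))
    return("modules must be pairwise disjoint")
  TRUE
})

#' Condition system for module selection
#'
#' Stores the target sample partition, the alternative partitions it is
#' compared against, the per-module within-cluster sums of squares for every
#' partition, and the contribution matrix \eqn{A} with
#' \eqn{a_{kr} = w_k(\pi_r) - w_k(\pi_0)}. A binary module selection
#' \eqn{x} classifies the samples when every margin
#' \eqn{L_r(x) = \sum_k x_k a_{kr}} is non-negative.
#'
#' @slot moduleIds character vector of module identifiers (rows of \code{A}).
#' @slot target integer partition (canonical cluster labels) of the samples.
#' @slot alternatives list of integer partitions, excluding the target.
#' @slot wss numeric matrix, modules x (1 + alternatives); first column is the
#'   target partition's per-module within-cluster SSE.
#' @slot A contribution matrix, modules x alternatives.
#'
#' @seealso [buildConditions()], [solveExact()], [greedySelect()]
#' @export
setClass("ConditionSystem",
  representation(moduleIds = "character", target = "integer",
                 alternatives = "list", wss = "matrix", A = "matrix")
)

setValidity("ConditionSystem", function(object) {
  K <- length(object@moduleIds)
  R <- length(object@alternatives)
  if (nrow(object@A) != K || ncol(object@A) != R)
    return("A must be modules x alternatives")
  if (nrow(object@wss) != K || ncol(object@wss) != R + 1L)
    return("wss must be modules x (alternatives + 1)")
  if (!all(is.finite(object@A))) return("non-finite contribution")
  tkey <- paste(object@target, collapse = ",")
  akeys <- vapply(object@alternatives, paste, character(1), collapse = ",")
  if (tkey %in% akeys) return("target partition listed among alternatives")
  TRUE
})

#' Result of a module selection
#'
#' Produced by [greedySelect()] and [solveExact()]. For the greedy solver the
#' full ranking, per-prefix average power trace and chosen prefix length are
#' recorded; the exact solver fills only the selection, margins and
#' feasibility.
#'
#' @slot moduleIds module identifiers, parallel to \code{x}.
#' @slot x integer 0/1 selection vector.
#' @slot selected integer indices of selected modules.
#' @slot margins numeric vector \eqn{L_r} over the alternative partitions.
#' @slot feasible logical; TRUE when all margins are non-negative.
#' @slot ordering integer ranking of modules (greedy only; ascending score).
#' @slot scores numeric per-module scores \eqn{s_k = -\sum_r a_{kr}}
#'   (greedy only).
#' @slot powerTrace numeric average power \eqn{P(M_n)} for each prefix
#'   length (greedy only).
#' @slot nStar integer chosen prefix length (greedy only).
#' @slot method "greedy" or "exact".
#' @slot info list of free-form metadata (sample ids, partition mode, ...).
#' @export
setClass("SelectionResult",
  representation(moduleIds = "character", x = "integer", selected = "integer",
                 margins = "numeric", feasible = "logical",
                 ordering = "integer", scores = "numeric",
                 powerTrace = "numeric", nStar = "integer",
                 method = "character", info = "list"),
  prototype(ordering = integer(0), scores = numeric(0),
            powerTrace = numeric(0), nStar = NA_integer_, info = list())
)

setValidity("SelectionResult", function(object) {
  if (length(object@x) != length(object@moduleIds))
    return("x and moduleIds lengths differ")
  if (!all(object@x %in% c(0L, 1L))) return("x must be binary")
  if (!setequal(object@selected, which(object@x == 1L)))
    return("selected inconsistent with x")
  TRUE
})

#' Gene set collection (GMT)
#'
#' @slot setIds unique set identifiers.
#' @slot descriptions one description per set.
#' @slot members list of character vectors of member gene ids (non-empty).
#' @export
setClass("GeneSets",
  representation(setIds = "character", descriptions = "character",
                 members = "list")
)

setValidity("GeneSets", function(object) {
  if (anyDuplicated(object@setIds)) return("set ids must be unique")
  if (length(object@members) != length(object@setIds) ||
      length(object@descriptions) != length(object@setIds))
    return("slot lengths differ")
  if (any(vapply(object@members, length, integer(1)) == 0L))
    return("empty member list")
  TRUE
})

#' Synthetic study design
#'
#' Describes a condition x phase x replicate study over a planted-partition
#' network: module sizes, within/between edge probabilities, which planted
#' modules respond (mean shift \code{delta} in designated phenotype cells),
#' Gaussian noise level and the seed that makes the whole study
#' reproducible.
#'
#' @slot conditions condition names (e.g. control vs stimulus).
#' @slot phases ordered phase names.
#' @slot replicates biological replicates per (condition, phase) cell.
#' @slot moduleSizes planted module sizes.
#' @slot pIn within-module edge probability.
#' @slot pOut between-module edge probability (must be < pIn).
#' @slot responsivePlan named list: planted module id -> character vector of
#'   "condition:phase" cells receiving the shift.
#' @slot delta additive mean shift applied in the planned cells.
#' @slot sigma standard deviation of the Gaussian noise.
#' @slot seed integer seed (mandatory).
#' @seealso [studyDesign()], [makeStudy()]
#' @export
setClass("StudyDesign",
  representation(conditions = "character", phases = "character",
                 replicates = "integer", moduleSizes = "integer",
                 pIn = "numeric", pOut = "numeric",
                 responsivePlan = "list", delta = "numeric",
                 sigma = "numeric", seed = "integer")
)

setValidity("StudyDesign", function(object) {
  if (object@pIn <= object@pOut) return("pIn must exceed pOut")
  if (object@sigma <= 0) return("sigma must be positive")
  if (object@replicates < 1L) return("replicates must be >= 1")
  if (is.na(object@seed)) return("seed is mandatory")
  if (any(object@moduleSizes < 2L)) return("module sizes must be >= 2")
  cells <- paste(rep(object@conditions, each = length(object@phases)),
                 rep(object@phases, length(object@conditions)), sep = ":")
  bad <- setdiff(unlist(object@responsivePlan), cells)
  if (length(bad))
    return(paste("responsive plan names unknown cell:", bad[1]))
  TRUE
})

#' External validation report
#'
#' @slot datasetId identifier of the validation dataset.
#' @slot modulesUsed module ids whose responsive values were clustered.
#' @slot tree the hclust tree over samples.
#' @slot clusters integer cluster labels at the cut.
#' @slot nClusters number of clusters cut.
#' @slot ari adjusted Rand index versus the known phases.
#' @export
setClass("ValidationReport",
  representation(datasetId = "character", modulesUsed = "character",
                 tree = "ANY", clusters = "integer", nClusters = "integer",
                 ari = "numeric")
)

## ---- accessors & show ----

#' Module accessors
#'
#' @param x a \code{ModuleSet}.
#' @return \code{moduleIds}: character ids; \code{moduleSizes}: named integer
#'   sizes; \code{moduleMembers}: named list of member vectors.
#' @export
moduleIds <- function(x) names(x@modules)

#' @rdname moduleIds
#' @export
moduleSizes <- function(x) vapply(x@modules, length, integer(1))

#' @rdname moduleIds
#' @export
moduleMembers <- function(x) x@modules

#' @export
setMethod("length", "ModuleSet", function(x) length(x@modules))

#' @export
setMethod("show", "ModuleSet", function(object) {
  sz <- moduleSizes(object)
  cat("ModuleSet with", length(object), "modules\n")
  if (length(object)) {
    cat("  sizes:", if (length(sz) > 8)
      paste(c(head(sz, 8), "..."), collapse = " ") else
      paste(sz, collapse = " "), "\n")
  }
  if (length(object@params))
    cat("  params:", paste(names(object@params),
        unlist(lapply(object@params, format)), sep = "=", collapse = ", "),
        "\n")
})

#' @export
setMethod("length", "GeneSets", function(x) length(x@setIds))

#' @export
setMethod("show", "GeneSets", function(object) {
  cat("GeneSets with", length(object), "sets; sizes",
      paste(range(vapply(object@members, length, integer(1))),
            collapse = "-"), "\n")
})

#' @export
setMethod("show", "ConditionSystem", function(object) {
  cat("ConditionSystem:", length(object@moduleIds), "modules,",
      length(object@alternatives), "alternative partitions,",
      "C =", max(object@target), "\n")
})

#' Selected module indices and feasibility
#'
#' @param x a \code{SelectionResult}.
#' @return \code{selectedModules}: character ids of the selected modules;
#'   \code{isFeasible}: logical; \code{selectionMargins}: numeric margins.
#' @export
selectedModules <- function(x) x@moduleIds[x@selected]

#' @rdname selectedModules
#' @export
isFeasible <- function(x) x@feasible

#' @rdname selectedModules
#' @export
selectionMargins <- function(x) x@margins

#' @export
setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s): %d/%d modules selected, %s\n",
      object@method, length(object@selected), length(object@x),
      if (isTRUE(object@feasible)) "feasible" else "infeasible"))
  if (length(object@selected))
    cat("  selected:", paste(selectedModules(object), collapse = " "), "\n")
  if (length(object@margins))
    cat("  min margin:", format(min(object@margins)), "\n")
})

#' @export
setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", length(object@conditions), "conditions x",
      length(object@phases), "phases x", object@replicates, "replicates;",
      length(object@moduleSizes), "planted modules (",
      length(object@responsivePlan), "responsive ), seed", object@seed, "\n")
})

#' @export
setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport [", object@datasetId, "]: ",
      length(object@modulesUsed), " modules, C = ", object@nClusters,
      ", ARI = ", format(object@ari), "\n", sep = "")
})
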