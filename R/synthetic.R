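## Synthetic study generator with planted ground truth: a planted-partition
## interaction network plus an expression matrix in which designated modules
## carry additive mean shifts in designated (condition, phase) cells. All
## randomness comes from R's Mersenne-Twister stream, seeded from the design
## (global RNG state is saved and restored).

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Construct a synthetic study design
#'
#' Defaults emulate a two-condition x three-phase x two-replicate design
#' with ten planted modules, three of which respond. The default responsive
#' plan assigns each responsive module a distinct subset of phenotype cells
#' via a binary code, so that every pair of cells differs in at least one
#' responsive module: this makes the multi-classification identifiable from
#' the planted signal (with fewer discriminating modules than
#' \eqn{\lceil \log_2(\mathrm{cells}) \rceil} some cells would be
#' indistinguishable by construction and no selection could classify them).
#'
#' @param conditions condition names.
#' @param phases ordered phase names.
#' @param replicates replicates per (condition, phase) cell.
#' @param moduleSizes planted module sizes; default draws 10 sizes uniformly
#'   from 4..9 under the seed.
#' @param nResponsive how many planted modules respond (used only when
#'   \code{responsivePlan} is NULL).
#' @param responsivePlan named list planted-module-id -> "condition:phase"
#'   cells, or NULL for the binary-code default.
#' @param pIn,pOut within/between-module edge probabilities.
#' @param delta additive mean shift in the planned cells.
#' @param sigma Gaussian noise standard deviation.
#' @param seed mandatory integer seed.
#' @return a [StudyDesign-class].
#' @export
studyDesign <- function(conditions = c("control", "treated"),
                        phases = c("G1", "S", "G2M"),
                        replicates = 2L,
                        moduleSizes = NULL,
                        nResponsive = 3L,
                        responsivePlan = NULL,
                        pIn = 0.9, pOut = 0.02,
                        delta = 2, sigma = 1, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(moduleSizes))
    moduleSizes <- .withSeed(seed * 131L + 7L,
                             sample(4:9, 10L, replace = TRUE))
  nMod <- length(moduleSizes)
  modIds <- paste0("P", seq_len(nMod))
  if (is.null(responsivePlan)) {
    stopifnot(nResponsive >= 1L, nResponsive <= nMod)
    cells <- paste(rep(conditions, each = length(phases)),
                   rep(phases, length(conditions)), sep = ":")
    if (2^nResponsive - 1L < length(cells))
      stop("nResponsive = ", nResponsive, " cannot discriminate ",
           length(cells), " phenotype cells; need at least ",
           ceiling(log2(length(cells) + 1)))
    # non-zero codewords: distinct codes make every cell pair separable,
    # and every cell carries at least one active module
    responsivePlan <- lapply(seq_len(nResponsive), function(b)
      cells[bitwAnd(seq_along(cells), bitwShiftL(1L, b - 1L)) > 0])
    names(responsivePlan) <- modIds[seq_len(nResponsive)]
  }
  new("StudyDesign", conditions = conditions, phases = phases,
      replicates = as.integer(replicates),
      moduleSizes = as.integer(moduleSizes),
      pIn = pIn, pOut = pOut, responsivePlan = responsivePlan,
      delta = delta, sigma = sigma, seed = as.integer(seed))
}

#' Generate the planted-partition network of a study design
#'
#' Each within-module node pair is an edge with probability \code{pIn},
#' each between-module pair with probability \code{pOut}. Deterministic
#' under the design's seed.
#'
#' @param design a [StudyDesign-class].
#' @return list with \code{network} (igraph, all planted nodes as vertices)
#'   and \code{truth} (list: \code{modules} a [ModuleSet-class] of the
#'   planted modules, \code{plan} the realized responsive plan,
#'   \code{design} the design).
#' @export
makeNetwork <- function(design) {
  sizes <- design@moduleSizes
  n <- sum(sizes)
  genes <- sprintf("G%03d", seq_len(n))
  block <- rep(seq_along(sizes), sizes)
  .withSeed(design@seed, {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    prob <- ifelse(block[pairs[, 1L]] == block[pairs[, 2L]],
                   design@pIn, design@pOut)
    keep <- stats::runif(nrow(pairs)) < prob
    el <- cbind(genes[pairs[keep, 1L]], genes[pairs[keep, 2L]])
    g <- if (nrow(el) > 0L)
      igraph::graph_from_edgelist(el, directed = FALSE)
    else igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g),
                              name = setdiff(genes, igraph::V(g)$name))
    mods <- split(genes, block)
    names(mods) <- paste0("P", seq_along(mods))
    list(network = g,
         truth = list(modules = new("ModuleSet", modules = mods,
                                    params = list(planted = TRUE,
                                                  pIn = design@pIn,
                                                  pOut = design@pOut)),
                      plan = design@responsivePlan,
                      design = design))
  })
}

#' Generate the expression matrix of a study design
#'
#' One sample per (condition, phase, replicate); each gene value is
#' Gaussian noise \eqn{N(0, \sigma^2)} plus \code{delta} for genes of a
#' responsive module in its planned cells. Sample ids are
#' \code{condition.phase.R<rep>}; labels are \code{condition:phase}.
#' Deterministic under the design's seed (an independent sub-stream from
#' the network's; pass \code{seedOffset} to draw a fresh replicate study
#' from the same truth).
#'
#' @param design a [StudyDesign-class].
#' @param truth the truth list from [makeNetwork()].
#' @param seedOffset added to the expression sub-seed (default 0).
#' @return list with \code{expression} (SummarizedExperiment, assay
#'   \code{"exprs"}, colData column \code{phenotype}) and \code{labels}
#'   (named character vector sample -> "condition:phase").
#' @export
makeExpression <- function(design, truth, seedOffset = 0L) {
  genes <- unlist(moduleMembers(truth$modules), use.names = FALSE)
  cells <- paste(rep(design@conditions, each = length(design@phases)),
                 rep(design@phases, length(design@conditions)), sep = ":")
  samples <- as.vector(vapply(cells, function(cell)
    paste0(sub(":", ".", cell, fixed = TRUE), ".R",
           seq_len(design@replicates)),
    character(design@replicates)))
  labels <- rep(cells, each = design@replicates)
  names(labels) <- samples
  vals <- .withSeed(design@seed + 1L + seedOffset,
    matrix(stats::rnorm(length(genes) * length(samples), 0, design@sigma),
           length(genes), length(samples),
           dimnames = list(genes, samples)))
  for (mid in names(truth$plan)) {
    members <- moduleMembers(truth$modules)[[mid]]
    shifted <- labels %in% truth$plan[[mid]]
    vals[members, shifted] <- vals[members, shifted] + design@delta
  }
  se <- SummarizedExperiment(
    assays = list(exprs = vals),
    colData = DataFrame(phenotype = unname(labels), row.names = samples))
  list(expression = se, labels = labels)
}

#' Generate a complete synthetic study
#'
#' Composes [makeNetwork()] and [makeExpression()]; optionally writes the
#' bundle to a directory in the package's standard text formats
#' (\code{expression.tsv}, \code{network.tsv}, \code{labels.tsv},
#' \code{truth.json}) so it can feed the pipeline end to end.
#'
#' @param design a [StudyDesign-class].
#' @param dir optional output directory (created if needed).
#' @return list with \code{network}, \code{expression}, \code{labels},
#'   \code{truth} and \code{design}.
#' @export
makeStudy <- function(design, dir = NULL) {
  net <- makeNetwork(design)
  expr <- makeExpression(design, net$truth)
  bundle <- list(network = net$network, expression = expr$expression,
                 labels = expr$labels, truth = net$truth, design = design)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeExpression(bundle$expression, file.path(dir, "expression.tsv"))
    writeNetwork(bundle$network, file.path(dir, "network.tsv"))
    writeLabels(bundle$labels, file.path(dir, "labels.tsv"))
    jsonlite::write_json(
      list(modules = moduleMembers(net$truth$modules),
           plan = net$truth$plan,
           params = list(pIn = design@pIn, pOut = design@pOut,
                         delta = design@delta, sigma = design@sigma,
                         replicates = design@replicates,
                         seed = design@seed)),
      file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE,
      pretty = TRUE)
  }
  bundle
}
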