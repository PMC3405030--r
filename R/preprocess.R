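## Probe collapsing, one-way ANOVA pre-filter, per-gene z-transformation and
## restriction of the interaction network to measured genes.

#' Average rows that share a gene id
#'
#' Microarray platforms often carry several probe sets per gene; rows with
#' identical gene ids are replaced by their element-wise arithmetic mean.
#' Row order follows the first occurrence of each id.
#'
#' @param expr SummarizedExperiment (assay \code{"exprs"}) or numeric matrix
#'   with gene ids as row names.
#' @return object of the same kind with one row per gene id.
#' @export
collapseProbes <- function(expr) {
  m <- .valueMatrix(expr)
  ids <- rownames(m)
  if (!anyDuplicated(ids)) return(expr)
  f <- factor(ids, levels = unique(ids))
  sums <- rowsum(m, f, reorder = FALSE)
  out <- sums / as.vector(table(f))
  .likeInput(expr, out, assayName = "exprs")
}

.likeInput <- function(template, m, assayName) {
  if (is(template, "SummarizedExperiment")) {
    a <- list(m); names(a) <- assayName
    SummarizedExperiment(assays = a,
                         colData = colData(template)[colnames(m), ,
                                                     drop = FALSE])
  } else m
}

#' One-way ANOVA differential-expression filter
#'
#' Retains genes whose one-way F test across the phenotype groups has
#' p-value below \code{alpha}. The F statistic is the classical
#' between/within mean-square ratio with degrees of freedom
#' \eqn{(G-1, m-G)}. Genes with zero total variance are removed (with a
#' message) before testing: they carry no evidence either way.
#'
#' @param expr SummarizedExperiment or numeric matrix, genes x samples.
#' @param groups named character vector sample id -> group label covering
#'   every column (a plain vector parallel to the columns also works).
#' @param alpha retention threshold on the raw p-value, in (0, 1).
#' @return the filtered object; per-gene F and p values of the retained
#'   genes are attached as attribute \code{"anova"} (matrix with columns
#'   \code{F} and \code{p}).
#' @examples
#' m <- rbind(flat = rep(1, 4), shifted = c(0, 0, 8, 8))
#' colnames(m) <- paste0("s", 1:4)
#' g <- c(s1 = "a", s2 = "a", s3 = "b", s4 = "b")
#' rownames(anovaFilter(m, g, alpha = 0.05))
#' @export
anovaFilter <- function(expr, groups, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  m <- .valueMatrix(expr)
  g <- .alignGroups(groups, colnames(m))
  G <- nlevels(g)
  n <- ncol(m)
  if (G < 2L) stop("ANOVA filter needs at least two phenotype groups")
  if (n == G) stop("no within-group degrees of freedom (one sample per group)")

  totvar <- rowSums((m - rowMeans(m))^2)
  const <- totvar <= .Machine$double.eps * n
  if (any(const)) {
    message("removed ", sum(const), " zero-variance gene(s) before ANOVA")
    m <- m[!const, , drop = FALSE]
    totvar <- totvar[!const]
  }
  if (nrow(m) == 0L) stop("no gene with nonzero variance")

  counts <- as.vector(table(g))
  gsum <- rowsum(t(m), g, reorder = TRUE)        # G x genes group sums
  gmean <- gsum / counts
  grand <- rowMeans(m)
  ssb <- as.vector(counts %*% (gmean - matrix(grand, nrow = G,
                                              ncol = length(grand),
                                              byrow = TRUE))^2)
  ssw <- totvar - ssb
  ssw[ssw < 0] <- 0  # numerical guard
  Fstat <- (ssb / (G - 1)) / (ssw / (n - G))
  p <- stats::pf(Fstat, G - 1, n - G, lower.tail = FALSE)
  keep <- is.finite(p) & p < alpha
  # infinite F (ssw == 0 with ssb > 0) is maximal evidence: keep
  keep[!is.finite(Fstat) | ssw == 0] <- TRUE
  out <- .likeInput(expr, m[keep, , drop = FALSE], assayName = "exprs")
  attr(out, "anova") <- cbind(F = Fstat[keep], p = p[keep])
  out
}

.alignGroups <- function(groups, sample_ids) {
  if (!is.null(names(groups))) {
    missing <- setdiff(sample_ids, names(groups))
    if (length(missing))
      stop("no phenotype label for sample(s): ",
           paste(missing, collapse = ", "))
    extra <- setdiff(names(groups), sample_ids)
    if (length(extra))
      warning("label(s) for sample(s) absent from the expression matrix: ",
              paste(extra, collapse = ", "))
    groups <- groups[sample_ids]
  } else if (length(groups) != length(sample_ids)) {
    stop("groups must be named by sample id or parallel to the columns")
  }
  factor(as.character(groups))
}

#' Per-gene z-transformation
#'
#' Standardizes each gene over all samples:
#' \eqn{z_{ij} = (g_{ij} - \mu_i)/\sigma_i} with \eqn{\sigma_i} the sample
#' standard deviation (\eqn{m-1} denominator). Rows must have nonzero
#' variance; run [anovaFilter()] (or drop constant rows) first.
#'
#' @param expr SummarizedExperiment or matrix, genes x samples.
#' @return object of the same kind with assay \code{"z"}; every row has
#'   mean 0 and standard deviation 1.
#' @export
zTransform <- function(expr) {
  m <- .valueMatrix(expr)
  if (ncol(m) < 2L) stop("z-transformation needs at least two samples")
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  if (any(sdv == 0))
    stop("zero-variance row(s) reached z-transformation: ",
         paste(utils::head(rownames(m)[sdv == 0], 5), collapse = ", "),
         "; filter constant genes first")
  z <- (m - mu) / sdv
  .likeInput(expr, z, assayName = "z")
}

#' Restrict a network to measured genes
#'
#' Keeps exactly the edges whose both endpoints appear among the row names
#' of the (z-transformed) expression object; nodes left without any edge are
#' dropped.
#'
#' @param net igraph network.
#' @param z SummarizedExperiment or matrix whose row names are the measured
#'   gene ids.
#' @return the induced igraph subnetwork.
#' @export
restrictToMeasured <- function(net, z) {
  measured <- rownames(.valueMatrix(z))
  keep <- intersect(igraph::V(net)$name, measured)
  g <- igraph::induced_subgraph(net, keep)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  if (igraph::vcount(g) == 0L || igraph::ecount(g) == 0L)
    stop("no interaction with both endpoints measured; ",
         "check that network and expression use the same gene id namespace")
  dropped <- igraph::vcount(net) - igraph::vcount(g)
  if (dropped > 0)
    message("restricted network: dropped ", dropped,
            " node(s) unmeasured or isolated")
  g
}
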