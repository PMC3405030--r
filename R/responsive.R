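#' Combined z-score responsive matrix
#'
#' Maps per-gene z-scores onto modules: the responsive value of module
#' \eqn{k} in sample \eqn{j} is the combined z-score
#' \deqn{v_{kj} = \frac{1}{\sqrt{m_k}} \sum_{i \in k} z_{ij},}
#' where \eqn{m_k} is the number of proteins in the module. Under
#' independent standard-normal member scores each \eqn{v_{kj}} is itself
#' standard normal, so module activities are comparable across module sizes.
#'
#' @param z SummarizedExperiment (assay \code{"z"}) or numeric matrix of
#'   per-gene z-scores, genes x samples.
#' @param ms a [ModuleSet-class]; every member must be present among the
#'   rows of \code{z} (run [filterModules()] first).
#' @return a SummarizedExperiment with assay \code{"responsive"}
#'   (modules x samples), carrying over the sample annotation of \code{z}.
#' @examples
#' z <- rbind(g1 = c(1, 0), g2 = c(1, 0))
#' colnames(z) <- c("s1", "s2")
#' ms <- new("ModuleSet", modules = list(M1 = c("g1", "g2")))
#' SummarizedExperiment::assay(computeResponsive(z, ms))
#' @export
computeResponsive <- function(z, ms) {
  zm <- .valueMatrix(z)
  mods <- moduleMembers(ms)
  memb <- unlist(mods, use.names = FALSE)
  ridx <- match(memb, rownames(zm))
  if (anyNA(ridx)) {
    grp <- rep(names(mods), lengths(mods))
    bad <- which(is.na(ridx))[1L]
    stop("module ", grp[bad], " member missing from z-scores: ", memb[bad])
  }
  grp <- rep(seq_along(mods), lengths(mods))
  V <- rowsum(zm[ridx, , drop = FALSE], grp, reorder = TRUE) /
    sqrt(lengths(mods))
  dimnames(V) <- list(names(mods), colnames(zm))
  if (is(z, "SummarizedExperiment"))
    SummarizedExperiment(assays = list(responsive = V),
                         colData = colData(z))
  else
    SummarizedExperiment(assays = list(responsive = V))
}
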