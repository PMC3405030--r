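## Readers/writers for the delimited-text formats. Everything downstream
## consumes the in-memory containers built here: SummarizedExperiment for
## gene x sample matrices, igraph for the interaction network, a named
## character vector for sample -> phenotype labels.

#' Read a gene x sample expression matrix
#'
#' The file must have a header row of sample ids and a first column of gene
#' ids; all remaining cells must parse as reals (no missing values).
#' Duplicate gene ids are retained as separate rows and collapsed later by
#' [collapseProbes()].
#'
#' @param path path to a delimited text file.
#' @param delimiter field separator (default tab).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{"exprs"}; row names are gene ids (possibly duplicated), column
#'   names sample ids.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "G1\t1\t2", "G2\t3\t4"), tf)
#' se <- readExpression(tf)
#' dim(se)
#' @export
readExpression <- function(path, delimiter = "\t") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("expression file must have a header and at least one gene row: ",
         path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  ncols <- lengths(fields)
  header <- fields[[1L]]
  # header may or may not carry a corner label for the gene-id column
  body_width <- ncols[2L]
  if (any(ncols[-1L] != body_width))
    stop("ragged rows in ", path, ": row ",
         which(ncols[-1L] != body_width)[1L] + 1L, " has ",
         ncols[-1L][which(ncols[-1L] != body_width)[1L]],
         " fields, expected ", body_width)
  sample_ids <- if (length(header) == body_width) header[-1L] else header
  if (length(sample_ids) != body_width - 1L)
    stop("header of ", path, " has ", length(header),
         " fields but data rows have ", body_width)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in header of ", path)
  gene_ids <- vapply(fields[-1L], `[`, character(1), 1L)
  vals <- matrix(NA_real_, length(gene_ids), length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(gene_ids)) {
    row <- suppressWarnings(as.numeric(fields[[i + 1L]][-1L]))
    if (anyNA(row)) {
      j <- which(is.na(row))[1L]
      stop("non-numeric cell '", fields[[i + 1L]][j + 1L],
           "' at gene row ", i, " (", gene_ids[i], "), sample column ", j,
           " (", sample_ids[j], ") in ", path)
    }
    vals[i, ] <- row
  }
  SummarizedExperiment(assays = list(exprs = vals))
}

#' @rdname readExpression
#' @param x a SummarizedExperiment (or plain numeric matrix with dimnames).
#' @param assayName which assay to write when \code{x} carries several.
#' @export
writeExpression <- function(x, path, delimiter = "\t", assayName = 1L) {
  m <- .valueMatrix(x, assayName)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(m)), collapse = delimiter), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i],
            format(m[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = delimiter), character(1))
  writeLines(body, con)
  invisible(path)
}

.valueMatrix <- function(x, assayName = 1L) {
  if (is(x, "SummarizedExperiment")) assay(x, assayName)
  else if (is.matrix(x)) x
  else stop("expected a SummarizedExperiment or matrix")
}

#' Read an undirected interaction network from an edge list
#'
#' Each non-empty line must contain at least two whitespace- or tab-separated
#' fields (source, target); extra columns such as weights are ignored (the
#' model is unweighted). Duplicate edges are merged and self-loops dropped
#' with a message.
#'
#' @param path path to the edge-list file.
#' @return an undirected, simple [igraph::graph] object.
#' @export
readNetwork <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty network file: ", path)
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("network line ", bad[1L], " has fewer than two columns: '",
         lines[bad[1L]], "'")
  el <- t(vapply(fields, function(f) f[1:2], character(2)))
  loops <- el[, 1L] == el[, 2L]
  if (any(loops))
    message("dropped ", sum(loops), " self-loop(s)")
  el <- el[!loops, , drop = FALSE]
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  ndup <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::ecount(g) < ndup)
    message("merged ", ndup - igraph::ecount(g), " duplicate edge(s)")
  g
}

#' @rdname readNetwork
#' @param net an igraph object.
#' @export
writeNetwork <- function(net, path) {
  el <- igraph::as_edgelist(net)
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Read a sample -> phenotype label table
#'
#' Two-column delimited text, sample id then phenotype label, no header.
#'
#' @param path path to the label file.
#' @param delimiter field separator.
#' @return named character vector: names are sample ids, values phenotype
#'   labels.
#' @export
readLabels <- function(path, delimiter = "\t") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("label line ", which(lengths(fields) < 2L)[1L],
         " needs two columns")
  labs <- vapply(fields, `[`, character(1), 2L)
  names(labs) <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names(labs)))
    stop("duplicate sample id in label file: ",
         names(labs)[duplicated(names(labs))][1L])
  labs
}

#' @rdname readLabels
#' @param labels named character vector.
#' @export
writeLabels <- function(labels, path, delimiter = "\t") {
  writeLines(paste(names(labels), labels, sep = delimiter), path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, fields set id, description, then member
#' gene ids.
#'
#' @param path path to the GMT file.
#' @return a [GeneSets-class] object.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("GMT line ", which(lengths(fields) < 3L)[1L],
         " must have id, description and at least one member")
  new("GeneSets",
      setIds = vapply(fields, `[`, character(1), 1L),
      descriptions = vapply(fields, `[`, character(1), 2L),
      members = lapply(fields, function(f) f[-(1:2)]))
}

#' Write / read a selection report
#'
#' Serializes a [SelectionResult-class] as JSON (module ids, ranking,
#' scores, power trace, selection vector, margins, feasibility) so a run can
#' be archived and re-loaded field-identically.
#'
#' @param result a \code{SelectionResult}.
#' @param path output path.
#' @export
writeReport <- function(result, path) {
  rep <- list(
    method = result@method,
    module_ids = result@moduleIds,
    x = result@x,
    selected = result@selected,
    selected_ids = selectedModules(result),
    margins = result@margins,
    feasible = result@feasible,
    ordering = result@ordering,
    scores = result@scores,
    power_trace = result@powerTrace,
    n_star = result@nStar
  )
  jsonlite::write_json(rep, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read a module membership table
#'
#' Two-column table of (module_id, member) rows.
#'
#' @param ms a \code{ModuleSet}.
#' @param path output path.
#' @export
writeModuleTable <- function(ms, path) {
  ids <- rep(moduleIds(ms), moduleSizes(ms))
  writeLines(c("module\tmember",
               paste(ids, unlist(moduleMembers(ms)), sep = "\t")), path)
  invisible(path)
}

#' @rdname writeModuleTable
#' @export
readModuleTable <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
  mods <- split(tab$member, factor(tab$module, levels = unique(tab$module)))
  new("ModuleSet", modules = mods, params = list(source = path))
}
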