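#' Areal adjacency graph
#'
#' Container for the neighbourhood structure of a set of areas (e.g. the 47
#' Kenyan counties). Edges are undirected, stored once with the smaller index
#' first; self-edges are rejected and duplicates collapsed.
#'
#' @param area_ids character vector of unique area labels, order fixed.
#' @param edges two-column matrix (or data.frame) of area labels or 1-based
#'   indices, one row per undirected neighbour pair.
#' @return An object of class \code{area_graph} with elements
#'   \code{area_ids}, \code{edges} (integer matrix, column-wise \code{i < j}),
#'   \code{n_areas} and \code{degree}.
#' @examples
#' g <- area_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' g$degree
#' @export
area_graph <- function(area_ids, edges) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) stop("duplicate area labels")
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  if (is.character(edges)) {
    idx <- match(edges, area_ids)
    if (anyNA(idx)) {
      bad <- unique(edges[is.na(idx)])
      stop("unknown area label(s) in edges: ", paste(bad, collapse = ", "))
    }
    edges <- matrix(idx, ncol = 2L)
  }
  storage.mode(edges) <- "integer"
  n <- length(area_ids)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L | edges > n)) stop("edge index out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-edges are not allowed")
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  degree <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n)
  structure(
    list(area_ids = area_ids, edges = edges, n_areas = n, degree = degree),
    class = "area_graph"
  )
}

#' @export
print.area_graph <- function(x, ...) {
  cat("area_graph: ", x$n_areas, " areas, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Per-area neighbour lists
#' @param graph an \code{area_graph}.
#' @return list of integer vectors, one per area.
#' @export
neighbour_list <- function(graph) {
  stopifnot(inherits(graph, "area_graph"))
  nb <- vector("list", graph$n_areas)
  for (a in seq_len(graph$n_areas)) nb[[a]] <- integer(0)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    i <- e[r, 1L]; j <- e[r, 2L]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

#' Read an areal adjacency structure from text
#'
#' Two dialects are accepted: a plain whitespace edge list (two labels per
#' line, \code{#} comments allowed; area order fixed by first appearance) and
#' the GAL spatial-weights format (a header line whose last/only count token
#' gives the number of areas, then for each area a line \code{label degree}
#' followed by a line listing its neighbours). A GAL file must list every
#' neighbour pair in both directions.
#'
#' @param source path to the file.
#' @param format \code{"auto"} (default), \code{"edgelist"} or \code{"gal"}.
#' @return an \code{\link{area_graph}}.
#' @export
read_adjacency <- function(source, format = c("auto", "edgelist", "gal")) {
  format <- match.arg(format)
  if (!file.exists(source)) stop("adjacency file not found: ", source)
  lines <- readLines(source, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("adjacency file is empty: ", source)
  if (format == "auto") {
    tok1 <- strsplit(lines[1L], "\\s+")[[1L]]
    n1 <- suppressWarnings(as.numeric(tok1))
    ## GAL header: a lone count, or the classic "0 n <file> <key>" line
    format <- if ((length(tok1) == 1L && !is.na(n1)) ||
                  (length(tok1) >= 2L && identical(tok1[1L], "0") &&
                     !is.na(n1[2L]))) "gal" else "edgelist"
  }
  if (format == "edgelist") read_edgelist_lines(lines) else read_gal_lines(lines)
}

read_edgelist_lines <- function(lines) {
  toks <- strsplit(lines, "\\s+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad)) stop("edge list line ", bad[1L], " does not have two labels")
  m <- do.call(rbind, toks)
  ids <- unique(as.vector(t(m)))
  area_graph(ids, m)
}

read_gal_lines <- function(lines) {
  head_tok <- strsplit(lines[1L], "\\s+")[[1L]]
  n <- as.integer(head_tok[if (length(head_tok) == 1L) 1L else 2L])
  if (is.na(n) || n < 1L) stop("cannot parse GAL header line")
  body <- lines[-1L]
  if (length(body) != 2L * n)
    stop("GAL body has ", length(body), " lines; expected ", 2L * n)
  ids <- character(n)
  nbrs <- vector("list", n)
  for (a in seq_len(n)) {
    hd <- strsplit(body[2L * a - 1L], "\\s+")[[1L]]
    ids[a] <- hd[1L]
    deg <- as.integer(hd[2L])
    nb <- strsplit(body[2L * a], "\\s+")[[1L]]
    if (!is.na(deg) && length(nb) != deg)
      stop("GAL area ", ids[a], " declares degree ", deg,
           " but lists ", length(nb), " neighbours")
    nbrs[[a]] <- nb
  }
  if (anyDuplicated(ids)) stop("duplicate area labels in GAL file")
  unknown <- setdiff(unique(unlist(nbrs)), ids)
  if (length(unknown))
    stop("unknown area label(s) in GAL neighbour lists: ",
         paste(unknown, collapse = ", "))
  ## symmetry check, then collapse to undirected edges
  for (a in seq_len(n)) {
    for (b in nbrs[[a]]) {
      bi <- match(b, ids)
      if (!(ids[a] %in% nbrs[[bi]]))
        stop("asymmetric GAL listing: ", ids[a], " -> ", b,
             " has no reverse entry")
    }
  }
  edges <- do.call(rbind, lapply(seq_len(n), function(a) {
    if (length(nbrs[[a]]) == 0L) return(NULL)
    cbind(ids[a], nbrs[[a]])
  }))
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2L)
  area_graph(ids, edges)
}

#' Write an adjacency structure as an edge list
#' @param graph an \code{area_graph}.
#' @param path output file path.
#' @export
write_adjacency <- function(graph, path) {
  stopifnot(inherits(graph, "area_graph"))
  e <- graph$edges
  lines <- paste(graph$area_ids[e[, 1L]], graph$area_ids[e[, 2L]])
  writeLines(lines, path)
  invisible(path)
}

#' Intrinsic CAR precision structure
#'
#' Builds the unscaled ICAR precision matrix \eqn{Q = D - W} (degree matrix
#' minus adjacency matrix) for an areal graph, together with the number of
#' connected components and the rank \eqn{n - c} of \eqn{Q}. All row sums of
#' \eqn{Q} are zero and \eqn{w'Qw = \sum_{i \sim j} (w_i - w_j)^2}.
#'
#' @param graph an \code{area_graph} with at least two areas.
#' @return object of class \code{icar_structure}: \code{precision_unscaled},
#'   \code{n_components}, \code{rank}, \code{component} (per-area membership)
#'   and the originating \code{graph}.
#' @export
build_icar_structure <- function(graph) {
  stopifnot(inherits(graph, "area_graph"))
  n <- graph$n_areas
  if (n < 2L) stop("need at least two areas")
  Q <- matrix(0, n, n, dimnames = list(graph$area_ids, graph$area_ids))
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    i <- e[r, 1L]; j <- e[r, 2L]
    Q[i, j] <- Q[i, j] - 1
    Q[j, i] <- Q[j, i] - 1
  }
  diag(Q) <- graph$degree
  if (any(graph$degree == 0L))
    warning("isolated area(s): ",
            paste(graph$area_ids[graph$degree == 0L], collapse = ", "),
            "; their frailty is identified only through the sum-to-zero constraint")
  comp <- graph_components(graph)
  structure(
    list(precision_unscaled = Q,
         n_components = max(comp),
         rank = n - max(comp),
         component = comp,
         graph = graph),
    class = "icar_structure"
  )
}

## connected-component labelling via igraph
graph_components <- function(graph) {
  ig <- igraph::make_empty_graph(n = graph$n_areas, directed = FALSE)
  if (nrow(graph$edges) > 0L)
    ig <- igraph::add_edges(ig, t(graph$edges))
  as.integer(igraph::components(ig)$membership)
}

#' ICAR log prior density of a frailty vector
#'
#' Pairwise-difference (intrinsic) Gaussian Markov random field density on
#' the contrast space:
#' \deqn{\log p(w \mid \sigma^2) = -\frac{r}{2}\log(2\pi\sigma^2)
#'   - \frac{1}{2\sigma^2} w' Q w,}
#' with \eqn{r} the rank of \eqn{Q} (areas minus connected components). The
#' generalised determinant of \eqn{Q}, constant in both \eqn{w} and
#' \eqn{\sigma^2}, is omitted. The density is invariant to adding a constant
#' to all frailties.
#'
#' @param frailties numeric vector, one value per area.
#' @param variance the conditional variance parameter \eqn{\sigma^2 > 0}.
#' @param structure an \code{\link{build_icar_structure}} result.
#' @return scalar log density.
#' @export
icar_log_density <- function(frailties, variance, structure) {
  stopifnot(inherits(structure, "icar_structure"))
  n <- nrow(structure$precision_unscaled)
  if (length(frailties) != n)
    stop("frailty vector length ", length(frailties), " != n_areas ", n)
  if (!is.numeric(variance) || length(variance) != 1L || variance <= 0)
    stop("variance must be a positive scalar")
  quad <- icar_quad_form(frailties, structure)
  -(structure$rank / 2) * log(2 * pi * variance) - quad / (2 * variance)
}

## w'Qw as the sum of squared differences over edges (O(|E|))
icar_quad_form <- function(frailties, structure) {
  e <- structure$graph$edges
  if (nrow(e) == 0L) return(0)
  sum((frailties[e[, 1L]] - frailties[e[, 2L]])^2)
}
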