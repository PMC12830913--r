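# Spiral-with-crosslinks temporal graph over (day, hour) cells.

#' Build the temporal graph over (day, hour) cells
#'
#' Nodes are the 24 hours of every listed day, ordered row-major by day then
#' hour. Each hour is connected to the previous and next hour of the same
#' day; the final hour of a day is connected to the first hour of the next
#' day, and every hour is connected to the same hour on the adjacent days —
#' but only when the next listed day is the calendar day immediately after.
#' Conceptually a spiral of hours with day-to-day crosslinks. Days absent
#' from the list create no edges, so gaps in the record disconnect the graph
#' and stop information flowing across them.
#'
#' @param days strictly increasing `Date` vector (duplicates are an error).
#' @param hour_weight,day_weight edge weights for within-day (hour-to-hour,
#'   including the midnight wrap) and day-to-day crosslink edges; both
#'   default to 1 (a single connection type).
#' @return A `time_graph`: list with `nodes` (data.frame of day, hour,
#'   index), `edges` (two-column index matrix), `weights`, and the number of
#'   days. Use [laplacian()] for the graph Laplacian.
#' @examples
#' g <- build_time_graph(as.Date("2024-01-01") + 0:1)
#' nrow(g$edges)  # 71
#' @export
build_time_graph <- function(days, hour_weight = 1, day_weight = 1) {
  days <- as.Date(days)
  if (anyDuplicated(days)) stop("duplicate dates in day grid")
  if (is.unsorted(days, strictly = TRUE)) stop("days must be strictly increasing")
  nd <- length(days)
  n <- nd * 24L
  idx <- function(d, h) (d - 1L) * 24L + h + 1L  # d 1-based, h 0-based

  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (d in seq_len(nd)) {
    # within-day chain h0-h1-...-h23
    from <- c(from, idx(d, 0:22)); to <- c(to, idx(d, 1:23))
    w <- c(w, rep(hour_weight, 23))
    if (d < nd && days[d + 1L] == days[d] + 1L) {
      # midnight wrap: last hour of d to first hour of d+1
      from <- c(from, idx(d, 23)); to <- c(to, idx(d + 1L, 0))
      w <- c(w, hour_weight)
      # crosslinks: same hour on adjacent days
      from <- c(from, idx(d, 0:23)); to <- c(to, idx(d + 1L, 0:23))
      w <- c(w, rep(day_weight, 24))
    }
  }
  nodes <- data.frame(index = seq_len(n),
                      date = rep(days, each = 24),
                      hour = rep(0:23, nd))
  structure(list(nodes = nodes, edges = cbind(from, to), weights = w,
                 days = days),
            class = "time_graph")
}

#' Graph Laplacian of a time graph
#'
#' Combinatorial Laplacian L = D - A (degree minus adjacency), returned as a
#' sparse symmetric matrix. L is positive semi-definite; its null space is
#' spanned by the indicator vectors of the connected components, so a
#' quadratic form v'Lv sums weighted squared differences across edges.
#'
#' @param graph a `time_graph` from [build_time_graph()].
#' @return A sparse `dgCMatrix` of dimension (24 x days)^2.
#' @export
laplacian <- function(graph) {
  stopifnot(inherits(graph, "time_graph"))
  n <- nrow(graph$nodes)
  e <- graph$edges
  a <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = c(graph$weights, graph$weights),
                            dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(a)) - a
}

#' Number of connected components of a time graph
#'
#' Equal to the number of maximal runs of consecutive calendar days, since
#' every within-run block is connected and no edge crosses a missing day.
#'
#' @param graph a `time_graph`.
#' @return Integer component count.
#' @export
n_components <- function(graph) {
  stopifnot(inherits(graph, "time_graph"))
  d <- graph$days
  if (length(d) == 0) return(0L)
  1L + sum(diff(as.integer(d)) > 1L)
}

#' Per-node component labels of a time graph
#'
#' @param graph a `time_graph`.
#' @return Integer vector, one label (1-based, in day order) per node.
#' @export
component_labels <- function(graph) {
  d <- graph$days
  runs <- c(1L, cumsum(diff(as.integer(d)) > 1L) + 1L)
  rep(runs, each = 24L)
}

#' @export
print.time_graph <- function(x, ...) {
  cat(sprintf("Time graph: %d days, %d nodes, %d edges, %d component(s)\n",
              length(x$days), nrow(x$nodes), nrow(x$edges), n_components(x)))
  invisible(x)
}

#' Export a time graph as an edge-list CSV
#'
#' Writes one row per undirected edge with node indices and their
#' (date, hour) labels, for inspection.
#'
#' @param graph a `time_graph`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_edges_csv <- function(graph, path) {
  e <- graph$edges
  nd <- graph$nodes
  out <- data.frame(from = e[, 1], to = e[, 2],
                    from_date = nd$date[e[, 1]], from_hour = nd$hour[e[, 1]],
                    to_date = nd$date[e[, 2]], to_hour = nd$hour[e[, 2]],
                    weight = graph$weights)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
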