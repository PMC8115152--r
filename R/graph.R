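#' H-depleted molecular graph with simple and valence vertex degrees
#'
#' Builds the hydrogen-depleted graph of a molecule: vertices are the heavy
#' atoms, edges the bonds between them. For every vertex the simple vertex
#' degree \eqn{\delta} (number of bonded heavy atoms) and the Kier-Hall
#' valence vertex degree \eqn{\delta^v} are computed. For second-row atoms
#' \eqn{\delta^v = Z^v - h} (valence electrons minus attached hydrogens);
#' for heavier heteroatoms \eqn{\delta^v = (Z^v - h) / (Z - Z^v - 1)}.
#' Neither quantity depends on bond orders, so kekulized aromatic systems
#' are handled identically to their aromatic forms.
#'
#' @param mol A \code{"molecule"} object from \code{\link{parse_smiles}}.
#' @return An object of class \code{"hgraph"}: list with \code{n} (vertex
#'   count), \code{adj} (list of integer neighbour vectors), \code{delta}
#'   and \code{delta_v} (numeric vectors), and \code{elements}.
#' @export
heavy_graph <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  n <- nrow(mol$atoms)
  adj <- rep(list(integer(0)), n)
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  delta <- vapply(adj, length, integer(1))

  el <- mol$atoms$element
  zv <- .VALENCE_ELECTRONS[el]
  z <- .ATOMIC_NUMBER[el]
  h <- mol$atoms$nh
  delta_v <- ifelse(z <= 9, zv - h, (zv - h) / (z - zv - 1))

  structure(list(n = n, adj = adj, delta = as.numeric(delta),
                 delta_v = as.numeric(delta_v), elements = el),
            class = "hgraph")
}

#' @export
print.hgraph <- function(x, ...) {
  cat(sprintf("<hgraph> %d vertices (%s)\n", x$n,
              paste(x$elements, collapse = "")))
  cat("  delta:   ", paste(x$delta, collapse = " "), "\n")
  cat("  delta_v: ", paste(round(x$delta_v, 3), collapse = " "), "\n")
  invisible(x)
}

#' Molecular connectivity index of order k
#'
#' Computes the Kier-Hall path connectivity index of order \code{k}: the sum
#' over all simple paths of \code{k} edges (\code{k + 1} distinct vertices,
#' each undirected path counted once) of the reciprocal square root of the
#' product of the vertex degrees along the path. Order 0 sums over single
#' vertices. With \code{valence = TRUE} the valence vertex degree
#' \eqn{\delta^v} replaces the simple degree \eqn{\delta}, giving the valence
#' indices \code{Xkv}; the third-order valence index X3v is the descriptor
#' used by the permeability models.
#'
#' @param g An \code{"hgraph"} (or a \code{"molecule"}, converted
#'   internally).
#' @param k Path order, an integer from 0 to 5.
#' @param valence Use valence vertex degrees?
#' @return A non-negative number; 0 when the graph has no path of order
#'   \code{k}.
#' @examples
#' \dontrun{
#' connectivity_index(parse_smiles("CCCC"), k = 3, valence = TRUE)  # 0.5
#' }
#' @export
connectivity_index <- function(g, k, valence = FALSE) {
  if (inherits(g, "molecule")) g <- heavy_graph(g)
  stopifnot(inherits(g, "hgraph"))
  if (!(length(k) == 1L && k %in% 0:5)) {
    stop("path order k must be a single integer in 0..5", call. = FALSE)
  }
  if (g$n == 0L) stop("empty graph", call. = FALSE)
  d <- if (valence) g$delta_v else g$delta
  if (k == 0L) {
    # degree-0 vertices (lone heavy atoms, e.g. methane) contribute nothing
    return(sum(1 / sqrt(d[d > 0])))
  }
  total <- 0
  path <- integer(k + 1L)
  # DFS over simple paths; undirected paths counted once by requiring the
  # first vertex index to be smaller than the last.
  extend <- function(v, depth, prod_d) {
    path[depth] <<- v
    if (depth == k + 1L) {
      if (path[1L] < v) total <<- total + 1 / sqrt(prod_d)
      return(invisible())
    }
    for (w in g$adj[[v]]) {
      if (!(w %in% path[seq_len(depth)])) extend(w, depth + 1L, prod_d * d[w])
    }
  }
  for (v in seq_len(g$n)) extend(v, 1L, d[v])
  total
}
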