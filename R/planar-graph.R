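#' Planar molecular graphs
#'
#' A `pmg` (planar molecular graph) is a hydrogen-suppressed molecular graph
#' together with a combinatorial embedding: every vertex carries a cyclic,
#' counterclockwise ordering of its neighbours (the rotation system) derived
#' from 2D coordinates. The faces of the drawing -- including the unbounded
#' external face -- are recovered by tracing the orbits of directed edges
#' under the rotation system, so all face-based descriptors are computed
#' purely combinatorially once the embedding is fixed.
#'
#' @section Structure:
#' A `pmg` is a list with components:
#' \describe{
#'   \item{ids}{character vector of vertex identifiers}
#'   \item{coords}{numeric matrix (n x 2) of 2D positions, y growing upward}
#'   \item{edges}{integer matrix (m x 2) of undirected edges, `edges[,1] < edges[,2]`}
#'   \item{rotation}{list of integer vectors: neighbours of each vertex in
#'     counterclockwise angular order}
#' }
#'
#' @name pmg
NULL

#' Build a planar molecular graph from coordinates and edges
#'
#' Constructs the combinatorial embedding implied by a planar drawing: the
#' rotation at each vertex is its neighbour list sorted counterclockwise by
#' the angle of the outgoing edge (angles measured from +x, y upward). The
#' caller guarantees the drawing is planar (edges do not cross); this is not
#' re-checked.
#'
#' @param coordinates numeric matrix or data frame with two columns (x, y),
#'   one row per vertex. Row names (or a character `id` attribute) are used
#'   as vertex identifiers; defaults to `"v1", "v2", ...`.
#' @param edges two-column matrix or data frame of vertex indices or ids.
#' @param ids optional character vector of vertex identifiers.
#' @param tol merge tolerance: two vertices closer than `tol` times the
#'   median edge length are rejected as duplicates.
#'
#' @return an object of class `pmg`.
#' @examples
#' hexagon <- cbind(cos(seq(30, 330, by = 60) * pi / 180),
#'                  sin(seq(30, 330, by = 60) * pi / 180))
#' benzene <- build_embedding(hexagon, cbind(1:6, c(2:6, 1)))
#' vertex_degree(benzene)
#' @export
build_embedding <- function(coordinates, edges, ids = NULL, tol = 1e-6) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 2L) {
    stop("`coordinates` must have exactly two columns (x, y)", call. = FALSE)
  }
  storage.mode(coordinates) <- "double"
  n <- nrow(coordinates)
  if (n < 1L) stop("graph must have at least one vertex", call. = FALSE)

  if (is.null(ids)) {
    ids <- rownames(coordinates)
    if (is.null(ids)) ids <- paste0("v", seq_len(n))
  }
  ids <- as.character(ids)
  if (length(ids) != n || anyDuplicated(ids)) {
    stop("vertex ids must be unique and match the number of coordinate rows",
         call. = FALSE)
  }
  rownames(coordinates) <- ids
  colnames(coordinates) <- c("x", "y")

  edges <- resolve_edges(edges, ids)
  m <- nrow(edges)
  if (m < 1L && n > 1L) stop("a connected graph on >1 vertex needs edges", call. = FALSE)
  if (any(edges[, 1] == edges[, 2])) stop("loops are not allowed", call. = FALSE)
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (anyDuplicated(edges)) stop("parallel edges are not allowed", call. = FALSE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- NULL

  # duplicate-position check, scaled by the median bond length
  if (m > 0L) {
    elen <- sqrt(rowSums((coordinates[edges[, 1], , drop = FALSE] -
                          coordinates[edges[, 2], , drop = FALSE])^2))
    scale <- stats::median(elen)
    dup <- find_coincident(coordinates, tol * scale)
    if (!is.null(dup)) {
      stop(sprintf("vertices '%s' and '%s' coincide within tolerance",
                   ids[dup[1]], ids[dup[2]]), call. = FALSE)
    }
  }

  rotation <- compute_rotation(coordinates, edges, n)
  g <- structure(
    list(ids = ids, coords = coordinates, edges = edges, rotation = rotation),
    class = "pmg"
  )
  if (!is_connected_pmg(g)) {
    stop("graph is disconnected; planar molecular graphs must be connected",
         call. = FALSE)
  }
  g
}

resolve_edges <- function(edges, ids) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("`edges` must have two columns", call. = FALSE)
  if (is.character(edges)) {
    idx <- match(edges, ids)
    if (anyNA(idx)) {
      bad <- unique(edges[is.na(idx)])
      stop(sprintf("edge endpoint(s) not among vertex ids: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    edges <- matrix(idx, ncol = 2L)
  } else {
    storage.mode(edges) <- "integer"
    if (nrow(edges) > 0L &&
        (anyNA(edges) || min(edges) < 1L || max(edges) > length(ids))) {
      stop("edge indices out of range", call. = FALSE)
    }
  }
  edges
}

find_coincident <- function(coords, eps) {
  if (eps <= 0) return(NULL)
  key <- paste(round(coords[, 1] / eps), round(coords[, 2] / eps))
  d <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (length(d) < 2L) return(NULL)
  # confirm an actual close pair (hashing is conservative)
  for (i in d) {
    for (j in d) {
      if (j > i && sum((coords[i, ] - coords[j, ])^2) < eps^2) return(c(i, j))
    }
  }
  NULL
}

compute_rotation <- function(coords, edges, n) {
  nbr <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  lapply(seq_len(n), function(v) {
    nb <- nbr[[v]]
    if (is.null(nb)) return(integer(0))
    ang <- atan2(coords[nb, 2] - coords[v, 2], coords[nb, 1] - coords[v, 1])
    unname(nb[order(ang)])
  })
}

is_connected_pmg <- function(g) {
  n <- length(g$ids)
  if (n == 1L) return(TRUE)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in g$rotation[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  all(seen)
}

#' @export
print.pmg <- function(x, ...) {
  cat(sprintf("Planar molecular graph: %d vertices, %d edges, %d faces\n",
              length(x$ids), nrow(x$edges), n_faces(x)))
  invisible(x)
}

vertex_index <- function(g, v) {
  if (is.character(v)) {
    idx <- match(v, g$ids)
  } else {
    idx <- as.integer(v)
    idx[idx < 1L | idx > length(g$ids)] <- NA_integer_
  }
  if (anyNA(idx)) {
    stop(sprintf("unknown vertex: %s", paste(v[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  idx
}

#' Vertex degree and neighbourhood degree
#'
#' `vertex_degree()` counts the neighbours of each vertex;
#' `neighborhood_degree()` sums the degrees of the neighbours of each vertex
#' (the degree-sum of the open neighbourhood).
#'
#' @param g a [pmg] object.
#' @param v vertices (ids or indices); default all vertices.
#' @return named integer vector.
#' @examples
#' g <- build_benzenoid(hexspec(cbind(0:1, 0), name = "naphthalene"))
#' table(vertex_degree(g))
#' @export
vertex_degree <- function(g, v = NULL) {
  stopifnot(inherits(g, "pmg"))
  deg <- vapply(g$rotation, length, integer(1))
  names(deg) <- g$ids
  if (is.null(v)) deg else deg[vertex_index(g, v)]
}

#' @rdname vertex_degree
#' @export
neighborhood_degree <- function(g, v = NULL) {
  stopifnot(inherits(g, "pmg"))
  deg <- vapply(g$rotation, length, integer(1))
  nd <- vapply(g$rotation, function(nb) sum(deg[nb]), integer(1))
  names(nd) <- g$ids
  if (is.null(v)) nd else nd[vertex_index(g, v)]
}

#' Enumerate the faces of a planar embedding
#'
#' Traces the orbits of directed edges under the rotation system: from the
#' directed edge (u, v) the walk continues along (v, w), where w immediately
#' precedes u in the counterclockwise rotation at v. Under this rule every
#' directed edge belongs to exactly one closed walk, the walks partition the
#' 2|E| directed edges, and each orbit is one face of the drawing. Internal
#' faces come out as counterclockwise boundary polygons (positive signed
#' area); the unique face with negative signed area is the external,
#' unbounded face.
#'
#' @param g a [pmg] object.
#' @return a list of face walks; each element is a list with components
#'   `vertices` (integer vector: the closed boundary walk, first vertex not
#'   repeated), `incident` (sorted unique incident vertex indices),
#'   `is_external` (flag), and `signed_area`.
#' @examples
#' benzene <- build_benzenoid(hexspec(cbind(0, 0)))
#' length(enumerate_faces(benzene))   # 2: the hexagon and the external face
#' @export
enumerate_faces <- function(g) {
  stopifnot(inherits(g, "pmg"))
  m <- nrow(g$edges)
  if (m == 0L) stop("face enumeration needs at least one edge", call. = FALSE)

  # directed edge table: 2m rows (u -> v)
  du <- c(g$edges[, 1], g$edges[, 2])
  dv <- c(g$edges[, 2], g$edges[, 1])
  # index of directed edge (u,v): lookup via per-vertex neighbour maps
  key <- paste(du, dv)
  eidx <- stats::setNames(seq_len(2L * m), key)

  # position of each neighbour in the rotation at each vertex
  rot <- g$rotation
  pos <- lapply(seq_along(rot), function(v) {
    p <- rot[[v]]
    stats::setNames(seq_along(p), p)
  })

  used <- logical(2L * m)
  faces <- list()
  for (start in seq_len(2L * m)) {
    if (used[start]) next
    walk <- integer(0)
    cur <- start
    repeat {
      if (used[cur]) {
        stop("rotation system inconsistent with adjacency (orbit re-entry)",
             call. = FALSE)
      }
      used[cur] <- TRUE
      u <- du[cur]; v <- dv[cur]
      walk <- c(walk, u)
      # next directed edge: (v, w), w the neighbour preceding u in rotation(v)
      p <- pos[[v]][[as.character(u)]]
      if (is.null(p)) stop("rotation system inconsistent with adjacency", call. = FALSE)
      k <- length(rot[[v]])
      w <- rot[[v]][[((p - 2L) %% k) + 1L]]
      cur <- eidx[[paste(v, w)]]
      if (cur == start) break
    }
    inc <- sort(unique(walk))
    xs <- g$coords[walk, 1]; ys <- g$coords[walk, 2]
    area <- sum(xs * ys[c(2:length(ys), 1)] - xs[c(2:length(xs), 1)] * ys) / 2
    faces[[length(faces) + 1L]] <- list(
      vertices = walk, incident = inc, is_external = FALSE, signed_area = area
    )
  }
  stopifnot(sum(lengths(lapply(faces, `[[`, "vertices"))) == 2L * m)

  areas <- vapply(faces, `[[`, numeric(1), "signed_area")
  ext <- which(areas < 0)
  if (length(ext) != 1L) ext <- which.max(abs(areas))  # degenerate drawings
  faces[[ext]]$is_external <- TRUE
  faces
}

n_faces <- function(g) {
  # Euler: V - E + F = 2 for a connected plane graph
  2L - length(g$ids) + nrow(g$edges)
}

check_face <- function(g, face) {
  if (!is.list(face) || is.null(face$incident)) {
    stop("`face` must be a face walk from enumerate_faces()", call. = FALSE)
  }
  if (max(face$incident) > length(g$ids) ||
      any(face$vertices < 1L)) {
    stop("face does not belong to this graph", call. = FALSE)
  }
  if (anyDuplicated(face$vertices)) {
    warning("face boundary revisits a vertex (graph not 2-connected); ",
            "incident vertices are counted once", call. = FALSE)
  }
  invisible(TRUE)
}

#' Face degree and neighbourhood face degree
#'
#' The face degree of a face is the sum of vertex degrees over its distinct
#' incident vertices; the neighbourhood face degree sums the neighbourhood
#' degrees instead. For 2-connected graphs every boundary walk is a simple
#' cycle, so "distinct" is immaterial; for other graphs a warning is issued
#' and each incident vertex is counted once.
#'
#' @param g a [pmg] object.
#' @param face one face walk as returned by [enumerate_faces()].
#' @return integer scalar.
#' @examples
#' benzene <- build_benzenoid(hexspec(cbind(0, 0)))
#' f <- enumerate_faces(benzene)
#' vapply(f, face_degree, numeric(1), g = benzene)  # 12 12
#' @export
face_degree <- function(g, face) {
  stopifnot(inherits(g, "pmg"))
  check_face(g, face)
  sum(vertex_degree(g)[face$incident])
}

#' @rdname face_degree
#' @export
neighborhood_face_degree <- function(g, face) {
  stopifnot(inherits(g, "pmg"))
  check_face(g, face)
  sum(neighborhood_degree(g)[face$incident])
}

#' Serialize a planar molecular graph to JSON
#'
#' The dump records ids, coordinates, the edge list and the rotation lists,
#' and round-trips exactly through [pmg_from_json()].
#'
#' @param g a [pmg] object.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
pmg_to_json <- function(g, path = NULL) {
  stopifnot(inherits(g, "pmg"))
  obj <- list(
    ids = g$ids,
    coordinates = unname(apply(g$coords, 1, as.numeric, simplify = FALSE)),
    edges = unname(apply(g$edges, 1, as.integer, simplify = FALSE)),
    rotation = lapply(g$rotation, as.integer)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname pmg_to_json
#' @param json a JSON string or file path produced by [pmg_to_json()].
#' @export
pmg_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  ids <- as.character(unlist(obj$ids))
  coords <- do.call(rbind, lapply(obj$coordinates, as.numeric))
  edges <- do.call(rbind, lapply(obj$edges, as.integer))
  g <- build_embedding(coords, edges, ids = ids)
  # restore the recorded rotation verbatim (defensive: should be identical)
  g$rotation <- lapply(obj$rotation, function(r) as.integer(unlist(r)))
  g
}
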