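#' Face-based and connectivity topological indices
#'
#' `nfi()` is the neighborhood face index: the sum of neighbourhood face
#' degrees over all faces of the plane graph, the unbounded external face
#' included. `face_index()` is the degree-based analogue (sum of face
#' degrees). `randic_index()` is the classical vertex-connectivity index
#' \eqn{\sum_{uv \in E} (d_u d_v)^{-1/2}}, and `edge_connectivity_index()`
#' its edge version \eqn{\sum_{e \sim f} (d_e d_f)^{-1/2}} over adjacent edge
#' pairs, with the line-graph edge degree \eqn{d_e = d_u + d_v - 2}.
#'
#' For a 2-connected plane graph every vertex lies on exactly `d(v)` faces,
#' so `nfi(g)` equals \eqn{\sum_v d(v)\,d_n(v)} and `face_index(g)` equals
#' \eqn{\sum_v d(v)^2}; this identity is the brute-force cross-check used in
#' the package's tests.
#'
#' @param g a [pmg] object.
#' @return a single number.
#' @examples
#' benzene <- build_benzenoid(hexspec(cbind(0, 0)))
#' nfi(benzene)            # 48
#' randic_index(benzene)   # 3
#' @export
nfi <- function(g) {
  stopifnot(inherits(g, "pmg"))
  faces <- enumerate_faces(g)
  sum(vapply(faces, neighborhood_face_degree, numeric(1), g = g))
}

#' @rdname nfi
#' @export
face_index <- function(g) {
  stopifnot(inherits(g, "pmg"))
  faces <- enumerate_faces(g)
  sum(vapply(faces, face_degree, numeric(1), g = g))
}

#' @rdname nfi
#' @export
randic_index <- function(g) {
  stopifnot(inherits(g, "pmg"))
  deg <- vapply(g$rotation, length, integer(1))
  if (any(deg == 0L)) stop("graph has an isolated vertex", call. = FALSE)
  sum(1 / sqrt(deg[g$edges[, 1]] * deg[g$edges[, 2]]))
}

#' @rdname nfi
#' @export
edge_connectivity_index <- function(g) {
  stopifnot(inherits(g, "pmg"))
  m <- nrow(g$edges)
  if (m < 2L) stop("edge-connectivity index needs at least two edges", call. = FALSE)
  deg <- vapply(g$rotation, length, integer(1))
  de <- deg[g$edges[, 1]] + deg[g$edges[, 2]] - 2L
  if (any(de == 0L)) stop("graph has an edge of edge-degree zero", call. = FALSE)
  # adjacent edge pairs share a vertex: enumerate per vertex
  total <- 0
  inc <- vector("list", length(deg))
  for (k in seq_len(m)) {
    inc[[g$edges[k, 1]]] <- c(inc[[g$edges[k, 1]]], k)
    inc[[g$edges[k, 2]]] <- c(inc[[g$edges[k, 2]]], k)
  }
  for (v in seq_along(inc)) {
    es <- inc[[v]]
    if (length(es) >= 2L) {
      pr <- utils::combn(es, 2L)
      total <- total + sum(1 / sqrt(de[pr[1, ]] * de[pr[2, ]]))
    }
  }
  total
}

#' Histogram of internal faces by neighbourhood face degree
#'
#' Counts the internal faces of a plane molecular graph grouped by their
#' neighbourhood face degree; the external face's neighbourhood face degree
#' is reported separately.
#'
#' @param g a [pmg] object.
#' @return a list with `internal` (named integer vector: degree -> count,
#'   sorted by degree) and `external` (integer scalar).
#' @examples
#' perylene <- build_benzenoid(catalog_hexspec("Perylene"))
#' face_histogram(perylene)   # internal {38: 4, 50: 1}, external 102
#' @export
face_histogram <- function(g) {
  stopifnot(inherits(g, "pmg"))
  faces <- enumerate_faces(g)
  nfd <- vapply(faces, neighborhood_face_degree, numeric(1), g = g)
  ext <- vapply(faces, `[[`, logical(1), "is_external")
  tab <- table(nfd[!ext])
  internal <- stats::setNames(as.integer(tab), names(tab))
  list(internal = internal, external = as.integer(nfd[ext]))
}

#' One-row tibble of all indices of a graph
#'
#' Convenience wrapper computing every descriptor the package provides for a
#' single graph.
#'
#' @param g a [pmg] object.
#' @param name compound label for the output row.
#' @return a tibble with columns `name`, `n_vertices`, `n_edges`, `n_faces`,
#'   `nfi`, `face_index`, `randic`, `eci`, `external_nfd`.
#' @export
index_report <- function(g, name = NA_character_) {
  stopifnot(inherits(g, "pmg"))
  h <- face_histogram(g)
  tibble::tibble(
    name = name,
    n_vertices = length(g$ids),
    n_edges = nrow(g$edges),
    n_faces = n_faces(g),
    nfi = nfi(g),
    face_index = face_index(g),
    randic = randic_index(g),
    eci = edge_connectivity_index(g),
    external_nfd = h$external
  )
}

# round half away from zero at `digits` decimals (printed-table convention;
# base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
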