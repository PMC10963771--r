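# shared fixtures: all built in code, no files

regular_hexagon <- function() {
  ang <- seq(30, 330, by = 60) * pi / 180
  build_embedding(cbind(cos(ang), sin(ang)), cbind(1:6, c(2:6, 1)))
}

hex_neighbours <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))

# random edge-connected polyhex grown cell by cell (may contain holes for
# larger n, which is fine: the structures stay 2-connected)
random_hexspec <- function(n_cells) {
  cells <- matrix(c(0L, 0L), ncol = 2)
  while (nrow(cells) < n_cells) {
    base <- cells[sample.int(nrow(cells), 1), ]
    cand <- sweep(hex_neighbours, 2, base, `+`)
    cand <- cand[!(paste(cand[, 1], cand[, 2]) %in% paste(cells[, 1], cells[, 2])), ,
                 drop = FALSE]
    if (nrow(cand) == 0) next
    cells <- rbind(cells, cand[sample.int(nrow(cand), 1), ])
  }
  hexspec(cells)
}

# independent brute-force oracle: for a 2-connected plane graph each vertex
# lies on exactly d(v) faces, so summing d_n(v) face-incidences vertex-wise
# needs no face enumeration at all
oracle_nfi <- function(g) {
  deg <- vertex_degree(g)
  sum(deg * neighborhood_degree(g))
}
oracle_face_index <- function(g) sum(vertex_degree(g)^2)

# independent Randic / edge-connectivity values through igraph
igraph_from_pmg <- function(g) {
  igraph::graph_from_edgelist(g$edges, directed = FALSE)
}
igraph_randic <- function(g) {
  ig <- igraph_from_pmg(g)
  d <- igraph::degree(ig)
  el <- igraph::as_edgelist(ig, names = FALSE)
  sum(1 / sqrt(d[el[, 1]] * d[el[, 2]]))
}
igraph_eci <- function(g) {
  lg <- igraph::make_line_graph(igraph_from_pmg(g))
  d <- igraph::degree(lg)
  el <- igraph::as_edgelist(lg, names = FALSE)
  sum(1 / sqrt(d[el[, 1]] * d[el[, 2]]))
}
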