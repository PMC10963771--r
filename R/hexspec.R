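#' Hexagon-cell specifications of benzenoid skeletons
#'
#' A `hexspec` describes a fused-hexagon (benzenoid) carbon skeleton by the
#' axial coordinates of its hexagonal cells on the pointy-top honeycomb
#' lattice. Cell (q, r) has centre at doubled-integer coordinates
#' (u, y) = (2q + r, 3r); its six corners are (u, y +/- 2) and
#' (u +/- 1, y +/- 1), all integers, so corner deduplication when fusing
#' cells is exact. The true cartesian drawing is x = sqrt(3) u, y = y
#' (uniform x-scaling preserves the angular order used by the rotation
#' system, so the integer coordinates are used directly).
#'
#' Two cells are adjacent (share an edge) when their axial difference is one
#' of (1,0), (-1,0), (0,1), (0,-1), (1,-1), (-1,1).
#'
#' @param cells two-column matrix or data frame of integer axial coordinates
#'   (q, r), one row per hexagon.
#' @param name optional compound label.
#' @return an object of class `hexspec`.
#' @examples
#' naphthalene <- hexspec(rbind(c(0, 0), c(1, 0)), name = "Naphthalene")
#' build_benzenoid(naphthalene)
#' @export
hexspec <- function(cells, name = NA_character_) {
  cells <- as.matrix(cells)
  if (ncol(cells) != 2L) stop("`cells` must have two columns (q, r)", call. = FALSE)
  storage.mode(cells) <- "integer"
  if (anyNA(cells)) stop("cell coordinates must be integers", call. = FALSE)
  if (anyDuplicated(cells)) stop("duplicate hexagon cells", call. = FALSE)
  colnames(cells) <- c("q", "r")
  structure(list(cells = cells, name = as.character(name)), class = "hexspec")
}

#' @export
print.hexspec <- function(x, ...) {
  cat(sprintf("hexspec '%s': %d hexagon cell(s)\n",
              x$name, nrow(x$cells)))
  invisible(x)
}

hex_adjacent <- function(d) {
  # d: integer vector c(dq, dr)
  (abs(d[1]) + abs(d[2]) == 1L) || (d[1] == 1L && d[2] == -1L) ||
    (d[1] == -1L && d[2] == 1L)
}

cells_connected <- function(cells) {
  n <- nrow(cells)
  if (n == 1L) return(TRUE)
  seen <- logical(n); seen[1] <- TRUE; stack <- 1L
  while (length(stack)) {
    i <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (j in which(!seen)) {
      if (hex_adjacent(cells[j, ] - cells[i, ])) {
        seen[j] <- TRUE; stack <- c(stack, j)
      }
    }
  }
  all(seen)
}

hex_corners <- function(q, r) {
  u <- 2L * q + r
  y <- 3L * r
  # counterclockwise from the top corner
  cbind(u = u + c(0L, -1L, -1L, 0L, 1L, 1L),
        y = y + c(2L, 1L, -1L, -2L, -1L, 1L))
}

#' Build the molecular graph of a benzenoid from its hexagon cells
#'
#' Vertices are the distinct hexagon corners, edges the hexagon sides; the
#' planar embedding comes from the lattice geometry. The result is the
#' hydrogen-suppressed carbon skeleton: 2-connected, maximum degree 3, every
#' bounded face a hexagon.
#'
#' @param spec a [hexspec], or anything `hexspec()` accepts.
#' @return a [pmg] object.
#' @examples
#' build_benzenoid(hexspec(cbind(0, 0)))           # benzene
#' build_benzenoid(hexspec(rbind(c(0,0), c(1,0)))) # naphthalene
#' @export
build_benzenoid <- function(spec) {
  if (!inherits(spec, "hexspec")) spec <- hexspec(spec)
  cells <- spec$cells
  if (!cells_connected(cells)) {
    stop("hexagon cells are not edge-connected", call. = FALSE)
  }
  corner_list <- lapply(seq_len(nrow(cells)),
                        function(i) hex_corners(cells[i, 1], cells[i, 2]))
  all_corners <- do.call(rbind, corner_list)
  key <- paste(all_corners[, 1], all_corners[, 2])
  uniq <- !duplicated(key)
  verts <- all_corners[uniq, , drop = FALSE]
  vid <- stats::setNames(seq_len(nrow(verts)), key[uniq])

  edges <- matrix(integer(0), ncol = 2)
  for (co in corner_list) {
    k <- paste(co[, 1], co[, 2])
    idx <- vid[k]
    edges <- rbind(edges, cbind(idx, idx[c(2:6, 1)]))
  }
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- unique(edges)

  build_embedding(verts, edges, ids = names(vid))
}

#' Read and write hexspec JSON
#'
#' The on-disk format is `{"name": str, "cells": [[q, r], ...]}` and
#' round-trips exactly.
#'
#' @param spec a [hexspec].
#' @param path file path (for `write_hexspec`) or path/JSON string (for
#'   `read_hexspec`).
#' @return `read_hexspec` returns a [hexspec]; `write_hexspec` returns
#'   `path` invisibly.
#' @export
write_hexspec <- function(spec, path) {
  stopifnot(inherits(spec, "hexspec"))
  obj <- list(name = spec$name,
              cells = unname(apply(spec$cells, 1, as.integer, simplify = FALSE)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_hexspec
#' @export
read_hexspec <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cells <- do.call(rbind, lapply(obj$cells, as.integer))
  hexspec(cells, name = if (is.null(obj$name)) NA_character_ else obj$name)
}
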