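#' Read a 2D MOL/SDF (V2000) file as a planar molecular graph
#'
#' Parses the atom and bond blocks of an MDL V2000 connection table, drops
#' hydrogen atoms (and their bonds) to obtain the hydrogen-suppressed
#' skeleton, and builds the planar embedding from the 2D coordinates. Bond
#' orders, charges and isotope fields are ignored. Only the first record of
#' an SD file is read.
#'
#' @param path path to a `.mol`/`.sdf` file (or a character vector of its
#'   lines).
#' @return a [pmg] object.
#' @export
read_mol <- function(path) {
  lines <- if (length(path) > 1L) path else readLines(path, warn = FALSE)
  if (length(lines) < 4L) stop("not a V2000 connection table", call. = FALSE)
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds)) {
    stop("malformed counts line in MOL file", call. = FALSE)
  }
  if (length(lines) < 4L + natoms + nbonds) {
    stop("truncated MOL file", call. = FALSE)
  }
  atom_lines <- lines[4L + seq_len(natoms)]
  x <- suppressWarnings(as.numeric(substr(atom_lines, 1, 10)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 11, 20)))
  sym <- trimws(substr(atom_lines, 32, 34))
  bond_lines <- lines[4L + natoms + seq_len(nbonds)]
  b1 <- suppressWarnings(as.integer(substr(bond_lines, 1, 3)))
  b2 <- suppressWarnings(as.integer(substr(bond_lines, 4, 6)))
  if (anyNA(c(x, y, b1, b2))) stop("malformed MOL atom/bond block", call. = FALSE)

  heavy <- sym != "H"
  keep_map <- cumsum(heavy)
  keep_bond <- heavy[b1] & heavy[b2]
  coords <- cbind(x = x[heavy], y = y[heavy])
  edges <- cbind(keep_map[b1[keep_bond]], keep_map[b2[keep_bond]])
  build_embedding(coords, edges,
                  ids = paste0(sym[heavy], seq_len(sum(heavy))))
}
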