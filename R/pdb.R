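#' Read atom centres and van der Waals radii from a PDB file
#'
#' Parses ATOM and HETATM records (via the bio3d reader) and attaches a van
#' der Waals radius per atom by element symbol.  Occupancy and alternate
#' locations are ignored; unknown elements fall back to the `default` entry of
#' the radius table.
#'
#' @param path PDB file path.
#' @param radii named vector of van der Waals radii in Angstrom; must contain
#'   a `default` entry.
#' @param keep_hetatm include HETATM records (default TRUE).
#' @return data.frame with columns `x`, `y`, `z`, `radius`, `element`,
#'   suitable for [voxelize_atoms()].
#' @export
read_pdb_atoms <- function(path,
                           radii = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
                                     S = 1.80, P = 1.80, default = 1.70),
                           keep_hetatm = TRUE) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("read_pdb_atoms() needs the 'bio3d' package", call. = FALSE)
  }
  if (is.na(radii["default"])) {
    stop("'radii' must contain a 'default' entry", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no atom records in ", path, call. = FALSE)
  elem <- toupper(trimws(at$elesy))
  elem[is.na(elem) | elem == ""] <-
    toupper(substr(trimws(at$elety[is.na(elem) | elem == ""]), 1L, 1L))
  r <- unname(radii[elem])
  r[is.na(r)] <- radii["default"]
  data.frame(x = at$x, y = at$y, z = at$z, radius = r, element = elem)
}
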