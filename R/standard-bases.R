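#' Standard reference-frame base geometry
#'
#' The package ships the fixed standard-reference-frame coordinates
#' (Tsukuba convention) for the five canonical bases A, C, G, T and U.
#' Each base is given in its own standard frame: the origin sits between
#' the Watson-Crick edges of an ideal pair, the x axis points into the
#' major groove, the y axis runs along the pseudo-dyad towards the
#' attached sugar, and the z axis completes a right-handed system,
#' pointing away from the face from which the base ring appears
#' clockwise. An ideal Watson-Crick partner is the complementary base
#' mapped through (x, y, z) -> (x, -y, -z), so that both bases of an
#' ideal pair share one frame origin with antiparallel y and z axes.
#'
#' @param base One of "A", "C", "G", "T", "U".
#' @return A list with elements \code{base}, \code{ring_atom_names}
#'   (9 for purines, 6 for pyrimidines), \code{ring_coords} (matrix,
#'   one row per ring atom), \code{atoms} (all shipped atoms incl.
#'   exocyclic Watson-Crick atoms and C1'), and \code{coords}.
#' @export
standard_base <- function(base) {
  std <- standard_base_table()
  base <- toupper(base)
  if (!base %in% names(std)) {
    stop("no standard geometry for base '", base, "'")
  }
  std[[base]]
}

PURINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")

is_purine <- function(base) base %in% c("A", "G")

ring_atom_names <- function(base) {
  if (is_purine(base)) PURINE_RING else PYRIMIDINE_RING
}

## Cached loader for the shipped coordinate table.
standard_base_env <- new.env(parent = emptyenv())

standard_base_table <- function() {
  if (!is.null(standard_base_env$std)) {
    return(standard_base_env$std)
  }
  path <- system.file("extdata", "standard_bases.tsv", package = "nucval")
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  std <- lapply(split(tab, tab$base), function(d) {
    coords <- as.matrix(d[, c("x", "y", "z")])
    rownames(coords) <- d$atom
    b <- d$base[1]
    ring <- ring_atom_names(b)
    stopifnot(all(ring %in% d$atom))
    list(base = b,
         ring_atom_names = ring,
         ring_coords = coords[ring, , drop = FALSE],
         atoms = d$atom,
         coords = coords)
  })
  standard_base_env$std <- std
  std
}
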