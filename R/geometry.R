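#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the sum of
#' squared distances between matched point sets, via singular value
#' decomposition of the covariance matrix with a determinant correction
#' so the rotation is never a reflection.
#'
#' @param reference n x 3 matrix of reference points.
#' @param observed n x 3 matrix of observed points (same order).
#' @return list(rotation = 3x3 proper orthonormal matrix,
#'   translation = length-3 vector, rmsd = Angstrom). The fitted
#'   positions are \code{reference \%*\% t(rotation) + translation}.
#' @export
superpose <- function(reference, observed) {
  reference <- as.matrix(reference)
  observed <- as.matrix(observed)
  if (nrow(reference) != nrow(observed) || ncol(reference) != 3 ||
      ncol(observed) != 3) {
    stop("point sets must be n x 3 matrices of equal length")
  }
  n <- nrow(reference)
  if (n < 3) stop("need at least 3 point pairs")
  cr <- colMeans(reference)
  co <- colMeans(observed)
  P <- sweep(reference, 2, cr)
  Q <- sweep(observed, 2, co)
  ## Collinearity check: second singular value of the centred reference.
  sv <- svd(P)$d
  if (sv[2] < 1e-8) stop("degenerate (collinear) point set")
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- unname(co - as.vector(R %*% cr))
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Fit the standard reference frame to an observed base
#'
#' Superposes the standard base's ring atoms (9 for purines, 6 for
#' pyrimidines; exocyclic atoms never enter the fit) onto the observed
#' ring atoms. The base frame is the standard frame carried through
#' that rigid motion: origin = image of (0,0,0), axes = columns of the
#' fitted rotation.
#'
#' @param residue A classified residue (see \code{\link{classify_residue}}).
#' @return list(origin, x, y, z, fit_rmsd) with unit, mutually
#'   orthogonal, right-handed axes.
#' @export
base_frame <- function(residue) {
  if (is.null(residue$parent_base) || residue$parent_base == "none") {
    stop("residue ", residue_key(residue$chain_id, residue$seq_num,
                                 residue$insertion_code),
         " has no parent base")
  }
  std <- standard_base(residue$parent_base)
  ring <- std$ring_atom_names
  obs <- residue_coords(residue, ring)
  if (anyNA(obs)) {
    missing <- ring[apply(is.na(obs), 1, any)]
    stop("incomplete base: residue ",
         residue_key(residue$chain_id, residue$seq_num,
                     residue$insertion_code),
         " lacks ring atom(s) ", paste(missing, collapse = ", "))
  }
  fit <- superpose(std$ring_coords, obs)
  list(origin = as.vector(fit$translation),
       x = fit$rotation[, 1], y = fit$rotation[, 2], z = fit$rotation[, 3],
       fit_rmsd = fit$rmsd)
}

## Coordinates of named atoms from a residue's atom table; NA rows when absent.
residue_coords <- function(residue, atom_names) {
  at <- residue$atoms
  idx <- match(atom_names, at$name)
  out <- matrix(NA_real_, length(atom_names), 3,
                dimnames = list(atom_names, c("x", "y", "z")))
  ok <- !is.na(idx)
  out[ok, ] <- as.matrix(at[idx[ok], c("x", "y", "z")])
  out
}

#' Simple base-pair parameters
#'
#' Computes the six intuitive intra-pair descriptors in the "simple"
#' pair frame. Base J is taken as the antiparallel partner: its y and z
#' axes are negated before combination. The pair z axis is the
#' normalized mean of the two aligned base normals; the pair y axis is
#' the unit C1'(j) to C1'(i) vector orthogonalized against z; x = y x z.
#' Shear, stretch and stagger are the components of origin_i - origin_j
#' along (x, y, z). With interbase angle gamma = angle(z_i, aligned z_j)
#' and hinge axis a = unit(aligned z_j x z_i), buckle = gamma (a . x)
#' and propeller = gamma (a . y), so buckle^2 + propeller^2 = gamma^2.
#' Opening is the signed angle (about the pair z axis) between the
#' projections of the two y axes onto the pair plane.
#'
#' @param frame_i,frame_j Base frames from \code{\link{base_frame}};
#'   frame_i belongs to the first (canonically purine) base.
#' @param c1_i,c1_j C1' atom positions of the two residues.
#' @return list(shear, stretch, stagger (Angstrom), buckle, propeller,
#'   opening (degrees), interbase_angle (degrees)).
#' @export
simple_parameters <- function(frame_i, frame_j, c1_i, c1_j) {
  zj <- -frame_j$z
  yj <- -frame_j$y
  gamma <- vangle(frame_i$z, zj)
  if (gamma > 90) {
    stop("not pairable: aligned base normals diverge by ", round(gamma, 1),
         " degrees")
  }
  z <- unitv(frame_i$z + zj)
  ydir <- c1_i - c1_j
  y <- ydir - sum(ydir * z) * z
  y <- unitv(y)
  x <- cross3(y, z)
  d <- frame_i$origin - frame_j$origin
  shear <- sum(d * x)
  stretch <- sum(d * y)
  stagger <- sum(d * z)
  hx <- cross3(zj, frame_i$z)
  if (vnorm(hx) < 1e-12) {
    buckle <- 0
    propeller <- 0
  } else {
    a <- unitv(hx)
    buckle <- gamma * sum(a * x)
    propeller <- gamma * sum(a * y)
  }
  yi_p <- frame_i$y - sum(frame_i$y * z) * z
  yj_p <- yj - sum(yj * z) * z
  opening <- rad2deg(atan2(sum(z * cross3(yj_p, yi_p)), sum(yj_p * yi_p)))
  list(shear = shear, stretch = stretch, stagger = stagger,
       buckle = buckle, propeller = propeller, opening = opening,
       interbase_angle = gamma)
}

## Hydrogen-bond atom pairs per Watson-Crick pair type,
## named purine_atom-pyrimidine_atom.
WC_BOND_TABLE <- list(
  "A-T" = list(c("N1", "N3"), c("N6", "O4")),
  "A-U" = list(c("N1", "N3"), c("N6", "O4")),
  "G-C" = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2"))
)

#' Watson-Crick hydrogen-bond lengths of a base pair
#'
#' Measures the donor/acceptor heavy-atom distances of the standard
#' Watson-Crick bonds: N1-N3 and N6-O4 for A-T / A-U, and O6-N4, N1-N3,
#' N2-O2 for G-C. Hydrogens are ignored throughout. A bond whose atoms
#' are not all present is reported with \code{distance = NA} and
#' \code{missing = TRUE} rather than silently dropped.
#'
#' @param res_pu Purine residue (A or G); \code{res_py} its pyrimidine
#'   partner.
#' @param pair_type "A-T", "A-U" or "G-C".
#' @return data.frame(atom_i, atom_j, distance, missing).
#' @export
hbond_lengths <- function(res_pu, res_py, pair_type) {
  bonds <- WC_BOND_TABLE[[pair_type]]
  if (is.null(bonds)) stop("no bond table for pair type '", pair_type, "'")
  res <- lapply(bonds, function(b) {
    pi <- residue_coords(res_pu, b[1])[1, ]
    pj <- residue_coords(res_py, b[2])[1, ]
    d <- if (anyNA(pi) || anyNA(pj)) NA_real_ else vnorm(pi - pj)
    data.frame(atom_i = b[1], atom_j = b[2], distance = d,
               missing = is.na(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
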