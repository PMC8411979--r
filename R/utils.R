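## Small vector helpers shared across the geometry chain.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Angle between two vectors in degrees, clamped against rounding.
vangle <- function(a, b) {
  ca <- sum(unitv(a) * unitv(b))
  ca <- max(-1, min(1, ca))
  acos(ca) * 180 / pi
}

## Rotation matrix for angle `deg` (degrees) about unit axis `axis` (Rodrigues).
rotation_about <- function(axis, deg) {
  u <- unitv(axis)
  th <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

## Canonical residue key "chain/seqnum[icode]" used throughout reports.
residue_key <- function(chain, seq_num, icode = "") {
  icode <- ifelse(is.na(icode) | icode == "." | icode == " ", "", icode)
  paste0(chain, "/", seq_num, icode)
}
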