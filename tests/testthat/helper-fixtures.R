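## Shared fixture builders for the test suite. Everything is generated
## in code; no binary fixtures.

c1p <- function(res) nucval:::residue_coords(res, "C1'")[1, ]

## Measure the simple parameters of a two-residue pair structure
## (purine residue first, as built by build_pair).
measure_pair <- function(st) {
  ri <- st$residues[[1]]
  rj <- st$residues[[2]]
  simple_parameters(base_frame(ri), base_frame(rj), c1p(ri), c1p(rj))
}

## Deterministic random rotation matrix from a seed.
random_rotation <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  nucval:::rotation_about(ax / sqrt(sum(ax^2)), stats::runif(1, 0, 360))
}

## Apply one rigid motion to every atom of a structure.
move_structure <- function(st, R, t_vec) {
  st$residues <- lapply(st$residues, function(res) {
    co <- as.matrix(res$atoms[, c("x", "y", "z")]) %*% t(R)
    co <- sweep(co, 2, t_vec, "+")
    res$atoms$x <- co[, 1]; res$atoms$y <- co[, 2]; res$atoms$z <- co[, 3]
    res
  })
  st
}

## A model of n isolated pairs with prescribed per-pair parameter
## draws; pairs separated by 30 A so they never cross-contact.
pairs_model <- function(specs, entry_id = "fixture") {
  residues <- list()
  for (k in seq_along(specs)) {
    st <- build_pair(specs[[k]])
    st <- move_structure(st, diag(3), c(30 * k, 0, 0))
    pu <- st$residues[[1]]; py <- st$residues[[2]]
    pu$seq_num <- k; py$seq_num <- k
    residues[[residue_key_t(pu)]] <- pu
    residues[[residue_key_t(py)]] <- py
  }
  structure(list(entry_id = entry_id, residues = residues,
                 resolution = NA_real_, rscc = NULL),
            class = "nucval_structure")
}

residue_key_t <- function(res) {
  paste0(res$chain_id, "/", res$seq_num, res$insertion_code)
}

## Specs whose four scored parameters sit exactly at the target means
## of the given class.
mean_spec <- function(category, pair_type) {
  g <- function(k) lookup_simple_target(category, pair_type, k)$mean
  pair_spec(category = category, pair_type = pair_type,
            shear = g("shear"), stretch = g("stretch"),
            buckle = g("buckle"), propeller = g("propeller"))
}

## Location where deposited PDB/mmCIF coordinate files would live for
## the worked-example checks against published structures.
deposited_path <- function(entry) {
  testthat::test_path("deposited", paste0(entry, ".cif"))
}
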