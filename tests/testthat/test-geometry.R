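test_that("superposition recovers exact rigid motions", {
  std <- standard_base("G")$ring_coords
  fit0 <- superpose(std, std)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)

  for (seed in 1:5) {
    R <- random_rotation(seed)
    t_vec <- c(seed, -2 * seed, 0.5)
    moved <- sweep(std %*% t(R), 2, t_vec, "+")
    fit <- superpose(std, moved)
    expect_equal(fit$rotation, R, tolerance = 1e-9)
    expect_equal(as.vector(fit$translation), t_vec, tolerance = 1e-9)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("superposition is the least-squares optimum under noise", {
  std <- standard_base("A")$ring_coords
  set.seed(42)
  R <- random_rotation(7)
  obs <- sweep(std %*% t(R), 2, c(1, 2, 3), "+") +
    matrix(rnorm(length(std), 0, 0.01), ncol = 3)
  fit <- superpose(std, obs)
  expect_gt(fit$rmsd, 0)
  expect_lt(fit$rmsd, 0.05)

  ## Independent oracle: the quadratic cost at the returned optimum
  ## must not exceed the cost of any random rotation + best translation.
  cost <- function(Rtry) {
    fitted <- std %*% t(Rtry)
    fitted <- sweep(fitted, 2, colMeans(obs) - colMeans(fitted), "+")
    mean(rowSums((fitted - obs)^2))
  }
  for (seed in 11:40) {
    expect_lte(cost(fit$rotation), cost(random_rotation(seed)) + 1e-12)
  }
})

test_that("superposition rejects degenerate input", {
  expect_error(superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:4, 2 * (1:4), -(1:4))
  expect_error(superpose(line, line), "degenerate")
})

test_that("base frames carry the standard frame through rigid motions", {
  st <- build_pair(pair_spec(category = "RNA-RNA", pair_type = "G-C"))
  g <- st$residues[[1]]
  f0 <- base_frame(g)
  expect_lt(f0$fit_rmsd, 1e-9)
  ## Orthonormal right-handed axes.
  M <- cbind(f0$x, f0$y, f0$z)
  expect_equal(t(M) %*% M, diag(3), tolerance = 1e-9)
  expect_equal(det(M), 1, tolerance = 1e-9)

  R <- random_rotation(3)
  t_vec <- c(-4, 5, 9)
  g2 <- move_structure(st, R, t_vec)$residues[[1]]
  f2 <- base_frame(g2)
  expect_equal(f2$origin, as.vector(R %*% f0$origin) + t_vec,
               tolerance = 1e-9)
  expect_equal(cbind(f2$x, f2$y, f2$z), R %*% M, tolerance = 1e-9)

  g$atoms <- g$atoms[g$atoms$name != "N7", ]
  expect_error(base_frame(g), "incomplete base")
})

test_that("simple parameters vanish for the ideal coplanar pair", {
  st <- build_pair(pair_spec(category = "DNA-DNA", pair_type = "A-T"))
  p <- measure_pair(st)
  for (k in c("shear", "stretch", "stagger", "buckle", "propeller",
              "opening")) {
    expect_equal(p[[k]], 0, tolerance = 1e-9)
  }
})

test_that("parameters are invariant under rigid motion of the whole pair", {
  spec <- pair_spec(category = "RNA-RNA", pair_type = "A-U", shear = 0.3,
                    stretch = -0.1, stagger = 0.15, buckle = 10,
                    propeller = -12, opening = 2)
  st <- build_pair(spec)
  p0 <- unlist(measure_pair(st))
  for (seed in 1:4) {
    st2 <- move_structure(st, random_rotation(seed), c(seed, -seed, 2))
    p2 <- unlist(measure_pair(st2))
    expect_lt(max(abs(p2 - p0)), 1e-9)
  }
})

test_that("exchanging the bases flips shear and buckle only", {
  spec <- pair_spec(category = "DNA-DNA", pair_type = "G-C", shear = -0.2,
                    stretch = -0.13, stagger = 0.1, buckle = -4,
                    propeller = -7, opening = 1.5)
  st <- build_pair(spec)
  ri <- st$residues[[1]]; rj <- st$residues[[2]]
  p <- simple_parameters(base_frame(ri), base_frame(rj), c1p(ri), c1p(rj))
  q <- simple_parameters(base_frame(rj), base_frame(ri), c1p(rj), c1p(ri))
  expect_equal(q$shear, -p$shear, tolerance = 1e-9)
  expect_equal(q$buckle, -p$buckle, tolerance = 1e-9)
  expect_equal(q$stretch, p$stretch, tolerance = 1e-9)
  expect_equal(q$stagger, p$stagger, tolerance = 1e-9)
  expect_equal(q$propeller, p$propeller, tolerance = 1e-9)
  expect_equal(q$opening, p$opening, tolerance = 1e-9)
})

test_that("buckle and propeller decompose the interbase angle", {
  set.seed(5)
  for (i in 1:10) {
    spec <- pair_spec(category = "RNA-RNA", pair_type = "G-C",
                      shear = runif(1, -0.5, 0.5),
                      stretch = runif(1, -0.3, 0.3),
                      buckle = runif(1, -25, 25),
                      propeller = runif(1, -25, 25))
    p <- measure_pair(build_pair(spec))
    expect_equal(p$buckle^2 + p$propeller^2, p$interbase_angle^2,
                 tolerance = 1e-6)
  }
})

test_that("hydrogen-bond measurement follows the per-type bond table", {
  at <- build_pair(pair_spec(category = "DNA-DNA", pair_type = "A-T"))
  hb_at <- hbond_lengths(at$residues[[1]], at$residues[[2]], "A-T")
  expect_equal(nrow(hb_at), 2)
  expect_setequal(paste0(hb_at$atom_i, "-", hb_at$atom_j),
                  c("N1-N3", "N6-O4"))

  gc <- build_pair(pair_spec(category = "DNA-DNA", pair_type = "G-C"))
  hb_gc <- hbond_lengths(gc$residues[[1]], gc$residues[[2]], "G-C")
  expect_equal(nrow(hb_gc), 3)
  expect_setequal(paste0(hb_gc$atom_i, "-", hb_gc$atom_j),
                  c("O6-N4", "N1-N3", "N2-O2"))
  expect_false(any(hb_gc$missing))

  ## Distances are plain Euclidean separations.
  ri <- gc$residues[[1]]
  rj <- gc$residues[[2]]
  d_direct <- sqrt(sum((nucval:::residue_coords(ri, "N1")[1, ] -
                          nucval:::residue_coords(rj, "N3")[1, ])^2))
  expect_equal(hb_gc$distance[hb_gc$atom_i == "N1"], d_direct,
               tolerance = 1e-12)

  ## A missing atom is flagged, never silently dropped.
  rj$atoms <- rj$atoms[rj$atoms$name != "N4", ]
  hb_miss <- hbond_lengths(ri, rj, "G-C")
  expect_equal(nrow(hb_miss), 3)
  expect_true(hb_miss$missing[hb_miss$atom_i == "O6"])
  expect_true(is.na(hb_miss$distance[hb_miss$atom_i == "O6"]))
})
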