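test_that("Z scoring and the per-pair geometry score behave as defined", {
  expect_equal(zscore(2.825, 2.825, 0.053), 0)
  expect_equal(zscore(2.878, 2.825, 0.053), 1.0)
  expect_equal(zscore(2.719, 2.825, 0.053), -2.0)
  expect_error(zscore(1, 1, 0), "positive")

  expect_equal(zbpg(0, 0, 0, 0), 0)
  expect_equal(zbpg(1, 1, 1, 1), 1)
  expect_equal(zbpg(3, 0, 0, 0), 1.5)        # rms form
  expect_equal(zbpg(3, 0, 0, 0, form = "mean_abs"), 0.75)
  expect_equal(zbpg(1, -1, 1, -1, form = "mean_abs"), 1)
})

test_that("rmsZ is the root mean square with absent-on-empty semantics", {
  expect_equal(rmsz(c(1, -1)), 1)
  expect_equal(rmsz(c(0, 0, 0)), 0)
  expect_true(is.na(rmsz(numeric(0))))
  ## Permutation invariance and scale consistency.
  set.seed(1)
  z <- rnorm(50)
  expect_equal(rmsz(sample(z)), rmsz(z))
  expect_equal(rmsz(2 * z), 2 * rmsz(z))
  ## Monte-Carlo calibration on standard normal draws.
  set.seed(2024)
  expect_equal(rmsz(rnorm(1e4)), 1, tolerance = 0.02)
})

test_that("jackknife SDs match hand evaluation and bootstrap", {
  expect_equal(jackknife_sd(c(2, 2, 2, 2)), 0)
  ## Hand check for {0, 2}: theta_(1) = rmsz({2}) = 2,
  ## theta_(2) = rmsz({0}) = 0, so sd = sqrt((1/2)((2-1)^2+(0-1)^2)) = 1.
  expect_equal(jackknife_sd(c(0, 2)), 1)
  expect_true(is.na(jackknife_sd(3)))

  set.seed(77)
  z <- rnorm(200)
  jk <- jackknife_sd(z)
  boots <- replicate(2000, rmsz(sample(z, replace = TRUE)))
  expect_equal(jk, sd(boots), tolerance = 0.2 * sd(boots))
})

test_that("Z_change standardizes metric differences", {
  z0 <- zchange(4, 1, 4, 1)
  expect_equal(z0$z_change, 0)
  expect_false(z0$significant)

  z1 <- zchange(10, 1, 5, 1)
  expect_equal(z1$z_change, 5 / sqrt(2), tolerance = 1e-12)
  expect_true(z1$significant)

  z2 <- zchange(10, NA, 5, NA)
  expect_true(is.na(z2$significant))

  ## One available sd still gives a determination.
  z3 <- zchange(10, 1, 5, NA)
  expect_equal(z3$z_change, 5)
  expect_true(z3$significant)
})

test_that("bond-valence sums follow the exponential closed form", {
  expect_equal(bond_valence(c(0, 0, 0), c(1.875, 0, 0), r_o = 1.875), 1)
  d_half <- 1.875 + 0.37 * log(2)
  expect_equal(bond_valence(c(0, 0, 0), c(d_half, 0, 0), r_o = 1.875),
               0.5, tolerance = 1e-12)
  ## Octahedral oxygen shell at 2.28 A: near the divalent expectation.
  lig <- rbind(c(2.28, 0, 0), c(-2.28, 0, 0), c(0, 2.28, 0),
               c(0, -2.28, 0), c(0, 0, 2.28), c(0, 0, -2.28))
  s <- bond_valence(c(0, 0, 0), lig, r_o = 1.875)
  expect_equal(s, 6 * exp((1.875 - 2.28) / 0.37), tolerance = 1e-12)
  expect_gt(s, 1.9); expect_lt(s, 2.1)
  ## Ligands beyond the coordination cutoff do not contribute.
  expect_equal(bond_valence(c(0, 0, 0), rbind(c(2, 0, 0), c(3.5, 0, 0)),
                            r_o = 1.875),
               exp((1.875 - 2) / 0.37), tolerance = 1e-12)
  expect_error(bond_valence(c(0, 0, 0), c(0, 0, 0), r_o = 1.875),
               "positive")
})

test_that("models built at target means validate to zero", {
  classes <- unique(load_simple_targets()[, c("category", "pair_type")])
  specs <- lapply(seq_len(10), function(k) {
    cl <- classes[((k - 1) %% nrow(classes)) + 1, ]
    mean_spec(cl$category, cl$pair_type)
  })
  st <- pairs_model(specs)
  rep <- validate_model(st)
  expect_equal(rep$n_pairs, 10)
  expect_equal(max(abs(rep$pairs$z_bpg)), 0, tolerance = 1e-6)
  for (k in c("shear", "stretch", "buckle", "propeller")) {
    expect_equal(rep$model[[paste0(k, "_rmsz")]], 0, tolerance = 1e-6)
  }
  expect_equal(sum(rep$pairs$outlier), 0)
})

test_that("one-sigma displacements give rmsZ exactly one", {
  cl <- list(category = "DNA-DNA", pair_type = "G-C")
  g <- function(k) lookup_simple_target(cl$category, cl$pair_type, k)
  spec_1sd <- pair_spec(
    category = cl$category, pair_type = cl$pair_type,
    shear = g("shear")$mean + g("shear")$sd,
    stretch = g("stretch")$mean + g("stretch")$sd,
    buckle = g("buckle")$mean + g("buckle")$sd,
    propeller = g("propeller")$mean + g("propeller")$sd)
  st <- pairs_model(rep(list(spec_1sd), 4))
  rep <- validate_model(st)
  for (k in c("shear", "stretch", "buckle", "propeller")) {
    expect_equal(rep$model[[paste0(k, "_rmsz")]], 1, tolerance = 1e-6)
  }
  expect_equal(rep$pairs$z_bpg, rep(1, 4), tolerance = 1e-6)
})

test_that("rmsZ converges to one on draws from the target Gaussians", {
  classes <- unique(load_simple_targets()[, c("category", "pair_type")])
  set.seed(31)
  n <- 60
  specs <- lapply(seq_len(n), function(k) {
    cl <- classes[sample(nrow(classes), 1), ]
    g <- function(kk) lookup_simple_target(cl$category, cl$pair_type, kk)
    pair_spec(category = cl$category, pair_type = cl$pair_type,
              shear = rnorm(1, g("shear")$mean, g("shear")$sd),
              stretch = rnorm(1, g("stretch")$mean, g("stretch")$sd),
              buckle = rnorm(1, g("buckle")$mean, g("buckle")$sd),
              propeller = rnorm(1, g("propeller")$mean,
                                g("propeller")$sd))
  })
  rep <- validate_model(pairs_model(specs))
  expect_equal(rep$n_pairs, n)
  for (k in c("shear", "stretch", "buckle", "propeller")) {
    v <- rep$model[[paste0(k, "_rmsz")]]
    s <- rep$model[[paste0(k, "_rmsz_sd")]]
    expect_lt(abs(v - 1), 3 * s)
  }
})

test_that("unvalidatable classes are reported but not scored", {
  ## DNA A-U pairs have no targets by design.
  st <- build_pair(pair_spec(category = "DNA-RNA", pair_type = "A-U"))
  st$residues[[2]]$comp_id <- "DU"
  st$residues[[2]] <- classify_residue(st$residues[[2]])
  expect_equal(st$residues[[2]]$nucleic_class, "DNA")
  rep <- validate_model(st)
  expect_equal(rep$n_pairs, 1)
  expect_false(rep$pairs$validated)
  expect_true(is.na(rep$pairs$z_bpg))

  ## Empty model: an empty report, absent metrics.
  empty <- structure(list(entry_id = "x", residues = list(),
                          resolution = NA_real_, rscc = NULL),
                     class = "nucval_structure")
  rep0 <- validate_model(empty)
  expect_equal(rep0$n_pairs, 0)
  expect_true(is.na(rep0$model$rmsz_bpg))
})

test_that("whole-model rmsZ_bpG changes classify by the 0.5 slider", {
  expect_equal(classify_rmszbpg_change(2.0, 1.6), "no meaningful change")
  expect_equal(classify_rmszbpg_change(2.0, 1.4), "improved")
  expect_equal(classify_rmszbpg_change(2.0, 2.6), "deteriorated")
})
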