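#' Specification for one synthetic Watson-Crick base pair
#'
#' @param category "DNA-DNA", "RNA-RNA" or "DNA-RNA".
#' @param pair_type "A-T", "A-U" or "G-C".
#' @param shear,stretch,stagger Translational parameters, Angstrom.
#' @param buckle,propeller,opening Rotational parameters, degrees.
#' @param noise_sd Gaussian noise per coordinate, Angstrom.
#' @param rotation,translation Optional global rigid motion applied to
#'   the finished pair.
#' @param seed Integer controlling all randomness (noise).
#' @return A \code{pair_spec} list.
#' @export
pair_spec <- function(category = "DNA-DNA", pair_type = "G-C",
                      shear = 0, stretch = 0, stagger = 0,
                      buckle = 0, propeller = 0, opening = 0,
                      noise_sd = 0, rotation = NULL, translation = NULL,
                      seed = 1L) {
  p <- list(category = category, pair_type = pair_type,
            shear = shear, stretch = stretch, stagger = stagger,
            buckle = buckle, propeller = propeller, opening = opening,
            noise_sd = noise_sd, rotation = rotation,
            translation = translation, seed = as.integer(seed))
  stopifnot(all(vapply(p[c("shear", "stretch", "stagger", "buckle",
                           "propeller", "opening")],
                       function(x) is.finite(x), logical(1))))
  class(p) <- "pair_spec"
  p
}

## Component ids per (category, pair_type): purine strand first.
## In hybrids the pyrimidine identity fixes which strand is DNA for
## A-T / A-U (T is DNA-only, U RNA-only); G-C hybrids default to DNA G.
synthetic_comp_ids <- function(category, pair_type) {
  key <- paste(category, pair_type)
  switch(key,
    "DNA-DNA A-T" = c("DA", "DT"), "DNA-DNA G-C" = c("DG", "DC"),
    "RNA-RNA A-U" = c("A", "U"),   "RNA-RNA G-C" = c("G", "C"),
    "DNA-RNA A-T" = c("A", "DT"),  "DNA-RNA A-U" = c("DA", "U"),
    "DNA-RNA G-C" = c("DG", "C"),
    stop("no synthetic layout for (", category, ", ", pair_type, ")"))
}

## Place the two bases of a pair for internal parameter vector u
## (shear, stretch, stagger, buckle, propeller, opening) in the
## identity pair frame. Returns list(R_i, o_i, R_j, o_j).
place_pair <- function(u) {
  gamma <- sqrt(u[4]^2 + u[5]^2)
  if (gamma > 1e-12) {
    a <- c(u[4] / gamma, u[5] / gamma, 0)
    Rp <- rotation_about(a, gamma / 2)
    Rm <- rotation_about(a, -gamma / 2)
  } else {
    Rp <- Rm <- diag(3)
  }
  z <- c(0, 0, 1)
  R_i <- Rp %*% rotation_about(z, u[6] / 2)
  R_j_aligned <- Rm %*% rotation_about(z, -u[6] / 2)
  R_j <- R_j_aligned %*% diag(c(1, -1, -1))
  delta <- c(u[1], u[2], u[3])
  list(R_i = R_i, o_i = delta / 2, R_j = R_j, o_j = -delta / 2)
}

## Residue from a standard base under rigid motion (R, o).
placed_residue <- function(base, comp_id, chain, seq_num, R, o) {
  std <- standard_base(base)
  co <- std$coords %*% t(R)
  co <- sweep(co, 2, o, "+")
  res <- list(chain_id = chain, seq_num = seq_num, insertion_code = "",
              comp_id = comp_id,
              atoms = data.frame(
                name = rownames(std$coords),
                element = substr(rownames(std$coords), 1, 1),
                x = co[, 1], y = co[, 2], z = co[, 3],
                altloc = "", occupancy = 1,
                stringsAsFactors = FALSE),
              had_altloc = FALSE)
  classify_residue(res)
}

#' Build a base pair with prescribed simple parameters
#'
#' Forward construction inverse to \code{\link{simple_parameters}}:
#' the two full bases (ring, Watson-Crick exocyclic atoms and C1') are
#' placed so that measuring the result reproduces the prescribed
#' parameters. Because the measured pair frame depends on the built
#' C1' positions, placement is refined by fixed-point iteration until
#' the residual is below 1e-9 (noiseless); prescriptions with
#' out-of-plane angles approaching 90 degrees are rejected as
#' non-invertible.
#'
#' @param spec A \code{\link{pair_spec}}.
#' @return A \code{nucval_structure} fragment with two residues
#'   (purine chain A, pyrimidine chain B).
#' @export
build_pair <- function(spec) {
  if (max(abs(c(spec$buckle, spec$propeller))) >= 85) {
    stop("non-invertible spec: |buckle| or |propeller| near 90 degrees")
  }
  comps <- synthetic_comp_ids(spec$category, spec$pair_type)
  bases <- strsplit(spec$pair_type, "-")[[1]]
  target <- c(spec$shear, spec$stretch, spec$stagger,
              spec$buckle, spec$propeller, spec$opening)
  u <- target
  build_once <- function(u) {
    pl <- place_pair(u)
    list(pu = placed_residue(bases[1], comps[1], "A", 1, pl$R_i, pl$o_i),
         py = placed_residue(bases[2], comps[2], "B", 1, pl$R_j, pl$o_j))
  }
  measure <- function(bp) {
    p <- simple_parameters(base_frame(bp$pu), base_frame(bp$py),
                           residue_coords(bp$pu, "C1'")[1, ],
                           residue_coords(bp$py, "C1'")[1, ])
    c(p$shear, p$stretch, p$stagger, p$buckle, p$propeller, p$opening)
  }
  bp <- build_once(u)
  for (it in seq_len(60)) {
    err <- target - measure(bp)
    if (max(abs(err)) < 1e-10) break
    u <- u + err
    bp <- build_once(u)
    if (it == 60) stop("pair construction did not converge for this spec")
  }
  residues <- list(pu = bp$pu, py = bp$py)
  names(residues) <- c(residue_key("A", 1), residue_key("B", 1))
  st <- structure(list(entry_id = "synthetic-pair", residues = residues,
                       resolution = NA_real_, rscc = NULL),
                  class = "nucval_structure")
  st <- apply_motion_noise(st, spec)
  st
}

apply_motion_noise <- function(st, spec) {
  R <- spec$rotation %||% diag(3)
  t_vec <- spec$translation %||% c(0, 0, 0)
  if (spec$noise_sd > 0) set.seed(spec$seed)
  st$residues <- lapply(st$residues, function(res) {
    co <- as.matrix(res$atoms[, c("x", "y", "z")])
    co <- co %*% t(R)
    co <- sweep(co, 2, t_vec, "+")
    if (spec$noise_sd > 0) {
      co <- co + matrix(stats::rnorm(length(co), 0, spec$noise_sd),
                        ncol = 3)
    }
    res$atoms$x <- co[, 1]; res$atoms$y <- co[, 2]; res$atoms$z <- co[, 3]
    res
  })
  st
}

#' Build a helical duplex of Watson-Crick pairs
#'
#' Stacks \code{n_pairs} built pairs along a common helix axis with
#' the given rise and twist. Purines go to chain A (residues 1..n,
#' 5' to 3'), pyrimidines to chain B with antiparallel numbering.
#'
#' @param n_pairs Number of pairs (>= 1).
#' @param specs A single \code{\link{pair_spec}} recycled for every
#'   step, or a list of one spec per pair.
#' @param rise Helical rise per step, Angstrom.
#' @param twist Helical twist per step, degrees.
#' @param resolution Optional resolution recorded on the model.
#' @return A \code{nucval_structure}.
#' @export
build_duplex <- function(n_pairs, specs = pair_spec(), rise = 3.4,
                         twist = 36, resolution = NA_real_) {
  stopifnot(n_pairs >= 1)
  if (inherits(specs, "pair_spec")) {
    specs <- rep(list(specs), n_pairs)
  }
  stopifnot(length(specs) == n_pairs)
  residues <- list()
  z <- c(0, 0, 1)
  for (k in seq_len(n_pairs)) {
    pr <- build_pair(specs[[k]])
    Rk <- rotation_about(z, (k - 1) * twist)
    tk <- c(0, 0, (k - 1) * rise)
    pu <- move_residue(pr$residues[[1]], Rk, tk)
    py <- move_residue(pr$residues[[2]], Rk, tk)
    pu$chain_id <- "A"; pu$seq_num <- k
    py$chain_id <- "B"; py$seq_num <- n_pairs + 1 - k
    residues[[residue_key("A", k)]] <- pu
    residues[[residue_key("B", n_pairs + 1 - k)]] <- py
  }
  ## Order residues 5' to 3' within each chain.
  ord <- c(paste0("A/", seq_len(n_pairs)), paste0("B/", seq_len(n_pairs)))
  structure(list(entry_id = "synthetic-duplex",
                 residues = residues[ord],
                 resolution = resolution, rscc = NULL),
            class = "nucval_structure")
}

move_residue <- function(res, R, t_vec) {
  co <- as.matrix(res$atoms[, c("x", "y", "z")]) %*% t(R)
  co <- sweep(co, 2, t_vec, "+")
  res$atoms$x <- co[, 1]; res$atoms$y <- co[, 2]; res$atoms$z <- co[, 3]
  res
}

#' Synthetic annotated structure collection with known truth
#'
#' Emulates the curated mining corpus: entries containing Watson-Crick
#' pairs whose simple parameters are drawn from per-class Gaussians
#' (defaults: the embedded target tables), with per-entry resolutions
#' and per-residue RSCC values drawn as specified. Two forms are
#' available: pre-extracted observation records (fast; bond lengths
#' are drawn directly from the hydrogen-bond Gaussians) or full
#' coordinate models (bond lengths are then emergent from the built
#' geometry).
#'
#' @param n_entries Number of entries.
#' @param pairs_per_entry Pairs per entry.
#' @param classes data.frame(category, pair_type) of pair classes to
#'   draw from (uniformly); defaults to the seven target classes.
#' @param simple_targets,hbond_targets Gaussian parameter tables in
#'   the target-table format.
#' @param resolution_range Entry resolutions drawn uniformly from this
#'   range, Angstrom.
#' @param rscc_mean,rscc_sd Gaussian RSCC model (truncated at 1).
#' @param seed Integer seed fixing all randomness.
#' @param as "records" or "structures".
#' @return list(records or structures (+ rscc sidecar maps), truth).
#' @export
synth_collection <- function(n_entries, pairs_per_entry = 4,
                             classes = NULL,
                             simple_targets = load_simple_targets(),
                             hbond_targets = load_hbond_targets(),
                             resolution_range = c(1.0, 1.6),
                             rscc_mean = 0.975, rscc_sd = 0.01,
                             seed = 1L, as = c("records", "structures")) {
  as <- match.arg(as)
  set.seed(as.integer(seed))
  if (is.null(classes)) {
    classes <- unique(simple_targets[, c("category", "pair_type")])
  }
  truth <- list(simple = simple_targets, hbond = hbond_targets,
                resolution_range = resolution_range,
                rscc_mean = rscc_mean, rscc_sd = rscc_sd)
  if (n_entries == 0) {
    return(list(records = empty_records(), structures = list(),
                truth = truth))
  }
  draw_rscc <- function(n) pmin(1, stats::rnorm(n, rscc_mean, rscc_sd))
  sp_lookup <- function(cat, pt, key) {
    i <- which(simple_targets$category == cat &
                 simple_targets$pair_type == pt & simple_targets$key == key)
    simple_targets[i, c("mean", "sd")]
  }
  records <- list()
  structures <- list()
  rsccs <- list()
  for (e in seq_len(n_entries)) {
    entry_id <- sprintf("synth%04d", e)
    res_e <- stats::runif(1, resolution_range[1], resolution_range[2])
    cls <- classes[sample(nrow(classes), pairs_per_entry, replace = TRUE), ,
                   drop = FALSE]
    if (as == "records") {
      for (k in seq_len(pairs_per_entry)) {
        cat <- cls$category[k]; pt <- cls$pair_type[k]
        hb <- hbond_targets[hbond_targets$category == cat &
                              hbond_targets$pair_type == pt, , drop = FALSE]
        bonds <- stats::setNames(
          stats::rnorm(nrow(hb), hb$mean, hb$sd), hb$key)
        par <- vapply(c("shear", "stretch", "buckle", "propeller"),
                      function(kk) {
                        g <- sp_lookup(cat, pt, kk)
                        stats::rnorm(1, g$mean, g$sd)
                      }, numeric(1))
        records[[length(records) + 1]] <- data.frame(
          entry_id = entry_id, res_i = paste0("A/", k),
          res_j = paste0("B/", k), category = cat, pair_type = pt,
          contains_modified = FALSE,
          shear = par[["shear"]], stretch = par[["stretch"]],
          buckle = par[["buckle"]], propeller = par[["propeller"]],
          bond_key = paste(names(bonds), collapse = ";"),
          bond_dist = paste(sprintf("%.6f", bonds), collapse = ";"),
          resolution = res_e,
          rscc_i = draw_rscc(1), rscc_j = draw_rscc(1),
          stringsAsFactors = FALSE)
      }
    } else {
      residues <- list()
      rscc <- numeric(0)
      for (k in seq_len(pairs_per_entry)) {
        cat <- cls$category[k]; pt <- cls$pair_type[k]
        par <- vapply(c("shear", "stretch", "buckle", "propeller"),
                      function(kk) {
                        g <- sp_lookup(cat, pt, kk)
                        stats::rnorm(1, g$mean, g$sd)
                      }, numeric(1))
        sp <- pair_spec(category = cat, pair_type = pt,
                        shear = par[["shear"]], stretch = par[["stretch"]],
                        stagger = stats::rnorm(1, 0, 0.1),
                        buckle = par[["buckle"]],
                        propeller = par[["propeller"]],
                        opening = stats::rnorm(1, 0, 1.5))
        pr <- build_pair(sp)
        ## Separate the pairs spatially so they never cross-contact.
        pu <- move_residue(pr$residues[[1]], diag(3), c(30 * k, 0, 0))
        py <- move_residue(pr$residues[[2]], diag(3), c(30 * k, 0, 0))
        pu$seq_num <- k; py$seq_num <- k
        ki <- residue_key("A", k); kj <- residue_key("B", k)
        residues[[ki]] <- pu
        residues[[kj]] <- py
        rscc[ki] <- draw_rscc(1); rscc[kj] <- draw_rscc(1)
      }
      structures[[entry_id]] <- structure(
        list(entry_id = entry_id, residues = residues,
             resolution = res_e, rscc = rscc),
        class = "nucval_structure")
      rsccs[[entry_id]] <- rscc
    }
  }
  list(records = if (length(records)) do.call(rbind, records)
                 else empty_records(),
       structures = structures, rsccs = rsccs, truth = truth)
}

empty_records <- function() {
  data.frame(entry_id = character(0), res_i = character(0),
             res_j = character(0), category = character(0),
             pair_type = character(0), contains_modified = logical(0),
             shear = numeric(0), stretch = numeric(0),
             buckle = numeric(0), propeller = numeric(0),
             bond_key = character(0), bond_dist = character(0),
             resolution = numeric(0), rscc_i = numeric(0),
             rscc_j = numeric(0), stringsAsFactors = FALSE)
}
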