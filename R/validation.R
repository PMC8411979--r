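#' Z score of a measurement against a target
#'
#' @param value Measured value.
#' @param mean,sd Target mean and standard deviation (sd > 0).
#' @return (value - mean) / sd.
#' @export
zscore <- function(value, mean, sd) {
  if (any(sd <= 0)) stop("sd must be positive")
  (value - mean) / sd
}

#' Per-pair base-pair geometry score Z_bpG
#'
#' Combines the Z scores of shear, stretch, buckle and propeller into
#' one normality score per base pair. The default form is the root
#' mean square of the four Z values; \code{form = "mean_abs"} (mean of
#' absolute Z values) is available as an alternative. Pairs with
#' Z_bpG > 3.00 are flagged as outliers downstream; an outlier does
#' not necessarily mark a modelling error, only decreasing likelihood
#' of one as the score grows.
#'
#' @param z_shear,z_stretch,z_buckle,z_propeller The four Z scores.
#' @param form "rms" (default) or "mean_abs".
#' @export
zbpg <- function(z_shear, z_stretch, z_buckle, z_propeller,
                 form = c("rms", "mean_abs")) {
  form <- match.arg(form)
  z <- c(z_shear, z_stretch, z_buckle, z_propeller)
  if (form == "rms") sqrt(mean(z^2)) else mean(abs(z))
}

#' Root-mean-square Z score
#'
#' @param values Z scores (non-empty for a defined result).
#' @return sqrt(mean(values^2)); NA (absent metric) on an empty input.
#' @export
rmsz <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(NA_real_)
  sqrt(mean(values^2))
}

#' Jackknife standard deviation of a statistic
#'
#' Leave-one-out resampling estimate:
#' sd = sqrt(((n-1)/n) * sum((theta_(i) - theta_bar)^2)), where
#' theta_(i) is the statistic computed without element i.
#'
#' @param values Sample values (need n >= 2).
#' @param statistic Function of a numeric vector; default
#'   \code{\link{rmsz}}.
#' @return The jackknife SD, or NA when n < 2.
#' @export
jackknife_sd <- function(values, statistic = rmsz) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) return(NA_real_)
  theta <- vapply(seq_len(n), function(i) statistic(values[-i]), numeric(1))
  sqrt((n - 1) / n * sum((theta - mean(theta))^2))
}

#' Standardized change of a quality metric between two models
#'
#' z_change = (m_before - m_after) / sqrt(sd_before^2 + sd_after^2),
#' so positive values mean improvement for lower-is-better metrics.
#' |z_change| > 2.6 is significant. When neither SD is available the
#' significance is undetermined (NA), mirroring metrics for which no
#' spread estimate exists.
#'
#' @param m_before,m_after Metric values.
#' @param sd_before,sd_after Their estimated standard deviations
#'   (either may be NA).
#' @param metric Optional metric name carried into the result.
#' @return list(metric, value_before, value_after, sd_before,
#'   sd_after, z_change, significant).
#' @export
zchange <- function(m_before, sd_before, m_after, sd_after,
                    metric = NA_character_) {
  s1 <- if (is.na(sd_before)) 0 else sd_before
  s2 <- if (is.na(sd_after)) 0 else sd_after
  denom <- sqrt(s1^2 + s2^2)
  if (is.na(sd_before) && is.na(sd_after)) {
    z <- NA_real_
    sig <- NA
  } else if (denom == 0) {
    z <- if (m_before == m_after) 0 else sign(m_before - m_after) * Inf
    sig <- abs(z) > 2.6
  } else {
    z <- (m_before - m_after) / denom
    sig <- abs(z) > 2.6
  }
  list(metric = metric, value_before = m_before, value_after = m_after,
       sd_before = sd_before, sd_after = sd_after,
       z_change = z, significant = sig)
}

#' Bond-valence sum of a coordinated ion
#'
#' Sum of exp((R_o - d) / B) over ligand atoms within the coordination
#' cutoff. For a divalent cation such as Cd2+ the expected sum is
#' about 2.0; for Cd the published parameters are R_o = 1.875 A for
#' oxygen ligands and R_o = 1.951 A for ring-nitrogen ligands, with
#' B = 0.37 A.
#'
#' @param center Position (3-vector) of the ion.
#' @param ligands Matrix (n x 3) of ligand positions.
#' @param r_o Length-n (or scalar) R_o per ligand, Angstrom.
#' @param b Bond-valence B parameter, Angstrom.
#' @param cutoff Coordination cutoff, Angstrom.
#' @return The bond-valence sum.
#' @export
bond_valence <- function(center, ligands, r_o, b = 0.37, cutoff = 3.0) {
  ligands <- matrix(ligands, ncol = 3)
  d <- sqrt(rowSums(sweep(ligands, 2, center)^2))
  if (any(d <= 0)) stop("ligand distances must be positive")
  r_o <- rep_len(r_o, length(d))
  keep <- d <= cutoff
  sum(exp((r_o[keep] - d[keep]) / b))
}

#' Validate the Watson-Crick base-pair geometry of a model
#'
#' Detects and classifies the Watson-Crick pairs, scores every pair's
#' simple parameters and hydrogen bonds against the target tables, and
#' aggregates model-level rmsZ metrics with jackknife standard
#' deviations. Pairs belonging to classes without targets (e.g. A-U in
#' DNA) are reported unvalidated; pairs with Z_bpG > 3.00 are flagged
#' as outliers.
#'
#' @param structure A \code{nucval_structure}.
#' @param screen Detection cutoffs, see \code{default_screen()}.
#' @param hbond_targets,simple_targets Optional replacement target
#'   tables.
#' @param zbpg_form Functional form passed to \code{\link{zbpg}}.
#' @return An object of class \code{nucval_report}: list(entry_id,
#'   pairs (per-pair data.frame), hbonds (per-bond data.frame), model
#'   (named metrics with SDs), counts, rejected).
#' @export
validate_model <- function(structure, screen = default_screen(),
                           hbond_targets = NULL, simple_targets = NULL,
                           zbpg_form = c("rms", "mean_abs")) {
  zbpg_form <- match.arg(zbpg_form)
  hbond_targets <- hbond_targets %||% load_hbond_targets()
  simple_targets <- simple_targets %||% load_simple_targets()
  det <- find_wc_pairs(structure, screen, targets = hbond_targets)
  pairs <- det$pairs

  prow <- list()
  brow <- list()
  for (p in pairs) {
    zs <- vapply(c("shear", "stretch", "buckle", "propeller"),
                 function(k) {
                   tg <- tryCatch(lookup_simple_target(
                     p$category, p$pair_type, k, simple_targets),
                     error = function(e) NULL)
                   if (is.null(tg)) return(NA_real_)
                   zscore(p$params[[k]], tg$mean, tg$sd)
                 }, numeric(1))
    validated <- !anyNA(zs)
    zb <- if (validated) {
      zbpg(zs[["shear"]], zs[["stretch"]], zs[["buckle"]],
           zs[["propeller"]], form = zbpg_form)
    } else NA_real_
    prow[[length(prow) + 1]] <- data.frame(
      pair_id = paste0(p$res_i, "-", p$res_j),
      res_i = p$res_i, res_j = p$res_j,
      category = p$category, pair_type = p$pair_type,
      contains_modified = p$contains_modified,
      shear = p$params$shear, stretch = p$params$stretch,
      stagger = p$params$stagger, buckle = p$params$buckle,
      propeller = p$params$propeller, opening = p$params$opening,
      z_shear = zs[["shear"]], z_stretch = zs[["stretch"]],
      z_buckle = zs[["buckle"]], z_propeller = zs[["propeller"]],
      z_bpg = zb, validated = validated,
      outlier = !is.na(zb) & zb > 3.00,
      stringsAsFactors = FALSE)
    for (k in seq_len(nrow(p$hbonds))) {
      key <- paste0(p$hbonds$atom_i[k], "-", p$hbonds$atom_j[k])
      tg <- tryCatch(lookup_hbond_target(p$category, p$pair_type, key,
                                         hbond_targets),
                     error = function(e) NULL)
      z <- if (is.null(tg) || is.na(p$hbonds$distance[k])) NA_real_
           else zscore(p$hbonds$distance[k], tg$mean, tg$sd)
      brow[[length(brow) + 1]] <- data.frame(
        pair_id = paste0(p$res_i, "-", p$res_j),
        category = p$category, pair_type = p$pair_type, key = key,
        distance = p$hbonds$distance[k], z = z,
        stringsAsFactors = FALSE)
    }
  }
  ptab <- if (length(prow)) do.call(rbind, prow) else empty_pair_table()
  btab <- if (length(brow)) do.call(rbind, brow) else empty_bond_table()

  model <- list(
    hbond_rmsz = rmsz(btab$z),
    hbond_rmsz_sd = jackknife_sd(btab$z),
    rmsz_bpg = rmsz(ptab$z_bpg),
    rmsz_bpg_sd = jackknife_sd(ptab$z_bpg))
  for (k in c("shear", "stretch", "buckle", "propeller")) {
    z <- ptab[[paste0("z_", k)]]
    model[[paste0(k, "_rmsz")]] <- rmsz(z)
    model[[paste0(k, "_rmsz_sd")]] <- jackknife_sd(z)
  }

  counts <- as.data.frame(table(category = ptab$category,
                                pair_type = ptab$pair_type),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, , drop = FALSE]
  structure(list(entry_id = structure$entry_id, pairs = ptab,
                 hbonds = btab, model = model, counts = counts,
                 n_pairs = nrow(ptab), rejected = det$rejected,
                 zbpg_form = zbpg_form),
            class = "nucval_report")
}

empty_pair_table <- function() {
  data.frame(pair_id = character(0), res_i = character(0),
             res_j = character(0), category = character(0),
             pair_type = character(0), contains_modified = logical(0),
             shear = numeric(0), stretch = numeric(0),
             stagger = numeric(0), buckle = numeric(0),
             propeller = numeric(0), opening = numeric(0),
             z_shear = numeric(0), z_stretch = numeric(0),
             z_buckle = numeric(0), z_propeller = numeric(0),
             z_bpg = numeric(0), validated = logical(0),
             outlier = logical(0), stringsAsFactors = FALSE)
}

empty_bond_table <- function() {
  data.frame(pair_id = character(0), category = character(0),
             pair_type = character(0), key = character(0),
             distance = numeric(0), z = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.nucval_report <- function(x, ...) {
  fmt <- function(v, s) {
    if (is.na(v)) return("absent")
    paste0(sprintf("%.2f", v),
           if (!is.na(s)) paste0(" +/- ", sprintf("%.2f", s)) else "")
  }
  cat("Watson-Crick validation of '", x$entry_id, "': ", x$n_pairs,
      " pairs, ", sum(x$pairs$outlier), " outlier(s) (Z_bpG > 3.00)\n",
      sep = "")
  m <- x$model
  cat("  hydrogen-bond rmsZ: ", fmt(m$hbond_rmsz, m$hbond_rmsz_sd), "\n",
      sep = "")
  for (k in c("shear", "stretch", "buckle", "propeller")) {
    cat("  ", format(k, width = 9), " rmsZ: ",
        fmt(m[[paste0(k, "_rmsz")]], m[[paste0(k, "_rmsz_sd")]]), "\n",
        sep = "")
  }
  cat("  rmsZ_bpG: ", fmt(m$rmsz_bpg, m$rmsz_bpg_sd), "\n", sep = "")
  invisible(x)
}

#' Classify a change in model-level rmsZ_bpG
#'
#' A whole-model change counts as meaningful only when it exceeds
#' twice the magnitude expected from plain re-refinement:
#' |delta| > 0.5.
#'
#' @param before,after rmsZ_bpG of the two models.
#' @return "improved", "deteriorated" or "no meaningful change".
#' @export
classify_rmszbpg_change <- function(before, after) {
  delta <- after - before
  if (delta < -0.5) "improved"
  else if (delta > 0.5) "deteriorated"
  else "no meaningful change"
}
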