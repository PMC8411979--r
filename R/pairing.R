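## Default detection screens. Deliberately liberal so that poorly
## modelled pairs (hydrogen-bond contacts out to >4 A) are still found
## and can be pulled back by restraints; tightened classification
## happens in classify_pair.
default_screen <- function() {
  list(origin_max = 15,      # A, base-frame origin pre-screen
       contact_max = 4.5,    # A, at least one inter-base N/O-N/O contact
       angle_max = 65,       # deg, aligned interbase angle
       stagger_max = 2.5)    # A, vertical separation
}

#' Find candidate base pairs
#'
#' Returns all residue pairs whose fitted base-frame origins lie within
#' the origin cutoff and which make at least one inter-base N/O to N/O
#' contact below the screen distance. Only base-moiety N/O atoms (ring
#' plus Watson-Crick exocyclic atoms) are considered, so backbone
#' phosphate contacts never create candidates.
#'
#' @param structure A \code{nucval_structure}.
#' @param screen Cutoff list, see \code{default_screen()}.
#' @return data.frame(res_i, res_j) of candidate residue keys.
#' @export
find_candidate_pairs <- function(structure, screen = default_screen()) {
  fr <- structure_frames(structure)
  keys <- names(fr)
  empty <- data.frame(res_i = character(0), res_j = character(0),
                      stringsAsFactors = FALSE)
  if (length(keys) < 2) return(empty)
  origins <- t(vapply(fr, function(f) f$origin, numeric(3)))
  no_coords <- lapply(keys, function(k) base_no_atoms(structure$residues[[k]]))
  names(no_coords) <- keys
  out <- list()
  for (a in seq_len(length(keys) - 1)) {
    for (b in seq(a + 1, length(keys))) {
      if (vnorm(origins[a, ] - origins[b, ]) > screen$origin_max) next
      da <- no_coords[[a]]
      db <- no_coords[[b]]
      if (nrow(da) == 0 || nrow(db) == 0) next
      dmin <- min(pairwise_dists(da, db))
      if (dmin <= screen$contact_max) {
        out[[length(out) + 1]] <- c(keys[a], keys[b])
      }
    }
  }
  if (length(out) == 0) return(empty)
  m <- do.call(rbind, out)
  data.frame(res_i = m[, 1], res_j = m[, 2], stringsAsFactors = FALSE)
}

## Base frames for all usable residues; failures (incomplete bases) skipped.
structure_frames <- function(structure) {
  out <- list()
  for (k in names(structure$residues)) {
    res <- structure$residues[[k]]
    if (is.null(res$usable) || !res$usable) next
    f <- tryCatch(base_frame(res), error = function(e) NULL)
    if (!is.null(f)) out[[k]] <- f
  }
  out
}

base_no_atoms <- function(residue) {
  std <- standard_base(residue$parent_base)
  keep <- std$atoms[grepl("^[NO]", std$atoms) & std$atoms != "O2'"]
  co <- residue_coords(residue, keep)
  co[stats::complete.cases(co), , drop = FALSE]
}

pairwise_dists <- function(a, b) {
  sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b))
}

#' Classify a candidate as a Watson-Crick pair or reject it
#'
#' A candidate is Watson-Crick iff the parent bases form \{A,T\},
#' \{A,U\} or \{G,C\}, the base normals are antiparallel (aligned
#' interbase angle within the screen), the vertical separation
#' (stagger) is within the screen, and all standard-bond atoms are
#' present. The returned pair is in canonical purine-first order with
#' measured simple parameters and hydrogen-bond lengths attached.
#' Rejection is a result, not an error, and carries a machine-readable
#' reason.
#'
#' @param candidate c(res_i, res_j) residue keys.
#' @param structure A \code{nucval_structure}.
#' @param screen Cutoff list.
#' @return A \code{nucval_pair} or a list with \code{rejected = TRUE}
#'   and a \code{reason}.
#' @export
classify_pair <- function(candidate, structure, screen = default_screen()) {
  ri <- structure$residues[[candidate[1]]]
  rj <- structure$residues[[candidate[2]]]
  if (is.null(ri) || is.null(rj)) {
    return(rejection(candidate, "unknown-residue"))
  }
  bases <- sort(c(ri$parent_base, rj$parent_base))
  combo <- paste(bases, collapse = "")
  pair_type <- switch(combo, "AT" = "A-T", "AU" = "A-U", "CG" = "G-C", NULL)
  if (is.null(pair_type)) {
    return(rejection(candidate, "non-WC-combination"))
  }
  ## Canonical purine-first order.
  if (!is_purine(ri$parent_base)) {
    tmp <- ri; ri <- rj; rj <- tmp
    candidate <- rev(candidate)
    flipped <- TRUE
  } else {
    flipped <- FALSE
  }
  fi <- tryCatch(base_frame(ri), error = function(e) NULL)
  fj <- tryCatch(base_frame(rj), error = function(e) NULL)
  if (is.null(fi) || is.null(fj)) {
    return(rejection(candidate, "incomplete-base"))
  }
  if (sum(fi$z * fj$z) > 0) {
    ## Normals parallel after the antiparallel convention -> aligned
    ## angle beyond 90 deg; treat as non-WC geometry.
    return(rejection(candidate, "not-antiparallel"))
  }
  c1i <- residue_coords(ri, "C1'")[1, ]
  c1j <- residue_coords(rj, "C1'")[1, ]
  if (anyNA(c1i) || anyNA(c1j)) {
    return(rejection(candidate, "missing-C1'"))
  }
  params <- tryCatch(simple_parameters(fi, fj, c1i, c1j),
                     error = function(e) NULL)
  if (is.null(params) || params$interbase_angle > screen$angle_max) {
    return(rejection(candidate, "interbase-angle"))
  }
  if (abs(params$stagger) > screen$stagger_max) {
    return(rejection(candidate, "vertical-separation"))
  }
  hb <- hbond_lengths(ri, rj, pair_type)
  if (any(hb$missing)) {
    return(rejection(candidate, "missing-bond-atoms"))
  }
  category <- pair_category(ri$nucleic_class, rj$nucleic_class)
  structure(list(
    res_i = candidate[1], res_j = candidate[2],
    category = category, pair_type = pair_type,
    contains_modified = isTRUE(ri$is_modified) || isTRUE(rj$is_modified),
    had_altloc = isTRUE(ri$had_altloc) || isTRUE(rj$had_altloc),
    order_flipped = flipped,
    params = params, hbonds = hb),
    class = "nucval_pair")
}

rejection <- function(candidate, reason) {
  list(rejected = TRUE, res_i = candidate[1], res_j = candidate[2],
       reason = reason)
}

pair_category <- function(class_i, class_j) {
  cls <- sort(c(class_i, class_j))
  if (identical(cls, c("DNA", "DNA"))) "DNA-DNA"
  else if (identical(cls, c("RNA", "RNA"))) "RNA-RNA"
  else "DNA-RNA"
}

#' Put a classified pair in canonical purine-first order
#'
#' The sign of shear and buckle depends on the base-pair direction, so
#' re-ordering to purine-first negates both and records the flip.
#' Idempotent; pairs already canonical are returned unchanged.
#'
#' @param pair A \code{nucval_pair} together with its structure (for
#'   residue lookup).
#' @param structure The parent \code{nucval_structure}.
#' @export
canonical_order <- function(pair, structure) {
  ri <- structure$residues[[pair$res_i]]
  if (is_purine(ri$parent_base)) return(pair)
  tmp <- pair$res_i
  pair$res_i <- pair$res_j
  pair$res_j <- tmp
  pair$params$shear <- -pair$params$shear
  pair$params$buckle <- -pair$params$buckle
  pair$order_flipped <- !isTRUE(pair$order_flipped)
  pair
}

#' Detect and classify all Watson-Crick pairs of a model
#'
#' Runs the full candidate screen and classification and resolves
#' conflicts so no residue appears in two Watson-Crick pairs: when
#' candidates share a residue the pair with more satisfied hydrogen
#' bonds wins, ties broken by the smaller mean absolute deviation from
#' the hydrogen-bond target means.
#'
#' @param structure A \code{nucval_structure}.
#' @param screen Cutoff list.
#' @param targets Optional replacement hydrogen-bond target table.
#' @return list(pairs = list of \code{nucval_pair}, rejected =
#'   data.frame(res_i, res_j, reason)).
#' @export
find_wc_pairs <- function(structure, screen = default_screen(),
                          targets = NULL) {
  targets <- targets %||% load_hbond_targets()
  cand <- find_candidate_pairs(structure, screen)
  pairs <- list()
  rejected <- list()
  if (nrow(cand) > 0) {
    for (i in seq_len(nrow(cand))) {
      p <- classify_pair(c(cand$res_i[i], cand$res_j[i]), structure, screen)
      if (isTRUE(p$rejected)) {
        rejected[[length(rejected) + 1]] <- p
      } else {
        pairs[[length(pairs) + 1]] <- p
      }
    }
  }
  ## Conflict resolution: greedy by (satisfied bonds, -mean |dev|).
  if (length(pairs) > 1) {
    score <- vapply(pairs, function(p) {
      ok <- sum(!p$hbonds$missing)
      dev <- mean(vapply(seq_len(nrow(p$hbonds)), function(k) {
        tg <- tryCatch(lookup_hbond_target(
          p$category, p$pair_type,
          paste0(p$hbonds$atom_i[k], "-", p$hbonds$atom_j[k]), targets),
          error = function(e) NULL)
        if (is.null(tg) || is.na(p$hbonds$distance[k])) return(1)
        abs(p$hbonds$distance[k] - tg$mean)
      }, numeric(1)))
      ok * 100 - dev
    }, numeric(1))
    ord <- order(score, decreasing = TRUE)
    used <- character(0)
    keep <- logical(length(pairs))
    for (i in ord) {
      p <- pairs[[i]]
      if (!(p$res_i %in% used) && !(p$res_j %in% used)) {
        keep[i] <- TRUE
        used <- c(used, p$res_i, p$res_j)
      }
    }
    dropped <- pairs[!keep]
    pairs <- pairs[keep]
    for (p in dropped) {
      rejected[[length(rejected) + 1]] <-
        rejection(c(p$res_i, p$res_j), "conflicting-pair")
    }
  }
  rej <- if (length(rejected)) {
    data.frame(res_i = vapply(rejected, `[[`, "", "res_i"),
               res_j = vapply(rejected, `[[`, "", "res_j"),
               reason = vapply(rejected, `[[`, "", "reason"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(res_i = character(0), res_j = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  list(pairs = pairs, rejected = rej)
}
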