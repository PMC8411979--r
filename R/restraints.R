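#' Resolution gate for nucleic-acid restraints
#'
#' Restraints are generated only when the diffraction data are worse
#' than 1.70 A; at resolutions better than or equal to 1.70 A the
#' targets are still produced, but for validation only. An unknown
#' resolution defaults to generating restraints (with a message).
#'
#' @param resolution Resolution in Angstrom, or NA.
#' @return TRUE iff restraints should be generated.
#' @export
resolution_gate <- function(resolution) {
  if (is.na(resolution)) {
    message("resolution unknown; restraint gate defaults to open")
    return(TRUE)
  }
  resolution > 1.70
}

#' Hydrogen-bond distance restraints for Watson-Crick pairs
#'
#' One distance restraint per standard bond per classified pair, with
#' target and sigma taken verbatim from the hydrogen-bond target table
#' and the block weight set to 2. Pairs involving residues with
#' alternate conformations are excluded, as are pairs whose class has
#' no targets (logged via the returned \code{skipped} attribute).
#'
#' @param pairs List of \code{nucval_pair} (from
#'   \code{\link{find_wc_pairs}}).
#' @param structure The parent structure (for residue selectors).
#' @param targets Optional replacement hydrogen-bond target table.
#' @return data.frame of distance restraints with attribute
#'   \code{skipped}.
#' @export
hbond_restraints <- function(pairs, structure, targets = NULL) {
  targets <- targets %||% load_hbond_targets()
  rows <- list()
  skipped <- character(0)
  for (p in pairs) {
    if (isTRUE(p$had_altloc)) {
      skipped <- c(skipped, paste0(p$res_i, "-", p$res_j, ": altloc"))
      next
    }
    ri <- structure$residues[[p$res_i]]
    rj <- structure$residues[[p$res_j]]
    tg1 <- tryCatch(
      lapply(seq_len(nrow(p$hbonds)), function(k)
        lookup_hbond_target(p$category, p$pair_type,
                            paste0(p$hbonds$atom_i[k], "-",
                                   p$hbonds$atom_j[k]), targets)),
      error = function(e) NULL)
    if (is.null(tg1)) {
      skipped <- c(skipped,
                   paste0(p$res_i, "-", p$res_j, ": no targets for ",
                          p$category, " ", p$pair_type))
      next
    }
    for (k in seq_len(nrow(p$hbonds))) {
      rows[[length(rows) + 1]] <- data.frame(
        kind = "distance",
        chain_1 = ri$chain_id, seq_1 = ri$seq_num,
        ins_1 = ri$insertion_code, atom_1 = p$hbonds$atom_i[k],
        chain_2 = rj$chain_id, seq_2 = rj$seq_num,
        ins_2 = rj$insertion_code, atom_2 = p$hbonds$atom_j[k],
        target = tg1[[k]]$mean, sigma = tg1[[k]]$sd, weight = 2,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_restraints()
  attr(out, "skipped") <- skipped
  out
}

empty_restraints <- function() {
  data.frame(kind = character(0), chain_1 = character(0),
             seq_1 = integer(0), ins_1 = character(0),
             atom_1 = character(0), chain_2 = character(0),
             seq_2 = integer(0), ins_2 = character(0),
             atom_2 = character(0), target = numeric(0),
             sigma = numeric(0), weight = numeric(0),
             stringsAsFactors = FALSE)
}

#' Base-stacking parallel-plane restraints
#'
#' One parallel-plane restraint per stacked contact between the bases
#' of sequential residues in a chain, with the interplanar distance
#' target of 3.4 A and block weight 5. Stacking partners are
#' consecutive residues whose base-frame origins are 2.5-5.0 A apart
#' along the mean base normal. Residues with alternate conformations
#' are excluded. Plane restraints reference the ring-atom sets of the
#' two bases.
#'
#' @param structure A \code{nucval_structure}.
#' @param sep_range Allowed origin separation along the mean normal.
#' @param target Interplanar distance target, Angstrom.
#' @param sigma Restraint sigma, Angstrom.
#' @return data.frame of plane restraints (one row per contact;
#'   ring-atom lists semicolon-joined).
#' @export
stacking_restraints <- function(structure, sep_range = c(2.5, 5.0),
                                target = 3.4, sigma = 0.2) {
  fr <- structure_frames(structure)
  rows <- list()
  keys <- names(structure$residues)
  for (i in seq_along(keys)[-1]) {
    k1 <- keys[i - 1]; k2 <- keys[i]
    r1 <- structure$residues[[k1]]; r2 <- structure$residues[[k2]]
    if (r1$chain_id != r2$chain_id) next
    if (abs(r2$seq_num - r1$seq_num) != 1) next
    if (isTRUE(r1$had_altloc) || isTRUE(r2$had_altloc)) next
    f1 <- fr[[k1]]; f2 <- fr[[k2]]
    if (is.null(f1) || is.null(f2)) next
    zm <- f1$z + if (sum(f1$z * f2$z) >= 0) f2$z else -f2$z
    if (vnorm(zm) < 1e-9) next
    zm <- unitv(zm)
    sep <- abs(sum((f2$origin - f1$origin) * zm))
    if (sep < sep_range[1] || sep > sep_range[2]) next
    rows[[length(rows) + 1]] <- data.frame(
      kind = "parallel_plane",
      chain_1 = r1$chain_id, seq_1 = r1$seq_num,
      ins_1 = r1$insertion_code,
      atom_1 = paste(ring_atom_names(r1$parent_base), collapse = ";"),
      chain_2 = r2$chain_id, seq_2 = r2$seq_num,
      ins_2 = r2$insertion_code,
      atom_2 = paste(ring_atom_names(r2$parent_base), collapse = ";"),
      target = target, sigma = sigma, weight = 5,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else empty_restraints()
}

#' Write external restraints in the refinement dialect
#'
#' Plain-text external-restraint records readable by the bundled
#' parser (\code{\link{read_external_restraints}}): per-kind scale
#' directives (hydrogen-bond block weight 2, stacking block weight 5),
#' then one \code{dist} record per distance restraint and one
#' \code{plan} record per plane restraint. The body carries no
#' timestamps, so regeneration on an unchanged model is byte-stable.
#'
#' @param restraints data.frame from \code{\link{hbond_restraints}}
#'   and/or \code{\link{stacking_restraints}} (rbind them).
#' @param path Output file.
#' @param header Extra comment lines for the file head.
#' @export
write_external_restraints <- function(restraints, path,
                                      header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# nucval external restraints format 1",
               paste0("# ", header)[nzchar(header)]), con)
  if (nrow(restraints) == 0) return(invisible(path))
  ins <- function(x) ifelse(nzchar(x), x, ".")
  for (kind in unique(restraints$kind)) {
    blk <- restraints[restraints$kind == kind, , drop = FALSE]
    writeLines(sprintf("exte weight scale %g", blk$weight[1]), con)
    for (i in seq_len(nrow(blk))) {
      r <- blk[i, ]
      rec <- if (kind == "distance") "dist" else "plan"
      writeLines(paste(
        "exte", rec,
        "first chain", r$chain_1, "resi", r$seq_1, "ins", ins(r$ins_1),
        "atom", r$atom_1,
        "second chain", r$chain_2, "resi", r$seq_2, "ins", ins(r$ins_2),
        "atom", r$atom_2,
        "value", sprintf("%.3f", r$target),
        "sigma", sprintf("%.3f", r$sigma)), con)
    }
  }
  invisible(path)
}

#' @rdname write_external_restraints
#' @export
read_external_restraints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  rows <- list()
  weight <- NA_real_
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (identical(f[1:3], c("exte", "weight", "scale"))) {
      weight <- as.numeric(f[4])
      next
    }
    v <- function(name) f[which(f == name)[1] + 1]
    second <- which(f == "second")
    v2 <- function(name) f[second + which(f[second:length(f)] == name)[1]]
    rows[[length(rows) + 1]] <- data.frame(
      kind = ifelse(f[2] == "dist", "distance", "parallel_plane"),
      chain_1 = v("chain"), seq_1 = as.integer(v("resi")),
      ins_1 = ifelse(v("ins") == ".", "", v("ins")), atom_1 = v("atom"),
      chain_2 = v2("chain"), seq_2 = as.integer(v2("resi")),
      ins_2 = ifelse(v2("ins") == ".", "", v2("ins")), atom_2 = v2("atom"),
      target = as.numeric(v("value")), sigma = as.numeric(v("sigma")),
      weight = weight, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else empty_restraints()
}

#' Generate the full restraint set for a model
#'
#' Hydrogen-bond restraints for all classified Watson-Crick pairs plus
#' stacking restraints, subject to the resolution gate. A pure
#' function of (structure, targets, gate): no timestamps, so repeated
#' generation is byte-identical.
#'
#' @param structure A \code{nucval_structure}.
#' @param resolution Override for the structure's recorded resolution.
#' @param nonucrest Disable all nucleic-acid restraints.
#' @param screen,targets Passed through to detection/lookup.
#' @return data.frame of restraints (possibly empty) with attribute
#'   \code{gate_open}.
#' @export
generate_restraints <- function(structure, resolution = NULL,
                                nonucrest = FALSE,
                                screen = default_screen(),
                                targets = NULL) {
  res <- resolution %||% structure$resolution
  open <- !nonucrest && resolution_gate(res)
  out <- if (!open) {
    empty_restraints()
  } else {
    det <- find_wc_pairs(structure, screen, targets = targets)
    rbind(hbond_restraints(det$pairs, structure, targets = targets),
          stacking_restraints(structure))
  }
  attr(out, "gate_open") <- open
  out
}
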