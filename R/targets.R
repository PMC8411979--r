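#' Mined Watson-Crick target tables
#'
#' The package embeds two target tables mined from high-quality
#' re-refined crystal structures at a 1.60 A resolution cutoff:
#' 17 hydrogen-bond length targets and 28 simple-parameter targets
#' (7 pair classes x 4 parameters), keyed by nucleic-acid category
#' (DNA-DNA, RNA-RNA, DNA-RNA), pair type (A-T, A-U, G-C) and bond or
#' parameter name. Values are served at their 3-decimal transcription
#' precision. Pairs containing modified nucleotides resolve to the
#' natural pair's targets. Re-mined tables produced by
#' \code{\link{aggregate_targets}} can be swapped in via the
#' \code{targets} argument accepted by the validation and restraint
#' functions.
#'
#' @param path Optional path to a replacement TSV (columns category,
#'   pair_type, key, mean, sd, count).
#' @return data.frame with those columns.
#' @export
load_hbond_targets <- function(path = NULL) {
  load_target_table(path %||% system.file(
    "extdata", "wc_hbond_targets.tsv", package = "nucval"))
}

#' @rdname load_hbond_targets
#' @export
load_simple_targets <- function(path = NULL) {
  load_target_table(path %||% system.file(
    "extdata", "wc_simple_targets.tsv", package = "nucval"))
}

load_target_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("category", "pair_type", "key", "mean", "sd", "count")
  if (!all(need %in% names(tab))) {
    stop("target table ", path, " lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (any(tab$sd <= 0) || any(tab$count <= 0)) {
    stop("target table ", path, " has non-positive sd or count")
  }
  tab
}

#' Look up a hydrogen-bond or simple-parameter target
#'
#' Exact lookups only: an unknown (category, pair type, key)
#' combination is an error, never a silent fallback across categories
#' (classes whose data could not be pooled stay separate; e.g. there is
#' no DNA-DNA A-U row).
#'
#' @param category "DNA-DNA", "RNA-RNA" or "DNA-RNA".
#' @param pair_type "A-T", "A-U" or "G-C".
#' @param atom_pair Bond key such as "N1-N3" (purine atom first).
#' @param targets Optional replacement table.
#' @return list(mean, sd, count).
#' @export
lookup_hbond_target <- function(category, pair_type, atom_pair,
                                targets = NULL) {
  lookup_target(targets %||% load_hbond_targets(),
                category, pair_type, atom_pair)
}

#' @rdname lookup_hbond_target
#' @param parameter One of "shear", "stretch", "buckle", "propeller".
#' @export
lookup_simple_target <- function(category, pair_type, parameter,
                                 targets = NULL) {
  lookup_target(targets %||% load_simple_targets(),
                category, pair_type, parameter)
}

lookup_target <- function(tab, category, pair_type, key) {
  i <- which(tab$category == category & tab$pair_type == pair_type &
               tab$key == key)
  if (length(i) != 1) {
    stop("no target for (", category, ", ", pair_type, ", ", key, ")")
  }
  list(mean = tab$mean[i], sd = tab$sd[i], count = tab$count[i])
}

#' Summary of the embedded target tables
#'
#' @return list(hbond_entries, simple_entries, pair_classes).
#' @export
target_table_digest <- function() {
  hb <- load_hbond_targets()
  sp <- load_simple_targets()
  classes <- unique(paste(sp$category, sp$pair_type))
  list(hbond_entries = nrow(hb),
       simple_entries = nrow(sp),
       pair_classes = length(classes))
}
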