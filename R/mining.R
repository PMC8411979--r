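#' Mining configuration
#'
#' Defaults follow the curated-collection recipe: both partners at
#' RSCC >= 0.95, resolution <= 1.60 A, Welch pooling tests at the 99%
#' confidence level, resolution sweep from 2.00 to 1.50 A in 0.05 A
#' steps.
#'
#' @param rscc_min Minimum per-residue RSCC (both partners).
#' @param resolution_max Resolution cutoff, Angstrom.
#' @param alpha Significance level of the pooling t-tests.
#' @param sweep Descending resolution cutoffs for the sweep.
#' @export
mining_config <- function(rscc_min = 0.95, resolution_max = 1.60,
                          alpha = 0.01,
                          sweep = seq(2.00, 1.50, by = -0.05)) {
  stopifnot(alpha > 0, alpha < 1, all(diff(sweep) < 0))
  list(rscc_min = rscc_min, resolution_max = resolution_max,
       alpha = alpha, sweep = sweep)
}

#' Extract observation records from a structure collection
#'
#' Runs pair detection and classification on every entry and emits one
#' record per Watson-Crick pair with complete standard bonds and
#' computable simple parameters (incomplete pairs are rejected during
#' classification and never reach the records). Signs are already
#' canonical (purine-first) at this point. Per-entry failures are
#' collected, not fatal.
#'
#' @param structures List of \code{nucval_structure} (each should carry
#'   a resolution; RSCC annotations via \code{$rscc} or \code{rsccs}).
#' @param rsccs Optional list of RSCC maps keyed like
#'   \code{structures}.
#' @return data.frame of observation records.
#' @export
extract_observations <- function(structures, rsccs = NULL) {
  rows <- list()
  for (nm in names(structures) %||% seq_along(structures)) {
    st <- structures[[nm]]
    rscc <- st$rscc %||% rsccs[[nm]]
    det <- tryCatch(find_wc_pairs(st), error = function(e) NULL)
    if (is.null(det)) next
    for (p in det$pairs) {
      rows[[length(rows) + 1]] <- data.frame(
        entry_id = st$entry_id, res_i = p$res_i, res_j = p$res_j,
        category = p$category, pair_type = p$pair_type,
        contains_modified = p$contains_modified,
        shear = p$params$shear, stretch = p$params$stretch,
        buckle = p$params$buckle, propeller = p$params$propeller,
        bond_key = paste(paste0(p$hbonds$atom_i, "-", p$hbonds$atom_j),
                         collapse = ";"),
        bond_dist = paste(sprintf("%.6f", p$hbonds$distance),
                          collapse = ";"),
        resolution = st$resolution %||% NA_real_,
        rscc_i = unname(rscc[p$res_i] %||% NA_real_)[1],
        rscc_j = unname(rscc[p$res_j] %||% NA_real_)[1],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty_records()
}

#' Filter observation records for target mining
#'
#' Keeps a record iff both partners have RSCC >= rscc_min and the
#' entry resolution is <= resolution_max (both boundaries inclusive).
#' Records without RSCC annotation are dropped: the mining set is
#' meant to contain exclusively high-quality, density-confirmed pairs.
#' Idempotent.
#'
#' @param records Observation records.
#' @param config A \code{\link{mining_config}}.
#' @export
filter_observations <- function(records, config = mining_config()) {
  keep <- !is.na(records$rscc_i) & !is.na(records$rscc_j) &
    records$rscc_i >= config$rscc_min &
    records$rscc_j >= config$rscc_min &
    !is.na(records$resolution) &
    records$resolution <= config$resolution_max
  records[keep, , drop = FALSE]
}

#' Aggregate filtered records into draft target tables
#'
#' Per (category, pair type, bond or parameter): count, sample mean
#' and sample standard deviation (n-1 denominator). Shear/buckle signs
#' are canonical before aggregation (records are purine-first).
#' Single-observation cells keep their count but have no sd; empty
#' cells yield no row.
#'
#' @param records Filtered observation records.
#' @return list(hbond, simple): draft tables in the target-table
#'   format (category, pair_type, key, mean, sd, count).
#' @export
aggregate_targets <- function(records) {
  agg <- function(df) {
    if (length(df$value) == 0) return(NULL)
    data.frame(category = df$category[1], pair_type = df$pair_type[1],
               key = df$key[1], mean = mean(df$value),
               sd = if (length(df$value) >= 2) stats::sd(df$value)
                    else NA_real_,
               count = length(df$value), stringsAsFactors = FALSE)
  }
  ## Long form for bonds.
  bl <- list()
  for (i in seq_len(nrow(records))) {
    keys <- strsplit(records$bond_key[i], ";")[[1]]
    dists <- as.numeric(strsplit(records$bond_dist[i], ";")[[1]])
    bl[[i]] <- data.frame(category = records$category[i],
                          pair_type = records$pair_type[i],
                          key = keys, value = dists,
                          stringsAsFactors = FALSE)
  }
  bonds <- if (length(bl)) do.call(rbind, bl) else
    data.frame(category = character(0), pair_type = character(0),
               key = character(0), value = numeric(0))
  params <- do.call(rbind, lapply(
    c("shear", "stretch", "buckle", "propeller"), function(k) {
      data.frame(category = records$category,
                 pair_type = records$pair_type, key = k,
                 value = records[[k]], stringsAsFactors = FALSE)
    }))
  collapse <- function(long) {
    if (is.null(long) || nrow(long) == 0) {
      return(data.frame(category = character(0), pair_type = character(0),
                        key = character(0), mean = numeric(0),
                        sd = numeric(0), count = integer(0),
                        stringsAsFactors = FALSE))
    }
    parts <- split(long, paste(long$category, long$pair_type, long$key))
    out <- do.call(rbind, lapply(parts, agg))
    rownames(out) <- NULL
    out[order(out$category, out$pair_type, out$key), , drop = FALSE]
  }
  list(hbond = collapse(bonds), simple = collapse(params))
}

#' Two-sided Welch test for pooling decisions
#'
#' Used both for comparing modified pairs with their natural
#' counterpart and for cross-category pooling. Samples are distinct
#' (not poolable) iff p < alpha; either sample smaller than 2 leaves
#' the decision undetermined.
#'
#' @param sample_a,sample_b Numeric samples.
#' @param alpha Significance level.
#' @return list(p, distinct, poolable); all NA when undetermined.
#' @export
pool_test <- function(sample_a, sample_b, alpha = 0.01) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    return(list(p = NA_real_, distinct = NA, poolable = NA))
  }
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    p <- if (mean(sample_a) == mean(sample_b)) 1 else 0
  } else {
    p <- stats::t.test(sample_a, sample_b, var.equal = FALSE)$p.value
  }
  list(p = p, distinct = p < alpha, poolable = p >= alpha)
}

#' Resolution sweep of observation counts
#'
#' Re-applies the filter at each cutoff of the sweep and tabulates the
#' per-class observation counts, supporting the choice of a resolution
#' cutoff that balances data quantity against coordinate precision.
#' Counts are monotone non-increasing as the cutoff tightens. The
#' trade-off judgement (e.g. accepting a cutoff one step before a
#' large data loss) remains with the analyst.
#'
#' @param records Observation records.
#' @param config A \code{\link{mining_config}}.
#' @return data.frame(cutoff, category, pair_type, count).
#' @export
resolution_sweep <- function(records, config = mining_config()) {
  rows <- list()
  for (cut in config$sweep) {
    cfg <- config
    cfg$resolution_max <- cut
    f <- filter_observations(records, cfg)
    classes <- unique(records[, c("category", "pair_type")])
    if (nrow(classes) == 0) next
    for (i in seq_len(nrow(classes))) {
      n <- sum(f$category == classes$category[i] &
                 f$pair_type == classes$pair_type[i])
      rows[[length(rows) + 1]] <- data.frame(
        cutoff = cut, category = classes$category[i],
        pair_type = classes$pair_type[i], count = n,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(cutoff = numeric(0), category = character(0),
               pair_type = character(0), count = integer(0),
               stringsAsFactors = FALSE)
}

#' Write a target table TSV
#'
#' @param table data.frame in the target-table format.
#' @param path Output path.
#' @param provenance Comment lines recorded at the file head.
#' @export
write_target_table <- function(table, path, provenance = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", c("nucval target table, version 1",
                            provenance)), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read observation records from TSV
#'
#' @param path A TSV written by \code{\link{write_observations}}.
#' @export
read_observations <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname read_observations
#' @param records Observation records.
#' @export
write_observations <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# nucval observation records, version 1", con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
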