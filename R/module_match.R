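#' Cross-condition module overlap with Fisher exact significance
#'
#' For every pair of modules (one from each partition, grey excluded) the
#' 2x2 table over the shared probe universe is tested with a one-sided
#' (enrichment) Fisher exact test, equivalently the hypergeometric upper
#' tail P(X >= overlap). Grey probes stay in the universe but form no
#' module.
#'
#' @param part_a,part_b Partition tibbles (`probe`, `module`) over the same
#'   probe universe (e.g. from two conditions' networks).
#' @param universe Optional probe universe (default: probes of `part_a`).
#' @return Tibble of class `module_overlap` with columns `module_a`,
#'   `module_b`, `size_a`, `size_b`, `overlap`, `p`, `neg_log10_p`.
#' @export
overlap_matrix <- function(part_a, part_b, universe = part_a$probe) {
  if (!setequal(part_a$probe, universe) || !setequal(part_b$probe, universe)) {
    stop("both partitions must cover the same probe universe", call. = FALSE)
  }
  n_u <- length(universe)
  mods_a <- setdiff(sort(unique(part_a$module)), "grey")
  mods_b <- setdiff(sort(unique(part_b$module)), "grey")
  sets_a <- lapply(mods_a, function(mm) part_a$probe[part_a$module == mm])
  sets_b <- lapply(mods_b, function(mm) part_b$probe[part_b$module == mm])
  names(sets_a) <- mods_a; names(sets_b) <- mods_b
  res <- tidyr::expand_grid(module_a = mods_a, module_b = mods_b)
  res$size_a <- unname(lengths(sets_a)[res$module_a])
  res$size_b <- unname(lengths(sets_b)[res$module_b])
  res$overlap <- unname(mapply(
    function(a, b) length(intersect(sets_a[[a]], sets_b[[b]])),
    res$module_a, res$module_b))
  ## one-sided Fisher exact (enrichment) == hypergeometric upper tail
  res$p <- stats::phyper(res$overlap - 1, res$size_a, n_u - res$size_a,
                         res$size_b, lower.tail = FALSE)
  res$neg_log10_p <- -log10(pmax(res$p, .Machine$double.xmin))
  class(res) <- c("module_overlap", class(res))
  res
}

#' Harmonize module labels across two partitions
#'
#' Greedy matching on the overlap table: repeatedly take the unmatched
#' (A, B) module pair with the smallest Fisher p-value (ties broken by
#' larger overlap count, then lexicographic labels) while p <= `max_p`, and
#' give the B module the A module's label/color. Unmatched B modules keep
#' distinct fresh labels. Grey is never matched.
#'
#' @param overlap A `module_overlap` table from [overlap_matrix()].
#' @param max_p Largest Fisher p-value still considered a match.
#' @return Tibble with columns `module_b`, `harmonized` (the A label the B
#'   module inherits, or a fresh `B_<label>` name) and `matched`.
#' @export
harmonize_labels <- function(overlap, max_p = 0.05) {
  ord <- overlap[order(overlap$p, -overlap$overlap,
                       overlap$module_a, overlap$module_b), ]
  mapping <- tibble::tibble(module_b = sort(unique(overlap$module_b)),
                            harmonized = NA_character_, matched = FALSE)
  used_a <- character(0)
  for (i in seq_len(nrow(ord))) {
    if (ord$p[i] > max_p) break
    a <- ord$module_a[i]; b <- ord$module_b[i]
    j <- match(b, mapping$module_b)
    if (a %in% used_a || mapping$matched[j]) next
    mapping$harmonized[j] <- a
    mapping$matched[j] <- TRUE
    used_a <- c(used_a, a)
  }
  fresh <- is.na(mapping$harmonized)
  mapping$harmonized[fresh] <- paste0("B_", mapping$module_b[fresh])
  mapping
}

#' Apply a harmonized label mapping to a partition
#'
#' @param partition Partition tibble (`probe`, `module`).
#' @param mapping Output of [harmonize_labels()].
#' @return Partition tibble with harmonized module labels and refreshed
#'   colors (grey unchanged).
#' @export
apply_harmonization <- function(partition, mapping) {
  idx <- match(partition$module, mapping$module_b)
  hit <- !is.na(idx)
  partition$module[hit] <- mapping$harmonized[idx[hit]]
  assign_module_colors(partition)
}
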