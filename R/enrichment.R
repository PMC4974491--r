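#' Propagate leaf annotations up an ontology
#'
#' A gene annotated to a term is annotated to every ancestor of that term
#' over `is_a` and `part_of` edges (set semantics: a gene reaches each
#' ancestor once regardless of path multiplicity). Each term then becomes a
#' gene set.
#'
#' @param onto Ontology list with `terms` (tibble `id`, `name`) and `edges`
#'   (tibble `child`, `parent`, `relation`), as from [simulate_ontology()]
#'   or [read_obo()].
#' @param annot Annotation tibble with columns `gene` and `term`.
#' @return SignatureDB tibble with columns `set`, `gene`, `source`
#'   (`"ontology"`). Annotations to unknown terms are dropped with a
#'   warning.
#' @export
propagate_annotations <- function(onto, annot) {
  known <- annot$term %in% onto$terms$id
  if (any(!known)) {
    warning(sum(!known), " annotation(s) to unknown terms dropped")
    annot <- annot[known, ]
  }
  parents <- split(onto$edges$parent, onto$edges$child)
  ancestors_of <- function(term) {
    out <- character(0); frontier <- term
    while (length(frontier)) {
      out <- union(out, frontier)
      frontier <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)), out)
    }
    out
  }
  anc_cache <- lapply(stats::setNames(unique(annot$term), unique(annot$term)),
                      ancestors_of)
  expanded <- annot |>
    dplyr::mutate(terms = anc_cache[.data$term]) |>
    tidyr::unnest_longer("terms") |>
    dplyr::distinct(.data$gene, set = .data$terms)
  tibble::tibble(set = expanded$set, gene = expanded$gene, source = "ontology")
}

#' Hypergeometric enrichment of a gene list in a signature
#'
#' With population size \eqn{N}, signature size \eqn{K} (restricted to the
#' population), list size \eqn{n} and overlap \eqn{k}:
#' \eqn{p_{enrich} = P(X \ge k)}, \eqn{p_{deplete} = P(X \le k)} for
#' \eqn{X \sim Hypergeom(N, K, n)}, and the signed z-score is
#' \eqn{z = \Phi^{-1}(1 - p_{enrich})} when \eqn{k \ge nK/N}, else
#' \eqn{-\Phi^{-1}(1 - p_{deplete})}. Exact tails (no normal approximation);
#' the sign encodes enrichment vs depletion.
#'
#' @param list_genes Gene list (the draw); must lie within `population`.
#' @param sig_genes Signature gene set (the successes).
#' @param population The platform gene universe.
#' @return Tibble with `k`, `expected`, `p_enrich`, `p_deplete`, `z`.
#' @export
hypergeom_enrich <- function(list_genes, sig_genes, population) {
  list_genes <- unique(list_genes)
  if (!all(list_genes %in% population)) {
    stop("gene list contains genes outside the population", call. = FALSE)
  }
  n_pop <- length(unique(population))
  kk <- length(intersect(sig_genes, population))
  nn <- length(list_genes)
  k <- length(intersect(list_genes, sig_genes))
  p_enrich <- stats::phyper(k - 1, kk, n_pop - kk, nn, lower.tail = FALSE)
  p_deplete <- stats::phyper(k, kk, n_pop - kk, nn, lower.tail = TRUE)
  expected <- nn * kk / n_pop
  ## clamp underflowed tails so z stays finite
  z <- if (k >= expected) {
    stats::qnorm(max(p_enrich, .Machine$double.xmin), lower.tail = FALSE)
  } else {
    -stats::qnorm(max(p_deplete, .Machine$double.xmin), lower.tail = FALSE)
  }
  tibble::tibble(k = k, expected = expected, p_enrich = p_enrich,
                 p_deplete = p_deplete, z = z)
}

#' Split module probes into up/down trend lists
#'
#' Per probe, the donor-averaged log2 profile over one condition's time
#' points is reduced to a net trend by summing the consecutive-time-point
#' differences (which telescopes to last minus first). Probes whose
#' time-course SD (of the donor-averaged profile) is at or below `sd_min`
#' are dropped; positive trends go to the module's up-list, negative to its
#' down-list, exact zeros are dropped; lists with fewer than `min_genes`
#' members are discarded.
#'
#' @param partition Partition tibble (`probe`, `module`).
#' @param x Log2 expression matrix containing the condition's samples.
#' @param condition Condition whose time course is analysed.
#' @param samples Sample annotations (default: parsed from `colnames(x)`).
#' @param sd_min Time-course SD threshold (log2 units).
#' @param min_genes Minimum surviving list size.
#' @param include_grey Also build lists for the grey class.
#' @return Tibble with columns `module`, `direction` (`"up"`/`"down"`),
#'   `list` (`"<module>_<direction>"`), `probe`, `trend`, `sd`.
#' @export
trend_split <- function(partition, x, condition,
                        samples = parse_sample_ids(x),
                        sd_min = 0.2, min_genes = 5, include_grey = FALSE) {
  sel <- samples[samples$condition == condition, ]
  if (length(unique(sel$timepoint)) < 2) {
    stop("need >= 2 time points for a trend", call. = FALSE)
  }
  tps <- sort(unique(sel$timepoint))
  prof <- vapply(tps, function(tp) {
    rowMeans(x[partition$probe, sel$sample[sel$timepoint == tp], drop = FALSE])
  }, numeric(nrow(partition)))
  trend <- rowSums(prof[, -1, drop = FALSE] - prof[, -ncol(prof), drop = FALSE])
  sds <- apply(prof, 1, stats::sd)
  out <- tibble::tibble(module = partition$module, probe = partition$probe,
                        trend = unname(trend), sd = unname(sds))
  if (!include_grey) out <- out[out$module != "grey", ]
  out <- out[out$sd > sd_min & out$trend != 0, ]
  out$direction <- ifelse(out$trend > 0, "up", "down")
  out$list <- paste0(out$module, "_", out$direction)
  out <- out |>
    dplyr::group_by(.data$list) |>
    dplyr::filter(dplyr::n() >= min_genes) |>
    dplyr::ungroup()
  out[, c("module", "direction", "list", "probe", "trend", "sd")]
}

#' Signature x trend-list enrichment z-score matrix
#'
#' For every (signature, trend list) pair the exact hypergeometric z-score
#' is computed against the platform population; entries whose two-sided
#' evidence is weak (`min(p_enrich, p_deplete) > p_cutoff`) are set to 0.
#' Trend lists with no surviving enrichment are removed, as are signatures
#' enriched nowhere; rows and columns are ordered by hierarchical clustering
#' of the z-matrix (1 - Pearson correlation, complete linkage).
#'
#' @param lists Trend-list tibble from [trend_split()] (possibly several
#'   conditions bound together; `list` names must be unique across input).
#' @param db SignatureDB tibble (`set`, `gene`).
#' @param population Platform gene universe.
#' @param p_cutoff Significance threshold below which a z-score is kept.
#' @return Numeric matrix (signatures x lists) of class `enrichment_matrix`
#'   with attribute `dropped` listing removed all-zero rows/columns.
#' @export
enrichment_matrix <- function(lists, db, population, p_cutoff = 0.05) {
  if (!nrow(lists)) stop("no trend lists supplied", call. = FALSE)
  list_sets <- split(lists$probe, lists$list)
  sig_sets <- split(db$gene, db$set)
  zmat <- matrix(0, length(sig_sets), length(list_sets),
                 dimnames = list(names(sig_sets), names(list_sets)))
  for (j in seq_along(list_sets)) {
    for (i in seq_along(sig_sets)) {
      e <- hypergeom_enrich(list_sets[[j]], sig_sets[[i]], population)
      if (min(e$p_enrich, e$p_deplete) <= p_cutoff) zmat[i, j] <- e$z
    }
  }
  dropped <- list(signatures = rownames(zmat)[rowSums(zmat != 0) == 0],
                  lists = colnames(zmat)[colSums(zmat != 0) == 0])
  zmat <- zmat[rowSums(zmat != 0) > 0, colSums(zmat != 0) > 0, drop = FALSE]
  cor_order <- function(m) {
    cc <- suppressWarnings(stats::cor(m))
    cc[!is.finite(cc)] <- 0
    stats::hclust(stats::as.dist(1 - cc), method = "complete")$order
  }
  if (nrow(zmat) > 2 && ncol(zmat) > 1) {
    zmat <- zmat[cor_order(t(zmat)), , drop = FALSE]
  }
  if (ncol(zmat) > 2 && nrow(zmat) > 1) {
    zmat <- zmat[, cor_order(zmat), drop = FALSE]
  }
  attr(zmat, "dropped") <- dropped
  class(zmat) <- c("enrichment_matrix", class(zmat))
  zmat
}
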