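#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Build the weighted coexpression network for one condition
#'
#' Runs the full per-condition chain: soft-thresholded adjacency over the
#' condition's samples, topological overlap, average-linkage dendrogram,
#' dynamic tree cut, eigengene-based module merging, and intramodular
#' connectivity. One network is built per condition over the same probe
#' universe so that partitions, connectivities and TOM neighborhoods remain
#' comparable across conditions.
#'
#' @param x Log2 expression matrix (the shared probe universe, e.g. the top
#'   2000 most variant probes).
#' @param condition Condition whose samples enter the correlation.
#' @param samples Sample annotations (default: parsed from `colnames(x)`).
#' @param power Soft-threshold exponent.
#' @param min_size,cut_height,deep_split,split_gap,tightness Dynamic-cut
#'   parameters, see [dynamic_tree_cut()].
#' @param merge_cut Eigengene-dissimilarity merge threshold.
#' @param keep_adjacency Keep the adjacency matrix in the result (needed for
#'   connectivity recomputation; disable to save memory).
#' @return Object of class `coexpr_network`: list with `condition`,
#'   `partition` (tibble `probe`, `module`, `color`, `k_within`), `tom`,
#'   `adjacency` (optional), `dendrogram`, `eigengenes`, `samples`, and
#'   `params`.
#' @export
condition_network <- function(x, condition, samples = parse_sample_ids(x),
                              power = 8, min_size = 8, cut_height = 0.995,
                              deep_split = TRUE, split_gap = 0.10,
                              tightness = 0.85, merge_cut = 0.2,
                              keep_adjacency = TRUE) {
  sel <- samples$sample[samples$condition == condition]
  if (!length(sel)) stop("no samples for condition ", condition, call. = FALSE)
  xc <- x[, sel, drop = FALSE]
  a <- adjacency_matrix(xc, power = power)
  tom <- tom_similarity(a)
  diss <- 1 - tom
  diag(diss) <- 0
  tree <- cluster_dendrogram(diss)
  part <- dynamic_tree_cut(tree, diss, min_size = min_size,
                           cut_height = cut_height, deep_split = deep_split,
                           split_gap = split_gap, tightness = tightness)
  part <- merge_modules(xc, part, merge_cut = merge_cut)
  conn <- intramodular_connectivity(a, part)
  part$k_within <- conn$k_within[match(part$probe, conn$probe)]
  me <- if (length(setdiff(unique(part$module), "grey"))) {
    module_eigengenes(xc, part)
  } else NULL
  structure(
    list(condition = condition, partition = part, tom = tom,
         adjacency = if (keep_adjacency) a,
         dendrogram = tree, eigengenes = me,
         samples = samples[samples$sample %in% sel, ],
         params = list(power = power, min_size = min_size,
                       cut_height = cut_height, deep_split = deep_split,
                       split_gap = split_gap, tightness = tightness,
                       merge_cut = merge_cut)),
    class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  nm <- setdiff(unique(x$partition$module), "grey")
  cat("Weighted coexpression network (", x$condition, "): ",
      nrow(x$partition), " probes, ", length(nm), " modules, ",
      sum(x$partition$module == "grey"), " grey\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Tidy a coexpression network into its probe-level partition
#'
#' @param x A `coexpr_network`.
#' @param ... Unused.
#' @return Tibble `probe`, `module`, `color`, `k_within`.
#' @export
tidy.coexpr_network <- function(x, ...) x$partition

#' One-row summary of a coexpression network
#'
#' @param x A `coexpr_network`.
#' @param ... Unused.
#' @return Tibble with `condition`, `n_probes`, `n_modules`, `n_grey`,
#'   `largest_module`, `median_k_within`.
#' @export
glance.coexpr_network <- function(x, ...) {
  mods <- x$partition$module[x$partition$module != "grey"]
  tibble::tibble(
    condition = x$condition,
    n_probes = nrow(x$partition),
    n_modules = length(unique(mods)),
    n_grey = sum(x$partition$module == "grey"),
    largest_module = if (length(mods)) max(table(mods)) else 0L,
    median_k_within = stats::median(x$partition$k_within[x$partition$module != "grey"]))
}

#' Compare two condition networks by module overlap
#'
#' Convenience wrapper: computes the Fisher overlap table between the two
#' partitions and the harmonized label mapping for network B.
#'
#' @param net_a,net_b `coexpr_network` objects over the same probe universe.
#' @param max_p Match threshold passed to [harmonize_labels()].
#' @return List with `overlap` (tibble) and `mapping` (tibble).
#' @export
compare_networks <- function(net_a, net_b, max_p = 0.05) {
  ov <- overlap_matrix(net_a$partition, net_b$partition)
  list(overlap = ov, mapping = harmonize_labels(ov, max_p = max_p))
}
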