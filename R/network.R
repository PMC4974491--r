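#' Soft-thresholded adjacency matrix
#'
#' Unsigned weighted adjacency \eqn{a_{ij} = |r_{ij}|^\beta} where `r` is the
#' Pearson correlation of probe profiles across the supplied samples
#' (pairwise-complete). Probes with zero variance get correlation 0 with all
#' others. The diagonal is set to 0 so that row sums are connectivities.
#'
#' @param x Log2 expression matrix (probes x samples), typically restricted
#'   to one condition's samples.
#' @param power Soft-threshold exponent beta.
#' @return Symmetric probes x probes matrix with entries in `[0, 1]`.
#' @export
adjacency_matrix <- function(x, power = 8) {
  if (ncol(x) < 3) stop("need >= 3 samples to correlate", call. = FALSE)
  r <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  a <- abs(r)^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = (l_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})}
#' with \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}; the diagonal is 1. The topological
#' overlap dissimilarity used for clustering is `1 - TOM`.
#'
#' @param a Adjacency matrix from [adjacency_matrix()].
#' @return Symmetric TOM matrix with entries in `[0, 1]`.
#' @export
tom_similarity <- function(a) {
  if (nrow(a) != ncol(a)) stop("adjacency must be square", call. = FALSE)
  if (max(abs(a - t(a))) > 1e-10) {
    stop("adjacency asymmetric beyond 1e-10", call. = FALSE)
  }
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a            # with zero diagonal this is exactly sum_{u != i,j}
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

#' Average-linkage dendrogram over a dissimilarity matrix
#'
#' @param diss Symmetric dissimilarity matrix with zero diagonal (typically
#'   `1 - tom_similarity(a)`).
#' @return An [stats::hclust] tree.
#' @export
cluster_dendrogram <- function(diss) {
  if (any(!is.finite(diss))) stop("dissimilarity contains non-finite values", call. = FALSE)
  if (max(abs(diss - t(diss))) > 1e-10 || any(abs(diag(diss)) > 1e-12)) {
    stop("dissimilarity must be symmetric with zero diagonal", call. = FALSE)
  }
  stats::hclust(stats::as.dist(diss), method = "average")
}

#' Dynamic dendrogram cut into coexpression modules
#'
#' Decomposes an average-linkage dendrogram into modules under a height
#' ceiling. Merges above `cut_height` are ignored, so branches below the
#' ceiling form the candidate clusters. With `deep_split`, branches are
#' adaptively split by a bottom-up gap rule: walking the merge sequence from
#' the bottom, two groups that each already hold `min_size` leaves and whose
#' join height exceeds both groups' core heights (median of their
#' internal merge heights) by at least `split_gap` are locked as separate
#' clusters. Candidate clusters are then validated for tightness: members
#' whose mean dissimilarity to the cluster exceeds `tightness` times their
#' mean dissimilarity to everything else are ejected, clusters that end up
#' looser than `tightness` times their mean outside dissimilarity are
#' dissolved, and clusters below `min_size` are dissolved. Dissolved or
#' unassigned probes receive the label `"grey"`.
#'
#' @param tree [stats::hclust] tree from [cluster_dendrogram()].
#' @param diss The dissimilarity matrix the tree was built from.
#' @param min_size Minimum module size.
#' @param cut_height Static height ceiling.
#' @param deep_split Enable adaptive within-branch splitting.
#' @param split_gap Minimum height gap (dissimilarity units) separating two
#'   lockable groups.
#' @param tightness Validation ratio: a cluster (and each member) must be at
#'   least this much tighter inside than towards the rest of the network.
#' @return Tibble with columns `probe`, `module` (labels `"M1"`, `"M2"`, ...
#'   by decreasing size, `"grey"` for unassigned) and `color`.
#' @export
dynamic_tree_cut <- function(tree, diss, min_size = 8, cut_height = 0.995,
                             deep_split = TRUE, split_gap = 0.10,
                             tightness = 0.85) {
  n <- nrow(diss)
  stopifnot(length(tree$height) == n - 1, min_size >= 2)
  m <- tree$merge
  hts <- tree$height

  leaves_l <- vector("list", 2 * n)   # group id -> leaves
  hist_l <- vector("list", 2 * n)     # group id -> internal merge heights
  locked <- logical(2 * n)
  composite <- logical(2 * n)
  ngroups <- 0L
  new_group <- function(leaves, heights, comp = FALSE) {
    ngroups <<- ngroups + 1L
    leaves_l[[ngroups]] <<- leaves
    hist_l[[ngroups]] <<- heights
    composite[ngroups] <<- comp
    ngroups
  }
  core_h <- function(g) {
    h <- hist_l[[g]]
    if (length(h)) stats::median(h) else 0
  }
  gid_of_node <- integer(n - 1)

  for (i in seq_len(n - 1)) {
    if (hts[i] > cut_height) next
    side <- lapply(1:2, function(k) {
      ch <- m[i, k]
      if (ch < 0) list(gid = 0L, leaves = -ch, comp = FALSE)
      else {
        g <- gid_of_node[ch]
        list(gid = g, leaves = leaves_l[[g]], comp = composite[g])
      }
    })
    if (side[[1]]$comp || side[[2]]$comp) {
      ## one side already resolved into locked clusters: a joining group can
      ## only become a cluster of its own (if big and separated), otherwise
      ## its leaves stay unassigned
      for (s in side) {
        if (s$comp || s$gid == 0L) next
        g <- s$gid
        if (deep_split && !locked[g] && length(leaves_l[[g]]) >= min_size &&
            (hts[i] - core_h(g)) >= split_gap) {
          locked[g] <- TRUE
        } else if (!locked[g]) {
          leaves_l[[g]] <- integer(0)   # spent: grey
        }
      }
      gid_of_node[i] <- new_group(integer(0), numeric(0), comp = TRUE)
      next
    }
    sz <- c(length(side[[1]]$leaves), length(side[[2]]$leaves))
    if (deep_split && min(sz) >= min_size) {
      cores <- vapply(side, function(s) if (s$gid > 0L) core_h(s$gid) else 0,
                      numeric(1))
      if (hts[i] - max(cores) >= split_gap) {
        for (s in side) if (s$gid > 0L) locked[s$gid] <- TRUE
        gid_of_node[i] <- new_group(integer(0), numeric(0), comp = TRUE)
        next
      }
    }
    if (deep_split && min(sz) < min_size && max(sz) >= min_size) {
      ## a sub-minimum group far above a big group's core is shaved to grey
      ## rather than absorbed
      big <- side[[which.max(sz)]]
      small <- side[[which.min(sz)]]
      if (hts[i] - core_h(big$gid) >= split_gap) {
        if (small$gid > 0L) leaves_l[[small$gid]] <- integer(0)
        gid_of_node[i] <- big$gid
        next
      }
    }
    heights <- c(if (side[[1]]$gid > 0L) hist_l[[side[[1]]$gid]],
                 if (side[[2]]$gid > 0L) hist_l[[side[[2]]$gid]],
                 hts[i])
    gid_of_node[i] <- new_group(c(side[[1]]$leaves, side[[2]]$leaves), heights)
    for (s in side) if (s$gid > 0L && !locked[s$gid]) leaves_l[[s$gid]] <- integer(0)
  }

  ## candidate clusters: locked groups plus surviving unresolved groups
  cand <- which(seq_len(2 * n) <= ngroups & (locked |
    (!composite[seq_len(2 * n)] & vapply(leaves_l, length, 0L) > 0)))
  labels <- rep("grey", n)
  dsum <- rowSums(diss)
  clusters <- list()
  for (g in cand) {
    cc <- leaves_l[[g]]
    if (length(cc) < min_size) next
    if (length(cc) == n) {
      ## no outside to compare with: a cluster spanning the whole universe
      ## must still be clearly tighter than the height ceiling
      w_in <- sum(diss[cc, cc]) / (length(cc) * (length(cc) - 1))
      if (w_in <= tightness * cut_height) clusters[[length(clusters) + 1]] <- cc
      next
    }
    ## outlier ejection: members far looser than the cluster's own scale
    sub <- diss[cc, cc, drop = FALSE]
    din <- rowSums(sub) / (length(cc) - 1)
    cc <- cc[din <= stats::median(din) + pmax(3 * stats::mad(din), 0.05)]
    if (length(cc) < min_size) next
    ## relative tightness ejection: tighter inside than towards the rest
    sub <- diss[cc, cc, drop = FALSE]
    din <- rowSums(sub) / (length(cc) - 1)
    dout <- (dsum[cc] - rowSums(sub)) / (n - length(cc))
    cc <- cc[din <= tightness * dout]
    if (length(cc) < min_size) next
    sub <- diss[cc, cc, drop = FALSE]
    w_in <- sum(sub) / (length(cc) * (length(cc) - 1))
    w_out <- (sum(dsum[cc]) - sum(sub)) / (length(cc) * (n - length(cc)))
    if (w_in > tightness * w_out) next
    clusters[[length(clusters) + 1]] <- cc
  }
  if (length(clusters)) {
    ord <- order(-lengths(clusters))
    for (j in seq_along(ord)) labels[clusters[[ord[j]]]] <- paste0("M", j)
  }
  probes <- tree$labels
  if (is.null(probes)) probes <- as.character(seq_len(n))
  assign_module_colors(tibble::tibble(probe = probes, module = labels))
}

## The classic module color sequence, assigned by decreasing module size.
module_color_sequence <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "seagreen")
}

#' Assign display colors to module labels
#'
#' Colors follow the conventional sequence (turquoise, blue, brown, ...) by
#' decreasing module size; unassigned probes are `"grey"`.
#'
#' @param partition Tibble with columns `probe` and `module`.
#' @return The partition with a (re)computed `color` column.
#' @export
assign_module_colors <- function(partition) {
  sizes <- sort(table(partition$module[partition$module != "grey"]),
                decreasing = TRUE)
  pal <- module_color_sequence()
  cols <- stats::setNames(
    c(pal, paste0("extra", seq_len(max(0, length(sizes) - length(pal)))))[
      seq_along(sizes)], names(sizes))
  partition$color <- unname(cols[partition$module])
  partition$color[partition$module == "grey"] <- "grey"
  partition
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' row-standardized expression submatrix, sign-oriented to correlate
#' positively with the module's mean expression profile, and scaled to unit
#' length.
#'
#' @param x Log2 expression matrix for the samples under analysis.
#' @param partition Partition tibble (`probe`, `module`).
#' @param include_grey Compute an eigengene for the grey pseudo-module too.
#' @return Samples x modules numeric matrix.
#' @export
module_eigengenes <- function(x, partition, include_grey = FALSE) {
  mods <- setdiff(unique(partition$module), if (include_grey) NULL else "grey")
  mods <- mods[order(mods)]
  if (!length(mods)) stop("no modules to summarise", call. = FALSE)
  me <- vapply(mods, function(mm) {
    idx <- partition$probe[partition$module == mm]
    sub <- x[idx, , drop = FALSE]
    z <- t(scale(t(sub)))
    z[!is.finite(z)] <- 0
    v <- svd(z, nu = 0, nv = 1)$v[, 1]
    mean_prof <- colMeans(sub)
    if (stats::sd(mean_prof) > 0 && stats::cor(v, mean_prof) < 0) v <- -v
    v / sqrt(sum(v^2))
  }, numeric(ncol(x)))
  rownames(me) <- colnames(x)
  me
}

#' Merge modules with similar eigengenes
#'
#' Modules whose eigengene dissimilarity (1 - Pearson correlation) falls
#' below `merge_cut` are merged: eigengenes are clustered by average linkage
#' and the tree cut at `merge_cut`; groups are collapsed onto the label of
#' their largest member and the procedure iterates with recomputed
#' eigengenes until no merge occurs. Grey is never merged.
#'
#' @param x Log2 expression matrix for the samples under analysis.
#' @param partition Partition tibble (`probe`, `module`).
#' @param merge_cut Eigengene dissimilarity threshold.
#' @return The merged partition tibble with refreshed colors.
#' @export
merge_modules <- function(x, partition, merge_cut = 0.2) {
  repeat {
    mods <- setdiff(unique(partition$module), "grey")
    if (length(mods) < 2) break
    me <- module_eigengenes(x, partition)
    dm <- 1 - stats::cor(me)
    grp <- stats::cutree(stats::hclust(stats::as.dist(dm), method = "average"),
                         h = merge_cut)
    if (max(grp) == length(mods)) break
    sizes <- table(partition$module)
    for (g in unique(grp)) {
      members <- colnames(me)[grp == g]
      if (length(members) < 2) next
      target <- members[which.max(sizes[members])]
      partition$module[partition$module %in% members] <- target
    }
  }
  assign_module_colors(partition)
}

#' Intramodular connectivity
#'
#' \eqn{kWithin_i = \sum_{j \ne i,\ label_j = label_i} a_{ij}}: the sum of a
#' probe's adjacency to the other members of its module. Grey probes get the
#' sum over the grey class (reported for completeness; it is not a module).
#'
#' @param a Adjacency matrix.
#' @param partition Partition tibble (`probe`, `module`).
#' @return Tibble with columns `probe`, `module`, `k_within`.
#' @export
intramodular_connectivity <- function(a, partition) {
  stopifnot(all(partition$probe %in% rownames(a)))
  k <- stats::setNames(numeric(nrow(partition)), partition$probe)
  for (mm in unique(partition$module)) {
    idx <- partition$probe[partition$module == mm]
    sub <- a[idx, idx, drop = FALSE]
    diag(sub) <- 0
    k[idx] <- rowSums(sub)
  }
  tibble::tibble(probe = partition$probe, module = partition$module,
                 k_within = unname(k[partition$probe]))
}

#' Strongest edges of a TOM network
#'
#' Returns the `budget` highest-TOM undirected edges, each pair reported
#' once with `from < to`, sorted by decreasing weight. Ties at the cutoff
#' are broken by `(from, to)` lexicographic order.
#'
#' @param tom TOM matrix with probe dimnames.
#' @param budget Maximum number of edges to keep.
#' @return Tibble with columns `from`, `to`, `weight`.
#' @export
top_edges <- function(tom, budget = 50000) {
  ids <- rownames(tom)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(tom)))
  ut <- which(upper.tri(tom), arr.ind = TRUE)
  edges <- tibble::tibble(from = ids[ut[, 1]], to = ids[ut[, 2]],
                          weight = tom[ut])
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges <- edges[order(-edges$weight, edges$from, edges$to), ]
  utils::head(edges, budget)
}

#' Betweenness centrality of an edge list
#'
#' Shortest-path betweenness per node of the undirected graph spanned by the
#' edge list, treated as unweighted (TOM weights are similarities, not
#' distances); unnormalized, with all shortest paths counted with
#' multiplicity.
#'
#' @param edges Tibble with columns `from` and `to` (extra columns ignored).
#' @return Tibble with columns `probe`, `betweenness`.
#' @export
node_betweenness <- function(edges) {
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE)
  b <- igraph::betweenness(g, directed = FALSE, weights = NA, normalized = FALSE)
  tibble::tibble(probe = names(b), betweenness = unname(b)) |>
    dplyr::arrange(dplyr::desc(.data$betweenness), .data$probe)
}
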