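#' Scale intramodular connectivity to 0-1 within each module
#'
#' Per module, connectivity is rescaled as `(k - min) / (max - min)`.
#' Single-probe or constant-connectivity modules map to 0 for all members.
#'
#' @param connectivity Tibble from [intramodular_connectivity()] (`probe`,
#'   `module`, `k_within`).
#' @return The tibble with an added `scaled_k` column (grey probes get `NA`:
#'   grey is a residual class, not a module).
#' @export
scale_connectivity <- function(connectivity) {
  connectivity |>
    dplyr::group_by(.data$module) |>
    dplyr::mutate(scaled_k = {
      rng <- range(.data$k_within)
      if (diff(rng) == 0) rep(0, dplyr::n()) else
        (.data$k_within - rng[1]) / diff(rng)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(scaled_k = ifelse(.data$module == "grey", NA_real_,
                                    .data$scaled_k))
}

#' Classify genes by expression and connectivity change between conditions
#'
#' Combines the scaled intramodular connectivities of two conditions with a
#' moderated T-statistic at a chosen time point. With
#' `delta_k = scaled_b - scaled_a`, the classes (mutually exclusive, in
#' precedence order) are:
#' `expression_and_connectivity` (red: `|T| > t_thresh` and
#' `|delta_k| > k_thresh`), `expression` (blue: `|T| > t_thresh` only),
#' `highly_connected` (green: scaled connectivity >= `high_k` in both
#' conditions), otherwise `none`. Probes grey in either condition have
#' missing `delta_k` and can only reach the `expression` class.
#'
#' @param scaled_a,scaled_b Outputs of [scale_connectivity()] for conditions
#'   A and B over the same probe universe.
#' @param de [moderated_t()] result for the B-vs-A (or A-vs-B) contrast at
#'   the time point of interest.
#' @param k_thresh Connectivity-change threshold.
#' @param t_thresh T-statistic threshold.
#' @param high_k Scaled-connectivity level defining "highly connected".
#' @return Tibble with columns `probe`, `scaled_a`, `scaled_b`, `delta_k`,
#'   `t`, `class`.
#' @export
classify_genes <- function(scaled_a, scaled_b, de,
                           k_thresh = 0.285, t_thresh = 3, high_k = 0.9) {
  if (!setequal(scaled_a$probe, scaled_b$probe) ||
      !all(de$probe %in% scaled_a$probe)) {
    stop("probe universes of the inputs do not align", call. = FALSE)
  }
  probes <- scaled_a$probe
  out <- tibble::tibble(probe = probes,
                        scaled_a = scaled_a$scaled_k,
                        scaled_b = scaled_b$scaled_k[match(probes, scaled_b$probe)],
                        t = de$t[match(probes, de$probe)])
  out$delta_k <- out$scaled_b - out$scaled_a
  big_t <- !is.na(out$t) & abs(out$t) > t_thresh
  big_k <- !is.na(out$delta_k) & abs(out$delta_k) > k_thresh
  high <- !is.na(out$scaled_a) & !is.na(out$scaled_b) &
    out$scaled_a >= high_k & out$scaled_b >= high_k
  out$class <- dplyr::case_when(
    big_t & big_k ~ "expression_and_connectivity",
    big_t ~ "expression",
    high ~ "highly_connected",
    TRUE ~ "none")
  out
}

#' Top-neighbor overlap between two networks ("rewiring")
#'
#' For a probe, ranks all other probes by TOM weight within each condition
#' (ties broken by probe-ID lexicographic order) and reports the percentage
#' of shared members between the two top-`top_n` neighbor sets. 100% means
#' the probe keeps its neighborhood; low values mean it rewires.
#'
#' @param tom_a,tom_b TOM matrices over the same probe universe.
#' @param probe Probe identifier (or index).
#' @param top_n Neighborhood size.
#' @return Percentage in `[0, 100]`.
#' @export
neighbor_overlap <- function(tom_a, tom_b, probe, top_n = 100) {
  ids <- rownames(tom_a)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(tom_a)))
  if (!identical(dim(tom_a), dim(tom_b))) {
    stop("TOM matrices must share the probe universe", call. = FALSE)
  }
  if (top_n >= nrow(tom_a)) {
    stop("top_n must be smaller than the probe universe", call. = FALSE)
  }
  i <- if (is.character(probe)) match(probe, ids) else as.integer(probe)
  if (is.na(i)) stop("probe not found: ", probe, call. = FALSE)
  rank_top <- function(tom) {
    w <- tom[i, -i]
    nm <- ids[-i]
    nm[order(-w, nm)][seq_len(top_n)]
  }
  100 * length(intersect(rank_top(tom_a), rank_top(tom_b))) / top_n
}

#' Neighbor overlap for many probes
#'
#' @inheritParams neighbor_overlap
#' @param probes Probes to evaluate (default: all).
#' @return Tibble with columns `probe`, `overlap_pct`.
#' @export
neighbor_overlap_table <- function(tom_a, tom_b, probes = rownames(tom_a),
                                   top_n = 100) {
  tibble::tibble(
    probe = probes,
    overlap_pct = vapply(probes, function(p)
      neighbor_overlap(tom_a, tom_b, p, top_n), numeric(1)))
}
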