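#' Remove probes undetected on too many arrays
#'
#' A measurement is called undetected when its detection p-value is at or
#' above `alpha_detect`. A probe is retained only if it is undetected on
#' fewer than `max_undetected` arrays (default: probes undetected on three or
#' more arrays are removed).
#'
#' @param x Log2 expression matrix (probes x samples).
#' @param d Detection p-value matrix, same dimensions and dimnames as `x`.
#' @param alpha_detect Detection-call threshold on the detection p-value.
#' @param max_undetected A probe is dropped when its undetected-array count
#'   reaches this value.
#' @return The filtered expression matrix.
#' @export
filter_undetected <- function(x, d, alpha_detect = 0.05, max_undetected = 3) {
  if (!identical(dim(x), dim(d)) ||
      !identical(rownames(x), rownames(d)) ||
      !identical(colnames(x), colnames(d))) {
    stop("expression and detection matrices must share dimensions and dimnames",
         call. = FALSE)
  }
  n_undet <- rowSums(d >= alpha_detect)
  x[n_undet < max_undetected, , drop = FALSE]
}

#' Quantile normalization
#'
#' Forces every column to share the same empirical distribution (the vector
#' of cross-column rank means); ties within a column receive the mean of
#' their rank-mean values. Thin wrapper over
#' [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param x Log2 expression matrix with at least two columns.
#' @return Matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples", call. = FALSE)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Select the most variant probes
#'
#' Keeps the `n` probes with the largest variance computed across all
#' samples pooled (conditions and time points together), preserving the
#' original probe order. Variance ties at the selection boundary are broken
#' by probe-ID lexicographic order.
#'
#' @param x Log2 expression matrix.
#' @param n Number of probes to retain.
#' @return Matrix restricted to the selected probes.
#' @export
select_most_variant <- function(x, n = 2000) {
  if (n > nrow(x)) {
    stop("n (", n, ") exceeds the number of probes (", nrow(x), ")", call. = FALSE)
  }
  v <- apply(x, 1, stats::var)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("row%06d", seq_len(nrow(x)))
  ord <- order(-v, ids)
  keep <- sort(ord[seq_len(n)])
  x[keep, , drop = FALSE]
}

## Invert the trigamma function by Newton iteration (for the moments
## estimator of the variance-prior degrees of freedom).
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    x <- 0.5 + 1 / yi
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

## Method-of-moments fit of the scaled inverse chi-square variance prior on
## log sample variances: log s^2 ~ log s0^2 + log F(d, d0).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e_z <- mean(z)
  v_z <- stats::var(z)
  v0 <- v_z - trigamma(df / 2)
  if (is.finite(v0) && v0 > 0) {
    d0 <- 2 * trigamma_inverse(v0)
    s0_2 <- exp(e_z - digamma(df / 2) + log(df / 2) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(e_z - digamma(df / 2) + log(df / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated t-test between two conditions at one time point
#'
#' Per-probe two-group comparison of donor replicates with empirical-Bayes
#' variance shrinkage: the pooled sample variance \eqn{s^2} (d degrees of
#' freedom) is shrunk towards a prior \eqn{s_0^2} (d0 degrees of freedom)
#' estimated across probes by method of moments on the log sample variances,
#' giving the posterior variance
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d),}
#' the statistic \eqn{T = \Delta \bar x / (\tilde s \sqrt{1/n_A + 1/n_B})}
#' and p-values from the t-distribution on \eqn{d + d_0} degrees of freedom.
#' `q` is the Benjamini-Hochberg adjustment within this (contrast, time
#' point) family.
#'
#' @param x Log2 expression matrix.
#' @param contrast Length-2 character vector `c(conditionA, conditionB)`;
#'   positive log-fold-changes mean higher in `conditionA`.
#' @param timepoint Time point (hours) at which to compare.
#' @param samples Sample annotation tibble (default: parsed from
#'   `colnames(x)` via [parse_sample_ids()]).
#' @param d0,s0_2 Optional fixed prior degrees of freedom / prior variance,
#'   overriding the moments estimates (`d0 = 0` reproduces the ordinary
#'   two-sample t-test; `d0 = Inf` pools all probes to the prior variance).
#' @return Tibble with columns `probe`, `logFC`, `t`, `p`, `q`, `contrast`,
#'   `timepoint`.
#' @export
moderated_t <- function(x, contrast, timepoint, samples = parse_sample_ids(x),
                        d0 = NULL, s0_2 = NULL) {
  stopifnot(length(contrast) == 2)
  sel_a <- samples$sample[samples$condition == contrast[1] &
                            samples$timepoint == timepoint]
  sel_b <- samples$sample[samples$condition == contrast[2] &
                            samples$timepoint == timepoint]
  if (length(sel_a) < 2 || length(sel_b) < 2) {
    stop("both conditions need >= 2 replicates at t = ", timepoint, " h",
         call. = FALSE)
  }
  xa <- x[, sel_a, drop = FALSE]
  xb <- x[, sel_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  dm <- rowMeans(xa) - rowMeans(xb)
  df <- na + nb - 2
  s2 <- (rowSums((xa - rowMeans(xa))^2) + rowSums((xb - rowMeans(xb))^2)) / df
  if (is.null(d0) || is.null(s0_2)) {
    prior <- fit_variance_prior(s2, df)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s0_2)) s0_2 <- prior$s0_2
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
    df_total <- df + d0
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tt <- dm / se
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  tibble::tibble(
    probe = rownames(x), logFC = unname(dm), t = unname(tt), p = unname(p),
    q = bh_adjust(unname(p)),
    contrast = paste0(contrast[1], "_vs_", contrast[2]),
    timepoint = timepoint)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (clipped at 1, monotone in rank); wraps
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Count differentially expressed probes per contrast and time point
#'
#' @param results A tibble of moderated-t results (rows from one or more
#'   [moderated_t()] calls bound together), or a list of such tibbles.
#' @param fdr False-discovery-rate threshold applied to `q`.
#' @return Tibble with columns `contrast`, `timepoint`, `n_de`.
#' @export
de_counts <- function(results, fdr = 0.05) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(results)
  }
  if (!nrow(results)) stop("no DE results supplied", call. = FALSE)
  results |>
    dplyr::group_by(.data$contrast, .data$timepoint) |>
    dplyr::summarise(n_de = sum(.data$q < fdr), .groups = "drop") |>
    dplyr::arrange(.data$contrast, .data$timepoint)
}
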