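#' Variance-stabilising-style expression transform
#'
#' `log2(normalised count + 1)` on size-factor-normalised counts: a
#' monotone, order-preserving transform that damps the mean-variance
#' relationship of count data before tissue-specificity scoring.
#'
#' @param counts Counts tibble (`transcript_id` + condition columns) or
#'   matrix.
#' @param sf Size factors; computed with [size_factors()] when `NULL`.
#' @return Tibble of transformed values, same shape as the input.
#' @export
transform_expression <- function(counts, sf = NULL) {
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  if (any(m < 0)) abort("negative counts")
  if (is.null(sf)) sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  out <- as_tibble(log2(norm + 1))
  out$transcript_id <- rownames(m)
  out[, c("transcript_id", setdiff(names(out), "transcript_id"))]
}

#' Tau tissue-specificity index
#'
#' For a per-condition expression vector `x` with maximum `max(x) > 0`,
#' `tau = sum(1 - x/max(x)) / (n - 1)`: 0 for uniform (broad) expression, 1
#' for expression confined to a single condition. The per-condition
#' components `1 - x/max(x)` are returned alongside for clustering
#' displays. Transcripts with all-zero expression get `tau = NA` and are
#' flagged rather than scored.
#'
#' @param expr Expression tibble (`transcript_id` + condition columns, e.g.
#'   from [transform_expression()]) or matrix; one row per transcript.
#' @return An object of class `haplotx_tau`: tibble with `transcript_id`,
#'   `tau`, `max_condition`, plus a `components` attribute (matrix of
#'   `1 - x/max` values).
#' @examples
#' expr <- tibble::tibble(transcript_id = "t1", a = 10, b = 5, c = 0, d = 0, e = 0)
#' tau_index(expr)   # tau = 0.875
#' @export
tau_index <- function(expr) {
  m <- if (is.matrix(expr)) expr else counts_matrix(expr)
  if (ncol(m) < 2) abort("tau needs at least two conditions")
  if (any(m < 0)) abort("negative expression values")
  mx <- apply(m, 1, max)
  comp <- 1 - sweep(m, 1, pmax(mx, .Machine$double.eps), "/")
  tau <- rowSums(comp) / (ncol(m) - 1)
  tau[mx == 0] <- NA_real_
  comp[mx == 0, ] <- NA_real_
  res <- tibble(
    transcript_id = rownames(m),
    tau = unname(tau),
    max_condition = colnames(m)[apply(m, 1, which.max)],
    computed = mx > 0
  )
  attr(res, "components") <- comp
  class(res) <- c("haplotx_tau", class(res))
  res
}

#' Per-condition tau components
#'
#' @param x A `haplotx_tau` result.
#' @return Matrix of `1 - x/max(x)` values (transcripts x conditions); the
#'   maximal condition of each transcript has component 0.
#' @export
tau_components <- function(x) attr(x, "components")

#' Tissue-specific transcript subset
#'
#' @param taus A `haplotx_tau` result (or tibble with a `tau` column).
#' @param threshold Strict lower bound on tau (default 0.8; `tau >
#'   threshold`).
#' @return List with `transcripts` (the qualifying subset) and `fraction`
#'   (share of scored transcripts above threshold).
#' @export
specific_set <- function(taus, threshold = 0.8) {
  scored <- taus[!is.na(taus$tau), , drop = FALSE]
  hit <- scored[scored$tau > threshold, , drop = FALSE]
  list(transcripts = as_tibble(hit),
       fraction = if (nrow(scored) == 0) NA_real_ else nrow(hit) / nrow(scored))
}

#' @export
glance.haplotx_tau <- function(x, ...) {
  tibble(n = nrow(x), n_scored = sum(!is.na(x$tau)),
         median_tau = stats::median(x$tau, na.rm = TRUE),
         frac_specific = specific_set(x)$fraction)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of tau values
#'
#' @param object A `haplotx_tau` result.
#' @param threshold Vertical reference line (default 0.8).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.haplotx_tau <- function(object, threshold = 0.8, ...) {
  df <- object[!is.na(object$tau), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2, colour = "red") +
    ggplot2::labs(x = expression(tau), y = "transcripts",
                  title = "Tissue specificity of retained transcripts") +
    ggplot2::theme_minimal()
}
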