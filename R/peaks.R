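#' Estimate the transcriptome-wide background mismatch rate
#'
#' Pools both strands: `n_total` (N) is the total number of sequenced bases
#' (sum of column depths) and `m_background` (M) the total count of the 11
#' non-T-to-C substitution types. The per-base null T-to-C rate is
#' \deqn{R = M / (11 \times N)} — dividing the pooled background mismatch
#' rate by the number of background substitution types yields the rate of a
#' single substitution type, which is the natural null rate for T-to-C in
#' the absence of crosslinking. When `m_background` is 0 (pristine data) the
#' rate is floored at `1 / (divisor * n_total)` so downstream p-values are
#' never exactly zero.
#'
#' @param tracks A `parclip_tracks` tibble covering both strands.
#' @param divisor Number of background substitution types the pooled rate is
#'   divided by, default 11.
#' @return An object of class `parclip_background`: a list with `n_total`,
#'   `m_background`, `rate`, `divisor`, `floored`.
#' @export
estimate_background <- function(tracks, divisor = 11) {
  n_total <- sum(as.numeric(tracks$depth))
  if (n_total == 0) stop("no usable coverage: total sequenced bases is 0",
                         call. = FALSE)
  m <- sum(as.numeric(tracks$other_mm))
  floored <- m == 0
  rate <- if (floored) 1 / (divisor * n_total) else m / (divisor * n_total)
  structure(
    list(n_total = n_total, m_background = m, rate = rate,
         divisor = divisor, floored = floored),
    class = "parclip_background"
  )
}

#' @export
print.parclip_background <- function(x, ...) {
  cat("PAR-CLIP background model\n")
  cat("  total sequenced bases (N): ", format(x$n_total, big.mark = ","), "\n")
  cat("  background mismatches (M): ", format(x$m_background, big.mark = ","),
      if (x$floored) " (rate floored)" else "", "\n", sep = "")
  cat("  null T-to-C rate R = M/(", x$divisor, "N) = ",
      signif(x$rate, 6), "\n", sep = "")
  invisible(x)
}

#' @method tidy parclip_background
#' @export
tidy.parclip_background <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, m_background = x$m_background,
                 rate = x$rate, divisor = x$divisor, floored = x$floored)
}

#' Exact upper-tail Poisson probability
#'
#' `P(X >= observed)` for `X ~ Poisson(rate * n_bases)`, the one-sided
#' p-value of an exact rate test of `observed` events over an exposure of
#' `n_bases` bases against null rate `rate` — identical to
#' `poisson.test(observed, n_bases, rate, alternative = "greater")$p.value`.
#'
#' @param observed Non-negative integer count(s) of T-to-C events.
#' @param n_bases Positive exposure(s): total sequenced bases in the group.
#' @param rate Positive per-base null rate.
#' @return The upper-tail probability, vectorized over inputs.
#' @examples
#' poisson_upper_tail(3, 1000, 0.001)  # lambda = 1: 1 - e^-1 (1 + 1 + 1/2)
#' @export
poisson_upper_tail <- function(observed, n_bases, rate) {
  if (any(observed < 0) || any(n_bases <= 0) || any(rate < 0))
    stop("observed must be >= 0, n_bases > 0 and rate >= 0", call. = FALSE)
  stats::ppois(observed - 1, lambda = rate * n_bases, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up BH q-values: sort ascending, take the cumulative minimum
#' from the largest rank of `p * m / rank`, cap at 1, return in input order.
#'
#' @param p_values Probabilities in `[0, 1]`.
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Test read groups for T-to-C enrichment and call clusters
#'
#' For every read group the expected T-to-C count under the background model
#' is `lambda_i = R * n_i`; an exact one-sided Poisson test gives a p-value,
#' BH adjustment a q-value over all tested groups genome-wide (both strands,
#' one family), and groups with `q <= alpha` are called clusters —
#' high-confidence RBP interaction sites. Groups with zero observed T-to-C
#' are retained through testing (they get p = 1), keeping the BH family
#' size honest.
#'
#' @param groups Quantified read groups ([quantify_groups()] /
#'   [find_read_groups()]), built from the same tracks as `model`.
#' @param model A `parclip_background` from [estimate_background()].
#' @param alpha FDR threshold, default 0.05 (inclusive).
#' @return A tibble of class `parclip_calls`: the input rows plus
#'   `expected`, `p_value`, `q_value`, `is_cluster`, with cluster names
#'   `CL<i>` for called rows. Input order preserved.
#' @export
call_clusters <- function(groups, model, alpha = 0.05) {
  stopifnot(inherits(model, "parclip_background"))
  out <- tibble::as_tibble(groups)
  if (nrow(out) == 0) {
    out$expected <- out$p_value <- out$q_value <- numeric(0)
    out$is_cluster <- logical(0)
  } else {
    out$expected <- model$rate * out$n_bases
    out$p_value <- ifelse(out$n_bases > 0,
                          poisson_upper_tail(out$o_t2c, pmax(out$n_bases, 1),
                                             model$rate),
                          1)
    out$q_value <- bh_adjust(out$p_value)
    out$is_cluster <- out$q_value <= alpha
    if ("name" %in% names(out) && any(out$is_cluster))
      out$name[out$is_cluster] <- paste0("CL", seq_len(sum(out$is_cluster)))
  }
  structure(out, class = c("parclip_calls", class(tibble::tibble())),
            background = model, alpha = alpha)
}

#' @method tidy parclip_calls
#' @export
tidy.parclip_calls <- function(x, ...) {
  tibble::as_tibble(unclass_calls(x))
}

#' @method glance parclip_calls
#' @export
glance.parclip_calls <- function(x, ...) {
  bg <- attr(x, "background")
  tibble::tibble(
    n_groups = nrow(x),
    n_clusters = sum(x$is_cluster),
    n_rejected = sum(!x$is_cluster),
    alpha = attr(x, "alpha"),
    rate = bg$rate, n_total = bg$n_total, m_background = bg$m_background
  )
}

unclass_calls <- function(x) {
  attr(x, "background") <- NULL
  attr(x, "alpha") <- NULL
  class(x) <- setdiff(class(x), "parclip_calls")
  x
}

#' Cluster-only and rejected-group views of a call set
#'
#' @param calls A `parclip_calls` tibble.
#' @return A tibble of the called clusters (`clusters()`) or of the groups
#'   that failed the FDR threshold (`rejected_groups()`).
#' @export
clusters <- function(calls) {
  tidy(calls)[calls$is_cluster, , drop = FALSE]
}

#' @rdname clusters
#' @export
rejected_groups <- function(calls) {
  tidy(calls)[!calls$is_cluster, , drop = FALSE]
}

#' End-to-end peak calling from a BAM file
#'
#' Runs the full caller: mismatch tracks, background estimation, read-group
#' derivation, Poisson testing and BH thresholding.
#'
#' @inheritParams build_tracks
#' @inheritParams find_read_groups
#' @inheritParams call_clusters
#' @inheritParams estimate_background
#' @return A `parclip_calls` tibble (see [call_clusters()]).
#' @export
call_peaks <- function(bam, fasta, min_mapq = 55L, min_baseq = 20L,
                       min_depth = 3L, gap = 0L, max_width = 50L,
                       alpha = 0.05, divisor = 11) {
  tracks <- build_tracks(bam, fasta, min_mapq = min_mapq,
                         min_baseq = min_baseq)
  model <- estimate_background(tracks, divisor = divisor)
  groups <- find_read_groups(tracks, min_depth = min_depth, gap = gap,
                             max_width = max_width)
  call_clusters(groups, model, alpha = alpha)
}

#' Diagnostic plot of a call set
#'
#' Observed versus expected T-to-C counts per read group, colored by cluster
#' status; the diagonal marks the null expectation.
#'
#' @param object A `parclip_calls` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot parclip_calls
#' @export
autoplot.parclip_calls <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$o_t2c,
                                   colour = .data$is_cluster)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = "cluster") +
    ggplot2::labs(x = "expected T-to-C (R × n)",
                  y = "observed T-to-C (O)",
                  title = "T-to-C enrichment over the Poisson background")
}
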