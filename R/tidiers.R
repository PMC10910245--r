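#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ridge fit into one row per model term
#'
#' @param x A [ridge_fit()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error` (from the sandwich
#'   covariance when it was computed) and `heritability` (`NA` for the
#'   intercept and covariate columns, which are never ranked).
#' @method tidy ridge_fit
#' @export
tidy.ridge_fit <- function(x, ...) {
  p <- length(x$m_bar)
  h <- rep(NA_real_, p)
  h[x$design$feature_cols] <- feature_heritability(x)
  tibble::tibble(
    term = names(x$m_bar),
    estimate = unname(x$m_bar),
    std.error = if (is.null(x$cov_m)) NA_real_ else sqrt(diag(x$cov_m)),
    heritability = h
  )
}

#' One-row summary of a ridge fit
#'
#' @param x A [ridge_fit()].
#' @param ... Unused.
#' @return Tibble with the penalty, the three components of the weighted
#'   sum-of-squares decomposition, and the problem size.
#' @method glance ridge_fit
#' @export
glance.ridge_fit <- function(x, ...) {
  tibble::tibble(
    C = x$C,
    e_res2 = x$e_res2,
    explained_ss = x$explained_ss,
    penalty_ss = x$C * sum(x$m_bar^2),
    total_weighted_ss = x$total_weighted_ss,
    nobs = length(x$y),
    nterms = length(x$m_bar)
  )
}

#' @method tidy youden_curve
#' @export
tidy.youden_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a Youden curve
#'
#' @param x A `youden_curve` from [score_subsets()].
#' @param ... Unused.
#' @return Tibble with the cutoff step, its subset size and J, and the
#'   curve maximum.
#' @method glance youden_curve
#' @export
glance.youden_curve <- function(x, ...) {
  j <- attr(x, "cutoff_index")
  tibble::tibble(
    cutoff_step = j,
    cutoff_size = x$subset_size[j],
    cutoff_J = x$mean_J[j],
    max_J = max(x$mean_J),
    n_steps = nrow(x)
  )
}

#' @method tidy support_table
#' @export
tidy.support_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a support table
#'
#' @param x A `support_table` from [run_stability()].
#' @param ... Unused.
#' @return Tibble with replication count, SNP count, and support extremes.
#' @method glance support_table
#' @export
glance.support_table <- function(x, ...) {
  tibble::tibble(
    n_iterations = x$n_iterations[1],
    n_snps = nrow(x),
    max_support = max(x$support),
    n_full_support = sum(x$support == x$n_iterations[1]),
    median_support = stats::median(x$support)
  )
}

#' Plot a Youden curve with its cutoff
#'
#' @param object A `youden_curve`.
#' @param ... Unused.
#' @return A ggplot: fold-averaged J against the number of leading ranked
#'   features, the first local maximum marked.
#' @method autoplot youden_curve
#' @export
autoplot.youden_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subset_size, y = .data$mean_J)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(
      data = df[df$is_cutoff, ],
      colour = "red", size = 2.5
    ) +
    ggplot2::labs(
      x = "leading ranked features",
      y = "fold-averaged Youden J",
      title = "Youden curve",
      subtitle = "red: first local maximum (selection cutoff)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-SNP support
#'
#' @param object A `support_table`.
#' @param top Show only the `top` most supported SNPs (default 50).
#' @param threshold Optional support threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot of support counts in decreasing order.
#' @method autoplot support_table
#' @export
autoplot.support_table <- function(object, top = 50, threshold = NULL, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  df$snp_id <- factor(df$snp_id, levels = df$snp_id)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$snp_id, y = .data$support)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(
      x = NULL, y = paste0("support (of ", df$n_iterations[1], ")"),
      title = "Replication support per SNP"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Histogram of PRS weights with selected tail bins highlighted
#'
#' @param weights Tibble with `snp_id`, `beta` (or named numeric vector).
#' @param n_bins,bin_fraction_max As in [select_by_beta_histogram()].
#' @return A ggplot histogram; bins below the occupancy ceiling (the
#'   selected tails) are filled red.
#' @export
plot_beta_histogram <- function(weights, n_bins = 50, bin_fraction_max = 2e-4) {
  if (is.numeric(weights)) {
    weights <- tibble::tibble(
      snp_id = names(weights) %||% as.character(seq_along(weights)),
      beta = unname(weights)
    )
  }
  rng <- range(weights$beta)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(
    weights$beta, breaks,
    rightmost.closed = TRUE, all.inside = TRUE
  )
  frac <- tabulate(bin, nbins = n_bins) / nrow(weights)
  df <- tibble::tibble(
    mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
    count = tabulate(bin, nbins = n_bins),
    selected = frac < bin_fraction_max & frac > 0
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count,
                                   fill = .data$selected)) +
    ggplot2::geom_col(width = diff(breaks)[1]) +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "red"), guide = "none"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "PRS weight", y = "SNPs per bin (log scale)",
      title = "PRS weight histogram",
      subtitle = "red: sparse tail bins selected as non-neutral"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
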