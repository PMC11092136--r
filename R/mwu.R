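# Mann-Whitney U testing, plain and resampled. The resampled form addresses
# the extreme size imbalance between the repurposing pairs (tens to thousands)
# and the background universe (up to hundreds of millions): each iteration
# draws a background subsample the same size as the DR sample and tests the
# fixed DR sample against it, yielding a distribution of p-values rather than
# a single one.

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with midrank tie handling, oriented as the number of
#' (x, y) cross-pairs where x exceeds y (ties counting one half). The p-value
#' uses the normal approximation with tie and continuity corrections; when
#' `length(x) * length(y) <= 400` and there are no ties, the exact null
#' distribution is used instead.
#'
#' @param x,y Numeric samples (each nonempty).
#' @param alternative `"two_sided"` (default) or `"less"` (x stochastically
#'   smaller than y).
#' @return A list with elements `U`, `p`, `n_x`, `n_y`, `exact`.
#' @examples
#' mwu_test(c(1, 2), c(10, 20))$U # 0
#' @export
mwu_test <- function(x, y, alternative = c("two_sided", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1 || length(y) < 1) {
    stop_invalid("Both samples must be nonempty.", "drembed_invalid_parameter")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_invalid("Samples must not contain NA.", "drembed_invalid_parameter")
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  exact <- (n1 * n2 <= 400) && !has_ties

  if (exact) {
    p <- switch(alternative,
      two_sided = {
        if (U > n1 * n2 / 2) {
          min(1, 2 * pwilcox(U - 1, n1, n2, lower.tail = FALSE))
        } else {
          min(1, 2 * pwilcox(U, n1, n2))
        }
      },
      less = pwilcox(U, n1, n2)
    )
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      corr <- switch(alternative, two_sided = sign(z) * 0.5, less = -0.5)
      z <- (z - corr) / sqrt(sigma2)
      p <- switch(alternative,
        two_sided = min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))),
        less = pnorm(z)
      )
    }
  }
  list(U = unname(U), p = unname(p), n_x = n1, n_y = n2, exact = exact)
}

#' Size-matched resampled Mann-Whitney U comparison
#'
#' Runs `n_iterations` MWU tests of the fixed DR-pair distance sample against
#' equally sized background subsamples drawn uniformly without replacement
#' (independently across iterations). Each iteration's draw is seeded from a
#' named substream of `seed`, so iteration k is reproducible and unaffected by
#' `n_iterations`.
#'
#' @param dr_distances Numeric vector of repurposing-pair distances (>= 2).
#' @param background Numeric vector of background distances, strictly larger
#'   than `dr_distances`.
#' @param n_iterations Number of resampling iterations (default 1000).
#' @param seed Master integer seed.
#' @param alternative Passed to [mwu_test()]; default `"two_sided"`.
#' @param method,source,filtered Optional labels stored in the result.
#' @return An object of class `resampled_mwu`: a list with the per-iteration
#'   `p_values`, their summary (`p_mean`, `p_std`, `p_median`), the DR-distance
#'   statistics (`dr_mean`, `dr_std`), `background_mean`, and the run
#'   bookkeeping (`n_dr`, `n_background_sampled`, `n_iterations`, labels).
#' @export
resampled_mwu <- function(dr_distances, background, n_iterations = 1000,
                          seed = 1L, alternative = c("two_sided", "less"),
                          method = NA_character_, source = NA_character_,
                          filtered = NA) {
  alternative <- match.arg(alternative)
  if (length(dr_distances) < 2) {
    stop_invalid("Need at least 2 DR distances.", "drembed_invalid_parameter")
  }
  if (length(background) <= length(dr_distances)) {
    stop_invalid(
      "Background universe must be strictly larger than the DR sample.",
      "drembed_invalid_parameter"
    )
  }
  if (n_iterations < 1) {
    stop_invalid("`n_iterations` must be >= 1.", "drembed_invalid_parameter")
  }
  n_dr <- length(dr_distances)
  p_values <- vapply(seq_len(n_iterations), function(i) {
    samp <- withr::with_seed(
      substream_seed(seed, paste0("mwu-iter-", i)),
      sample(background, n_dr)
    )
    mwu_test(dr_distances, samp, alternative = alternative)$p
  }, numeric(1))

  structure(
    list(
      method = method, source = source, filtered = filtered,
      alternative = alternative, seed = as.integer(seed),
      n_dr = n_dr, n_background_sampled = n_dr,
      n_background_total = length(background),
      n_iterations = as.integer(n_iterations),
      p_values = p_values,
      p_mean = mean(p_values), p_std = pop_sd(p_values),
      p_median = median(p_values),
      dr_mean = mean(dr_distances), dr_std = pop_sd(dr_distances),
      background_mean = mean(background)
    ),
    class = "resampled_mwu"
  )
}

#' @export
print.resampled_mwu <- function(x, ...) {
  cat(
    "<resampled_mwu> ",
    if (!is.na(x$method)) paste0("method=", x$method, " ") else "",
    if (!is.na(x$source)) paste0("source=", x$source, " ") else "",
    if (!is.na(x$filtered)) paste0("filtered=", x$filtered, " ") else "",
    "\n  n_dr=", x$n_dr, " vs background subsamples of ", x$n_background_sampled,
    " (universe ", x$n_background_total, "), ", x$n_iterations, " iterations\n",
    sprintf(
      "  p: mean %.4g, sd %.4g, median %.4g\n", x$p_mean, x$p_std, x$p_median
    ),
    sprintf(
      "  distances: DR mean %.4f +/- %.4f, background mean %.4f\n",
      x$dr_mean, x$dr_std, x$background_mean
    ),
    sep = ""
  )
  invisible(x)
}

#' Tidy a resampled MWU result
#'
#' @param x A `resampled_mwu` object.
#' @param ... Unused.
#' @method tidy resampled_mwu
#' @return A tibble with one row per iteration: `iteration`, `p`.
#' @export
tidy.resampled_mwu <- function(x, ...) {
  tibble(iteration = seq_len(x$n_iterations), p = x$p_values)
}

#' One-row summary of a resampled MWU result
#'
#' @param x A `resampled_mwu` object.
#' @param ... Unused.
#' @method glance resampled_mwu
#' @return A one-row tibble with the test labels, sample sizes, p-value
#'   statistics and distance statistics.
#' @export
glance.resampled_mwu <- function(x, ...) {
  tibble(
    method = x$method, source = x$source, filtered = x$filtered,
    alternative = x$alternative,
    n_dr = x$n_dr, n_background_sampled = x$n_background_sampled,
    n_background_total = x$n_background_total,
    n_iterations = x$n_iterations,
    p_mean = x$p_mean, p_std = x$p_std, p_median = x$p_median,
    frac_p_lt_05 = mean(x$p_values < 0.05),
    dr_mean = x$dr_mean, dr_std = x$dr_std,
    background_mean = x$background_mean
  )
}

#' Histogram of the resampled p-value distribution
#'
#' @param object A `resampled_mwu` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @method autoplot resampled_mwu
#' @return A ggplot object.
#' @export
autoplot.resampled_mwu <- function(object, bins = 40, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(
      bins = bins, boundary = 0, fill = "steelblue", colour = "grey30"
    ) +
    ggplot2::geom_vline(xintercept = 0.05, linetype = 2, colour = "firebrick") +
    ggplot2::labs(
      x = "Mann-Whitney U p-value",
      y = "iterations",
      title = paste0(
        "Resampled MWU (", object$n_iterations, " iterations)",
        if (!is.na(object$method)) paste0(", ", object$method) else ""
      ),
      subtitle = sprintf(
        "n_dr = %d; p median = %.3g; DR mean %.4f vs background mean %.4f",
        object$n_dr, object$p_median, object$dr_mean, object$background_mean
      )
    ) +
    ggplot2::theme_minimal()
}
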