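# t-SNE projection of embedding sets to 2D/3D and class-coloured scatter
# plots, used to check visually that an encoding groups proteins of the same
# functional class.

#' Project an embedding set with t-SNE
#'
#' Rows are sorted into canonical id order before projection, so the result is
#' independent of input row order; with a fixed seed the projection is
#' deterministic.
#'
#' @param embeddings An `embedding_set` with at least 4 rows.
#' @param dims 2 (default) or 3 output dimensions.
#' @param perplexity t-SNE perplexity; must satisfy `perplexity < (n - 1) / 3`.
#'   Default 30.
#' @param seed Integer seed.
#' @return An object of class `protein_projection`: a tibble with columns `id`,
#'   `x`, `y` (and `z` for `dims = 3`), with the source method, perplexity and
#'   seed stored as attributes.
#' @export
tsne_project <- function(embeddings, dims = 2, perplexity = 30, seed = 1L) {
  stopifnot(inherits(embeddings, "embedding_set"))
  if (!dims %in% c(2, 3)) {
    stop_invalid("`dims` must be 2 or 3.", "drembed_invalid_parameter")
  }
  n <- length(embeddings$ids)
  if (n < 4) {
    stop_invalid("t-SNE needs at least 4 rows.", "drembed_invalid_parameter")
  }
  if (perplexity >= (n - 1) / 3) {
    stop_invalid(
      paste0(
        "`perplexity` must be < (n - 1) / 3 = ", (n - 1) / 3,
        " for n = ", n, " proteins."
      ),
      "drembed_invalid_parameter"
    )
  }
  ids <- sort_c(embeddings$ids)
  m <- embeddings$matrix[match(ids, embeddings$ids), , drop = FALSE]
  fit <- withr::with_seed(
    substream_seed(seed, "tsne"),
    Rtsne::Rtsne(
      m,
      dims = dims, perplexity = perplexity,
      check_duplicates = FALSE, pca = ncol(m) > 50, verbose = FALSE
    )
  )
  coords <- fit$Y
  out <- tibble(id = ids, x = coords[, 1], y = coords[, 2])
  if (dims == 3) out$z <- coords[, 3]
  structure(
    out,
    class = c("protein_projection", class(out)),
    method_label = embeddings$method,
    perplexity = perplexity,
    seed = as.integer(seed),
    dims = dims
  )
}

projection_plot_data <- function(projection, classes) {
  stopifnot(inherits(projection, "protein_projection"))
  if (nrow(projection) == 0) {
    stop_invalid("Empty projection.", "drembed_invalid_records")
  }
  class_map <- classes
  if (is.data.frame(classes)) {
    stopifnot(all(c("id", "class") %in% names(classes)))
    if (anyDuplicated(classes$id)) {
      stop_invalid(
        "Each id must map to a single class; use select_single_class() upstream.",
        "drembed_invalid_records"
      )
    }
    class_map <- stats::setNames(classes$class, classes$id)
  }
  missing <- setdiff(projection$id, names(class_map))
  if (length(missing) > 0) {
    stop_invalid(
      paste0(
        "Ids missing from the class map: ",
        paste(head(missing, 10), collapse = ", "),
        if (length(missing) > 10) ", ..." else ""
      ),
      "drembed_invalid_records"
    )
  }
  df <- as_tibble(projection)
  df$class <- unname(class_map[df$id])
  if ("z" %in% names(df)) {
    # simple oblique 3D perspective onto the page
    df$px <- df$x + 0.45 * df$z
    df$py <- df$y + 0.35 * df$z
    df <- df[order(df$z), , drop = FALSE]
  } else {
    df$px <- df$x
    df$py <- df$y
  }
  df
}

#' Class-coloured scatter plot of a projection
#'
#' One marker per protein, coloured by its (single) functional class. 3D
#' projections are drawn as an oblique perspective scatter, depth-ordered.
#'
#' @param projection A `protein_projection`.
#' @param classes Either a tibble (`id`, `class`) with one class per id, or a
#'   named character vector `id -> class`.
#' @param out_path Optional image path (`.png`, `.svg`, `.pdf`); written with
#'   `ggplot2::ggsave()`.
#' @param point_size Marker size.
#' @return The ggplot object, invisibly if `out_path` is given.
#' @export
plot_class_scatter <- function(projection, classes, out_path = NULL,
                               point_size = 1.6) {
  df <- projection_plot_data(projection, classes)
  dims <- attr(projection, "dims") %||% 2
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$px, y = .data$py, colour = .data$class
  )) +
    ggplot2::geom_point(size = point_size, alpha = 0.85) +
    ggplot2::labs(
      x = "t-SNE 1", y = "t-SNE 2", colour = "class",
      title = paste0(
        "t-SNE (", dims, "D) of ", attr(projection, "method_label"),
        " embeddings"
      ),
      subtitle = if (dims == 3) "oblique perspective of the 3D layout" else NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, p, width = 7, height = 5.5, dpi = 150)
    return(invisible(p))
  }
  p
}

#' @rdname plot_class_scatter
#' @param object A `protein_projection` (autoplot interface).
#' @param ... Passed to [plot_class_scatter()].
#' @method autoplot protein_projection
#' @export
autoplot.protein_projection <- function(object, classes, ...) {
  plot_class_scatter(object, classes, ...)
}
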