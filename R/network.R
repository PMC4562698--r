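#' Build an RSSI-thresholded contact network
#'
#' Symmetric weighted adjacency over tags: every encounter record (dyadic
#' records count once, using the maximum RSSI over both sides; single
#' records count once with their own maximum) whose combined maximum RSSI
#' is at least `rssi_threshold` increments its pair's edge weight by one.
#' With the default calibration, threshold 0 selects encounters closer
#' than about 5 m and threshold 40 encounters closer than about 0.1 m
#' (body contact).
#'
#' @param records Record tibble from [call_dyads()], ideally restricted to
#'   common uptime first (see [restrict_to_common_uptime()]).
#' @param rssi_threshold Minimum combined maximum RSSI for an encounter to
#'   count.
#' @param tags Optional character vector fixing the node set (defaults to
#'   the tags present in `records`).
#' @param sex Optional named vector of node attributes (e.g. `"F"`/`"M"`)
#'   carried into exports.
#' @return An object of class `contact_network`: integer weight matrix
#'   (`$weights`, symmetric, zero diagonal), `$threshold`, `$nodes`, and
#'   the time window spanned by the records (`$window`).
#' @export
build_network <- function(records, rssi_threshold = 0, tags = NULL,
                          sex = NULL) {
  cv <- record_covariates(records)
  tags <- sort(tags %||% unique(c(records$tag_a, records$tag_b)))
  w <- matrix(0L, length(tags), length(tags), dimnames = list(tags, tags))
  keep <- cv$max_rssi >= rssi_threshold
  for (i in which(keep)) {
    a <- cv$tag_a[i]; b <- cv$tag_b[i]
    w[a, b] <- w[a, b] + 1L
    w[b, a] <- w[b, a] + 1L
  }
  nodes <- tibble::tibble(
    tag_id = tags,
    sex = if (!is.null(sex)) unname(sex[tags]) else NA_character_
  )
  structure(list(
    weights = w,
    threshold = rssi_threshold,
    nodes = nodes,
    window = if (nrow(records)) c(min(records$start_t), max(records$end_t))
             else c(NA_real_, NA_real_),
    n_encounters = sum(keep)
  ), class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf(
    "<contact_network> %d tags, threshold %g+ max RSSI, %d encounters, density %.3f\n",
    nrow(x$weights), x$threshold, x$n_encounters, network_density(x)
  ))
  invisible(x)
}

#' Network density
#'
#' Proportion of possible tag pairs connected by at least one encounter.
#'
#' @param net A [build_network()] result.
#' @return A proportion in `[0, 1]`.
#' @export
network_density <- function(net) {
  n <- nrow(net$weights)
  if (n < 2) abort("Density undefined for fewer than two nodes.")
  sum(net$weights[upper.tri(net$weights)] > 0) / choose(n, 2)
}

#' Convert a contact network to an igraph object
#'
#' @param net A [build_network()] result.
#' @return An undirected weighted [igraph::graph].
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!all(is.na(net$nodes$sex))) {
    igraph::V(g)$sex <- net$nodes$sex
  }
  igraph::graph_attr(g, "rssi_threshold") <- net$threshold
  g
}

#' Export and import contact networks
#'
#' Three lossless on-disk formats: an edge-list CSV (`tag_a,tag_b,weight`,
#' nonzero pairs only, plus a node table side file when node attributes
#' are present is not needed — isolated nodes are retained through a
#' `# nodes:` header comment), a full symmetric matrix CSV with tag ids as
#' header row and column, and GraphML (via igraph) carrying the `sex` node
#' attribute and the threshold as a graph attribute.
#'
#' @param net A [build_network()] result.
#' @param path Output file.
#' @param format `"edgelist"`, `"matrix"` or `"graphml"`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a `contact_network`.
#' @export
write_network <- function(net, path, format = c("edgelist", "matrix",
                                                "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    w <- net$weights
    idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    el <- tibble::tibble(
      tag_a = rownames(w)[idx[, 1]],
      tag_b = colnames(w)[idx[, 2]],
      weight = w[idx]
    ) |> dplyr::arrange(.data$tag_a, .data$tag_b)
    hdr <- paste0("# nodes: ", paste(rownames(w), collapse = " "),
                  "; threshold: ", net$threshold)
    writeLines(hdr, path)
    readr::write_csv(el, path, append = TRUE, col_names = TRUE)
  } else if (format == "matrix") {
    w <- net$weights
    df <- tibble::as_tibble(w, rownames = "tag_id")
    hdr <- paste0("# threshold: ", net$threshold)
    writeLines(hdr, path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("edgelist", "matrix", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    hdr <- readLines(path, n = 1)
    meta <- sub("^# nodes: ", "", hdr)
    nodes <- strsplit(sub(";.*$", "", meta), " ")[[1]]
    threshold <- as.numeric(sub("^.*threshold: ", "", hdr))
    el <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
    w <- matrix(0L, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(el))) {
      w[el$tag_a[i], el$tag_b[i]] <- as.integer(el$weight[i])
      w[el$tag_b[i], el$tag_a[i]] <- as.integer(el$weight[i])
    }
  } else if (format == "matrix") {
    hdr <- readLines(path, n = 1)
    threshold <- as.numeric(sub("^# threshold: ", "", hdr))
    df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
    nodes <- df$tag_id
    w <- as.matrix(df[, -1])
    rownames(w) <- nodes
    storage.mode(w) <- "integer"
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    w0 <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    nodes <- igraph::V(g)$name
    dimnames(w0) <- list(nodes, nodes)
    w <- w0
    storage.mode(w) <- "integer"
    threshold <- igraph::graph_attr(g, "rssi_threshold")
    sex <- if ("sex" %in% igraph::vertex_attr_names(g)) igraph::V(g)$sex
    net <- structure(list(
      weights = w, threshold = threshold,
      nodes = tibble::tibble(tag_id = nodes,
                             sex = sex %||% NA_character_),
      window = c(NA_real_, NA_real_),
      n_encounters = NA_integer_
    ), class = "contact_network")
    return(net)
  }
  structure(list(
    weights = w, threshold = threshold,
    nodes = tibble::tibble(tag_id = rownames(w), sex = NA_character_),
    window = c(NA_real_, NA_real_), n_encounters = NA_integer_
  ), class = "contact_network")
}

#' Plot a contact network
#'
#' Force-directed (Fruchterman-Reingold) layout with edge width
#' proportional to contact count; a convenience view, not part of the
#' analytical contract.
#'
#' @param object A [build_network()] result.
#' @param edge_scale Multiplier on edge widths (dense low-threshold
#'   networks are easier to read around 1/5).
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.contact_network <- function(object, edge_scale = 1, seed = 1L, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(
    tag_id = object$nodes$tag_id,
    sex = object$nodes$sex,
    x = xy[, 1], y = xy[, 2]
  )
  ed <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble::tibble(
    x = nodes$x[match(ed$from, nodes$tag_id)],
    y = nodes$y[match(ed$from, nodes$tag_id)],
    xend = nodes$x[match(ed$to, nodes$tag_id)],
    yend = nodes$y[match(ed$to, nodes$tag_id)],
    weight = ed$weight
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight * edge_scale),
      colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   fill = .data$sex %||% "tag"),
      shape = 21, size = 6, show.legend = !all(is.na(nodes$sex))
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$tag_id),
      size = 2.5
    ) +
    ggplot2::scale_linewidth_continuous(range = c(0.2, 2)) +
    ggplot2::labs(
      title = sprintf("Contact network (max RSSI >= %g)", object$threshold),
      linewidth = "contacts", fill = "sex"
    ) +
    ggplot2::theme_void()
}
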