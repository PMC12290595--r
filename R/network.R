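#' Construct a connectivity network
#'
#' A connectivity network is a tibble edge list (columns `node_i`, `node_j`,
#' `weight`, `signed_value`, `lag`) carrying node, metric, band and
#' trial-count metadata as attributes. Edges are undirected and stored with
#' `node_i < node_j`; weights are non-negative and finite.
#'
#' @param edges data frame with at least `node_i`, `node_j`, `weight`;
#'   optional `signed_value` and `lag`
#' @param nodes tibble with `id`, `label` and optional `x`, `y`, `z`
#'   positions (mm), or a character vector of labels
#' @param metric metric id (see [CONN_METRICS])
#' @param band numeric `c(fmin, fmax)` in Hz (NA for time-domain metrics)
#' @param n_trials number of trials averaged into the edges
#' @param normalized has [normalize_by_max()] been applied
#' @param flags character vector of machine-readable quality flags
#' @return object of class `conn_network` (a tibble subclass)
#' @export
conn_network <- function(edges, nodes, metric, band = c(NA_real_, NA_real_),
                         n_trials = 0L, normalized = FALSE,
                         flags = character()) {
  if (is.character(nodes)) {
    nodes <- tibble(id = seq_along(nodes), label = nodes)
  }
  edges <- as_tibble(edges)
  if (!all(c("node_i", "node_j", "weight") %in% names(edges))) {
    config_error("edges need columns node_i, node_j, weight")
  }
  if (!"signed_value" %in% names(edges)) edges$signed_value <- NA_real_
  if (!"lag" %in% names(edges)) edges$lag <- NA_integer_
  edges <- edges[, c("node_i", "node_j", "weight", "signed_value", "lag")]
  if (nrow(edges) > 0L) {
    if (any(edges$node_i >= edges$node_j)) {
      config_error("edges must satisfy node_i < node_j (undirected half-matrix)")
    }
    if (anyDuplicated(edges[, c("node_i", "node_j")])) {
      config_error("duplicate edges")
    }
    if (any(!is.finite(edges$weight)) || any(edges$weight < 0)) {
      config_error("edge weights must be finite and non-negative")
    }
  }
  new_tibble(edges, nodes = nodes, metric = metric, band = band,
             n_trials = as.integer(n_trials), normalized = isTRUE(normalized),
             flags = flags, class = "conn_network")
}

#' @export
print.conn_network <- function(x, ...) {
  b <- attr(x, "band")
  cat(sprintf("# connectivity network: %s, %d nodes, %d edges, N = %d trials%s%s\n",
              attr(x, "metric"), nrow(attr(x, "nodes")), nrow(x),
              attr(x, "n_trials"),
              if (!is.na(b[1L])) sprintf(", band %g-%g Hz", b[1L], b[2L]) else "",
              if (attr(x, "normalized")) ", normalized" else ""))
  if (length(attr(x, "flags"))) {
    cat("# flags:", paste(attr(x, "flags"), collapse = ", "), "\n")
  }
  NextMethod()
}

#' Network accessors
#' @param net a [conn_network()]
#' @return nodes tibble / metric id / trial count
#' @export
network_nodes <- function(net) attr(net, "nodes")

#' @rdname network_nodes
#' @export
network_metric <- function(net) attr(net, "metric")

#' @rdname network_nodes
#' @export
network_flags <- function(net) attr(net, "flags")

#' Normalize a network by its maximum edge weight
#'
#' Divides all weights (and signed values) by the maximum weight so the
#' strongest edge becomes 1. A network whose weights are all zero is returned
#' unchanged with an `all_zero` flag. Idempotent.
#'
#' @param net a [conn_network()]
#' @return normalized network
#' @export
normalize_by_max <- function(net) {
  if (nrow(net) == 0L) {
    attr(net, "normalized") <- TRUE
    return(net)
  }
  mx <- max(net$weight)
  if (mx == 0) {
    attr(net, "flags") <- union(attr(net, "flags"), "all_zero")
    attr(net, "normalized") <- TRUE
    return(net)
  }
  out <- net
  out$weight <- net$weight / mx
  out$signed_value <- net$signed_value / mx
  attr(out, "normalized") <- TRUE
  out
}

#' Keep the strongest fraction of edges
#'
#' Retains the `k = ceiling(p * E)` largest-weight edges of the `E` existing
#' edges. Ties at the cutoff are broken by ascending `(node_i, node_j)`
#' lexicographic order, so the result is deterministic.
#'
#' @param net a [conn_network()]
#' @param p fraction in (0, 1]
#' @return thresholded network
#' @export
threshold_top_fraction <- function(net, p) {
  if (p <= 0 || p > 1) config_error("`p` must be in (0, 1]")
  if (nrow(net) == 0L) return(net)
  k <- ceiling(p * nrow(net))
  ord <- order(-net$weight, net$node_i, net$node_j)
  keep <- sort(ord[seq_len(k)])
  at <- attributes(net)
  out <- net[keep, ]
  for (a in c("nodes", "metric", "band", "n_trials", "normalized", "flags")) {
    attr(out, a) <- at[[a]]
  }
  class(out) <- class(net)
  out
}

#' Node degree and strength
#'
#' Degree is the number of incident edges; strength the sum of incident edge
#' weights.
#'
#' @param net a [conn_network()]
#' @return tibble with `id`, `label`, and `degree` / `strength`
#' @export
node_degree <- function(net) {
  nodes <- network_nodes(net)
  cnt <- tabulate(c(net$node_i, net$node_j), nbins = nrow(nodes))
  tibble(id = nodes$id, label = nodes$label, degree = cnt)
}

#' @rdname node_degree
#' @export
node_strength <- function(net) {
  nodes <- network_nodes(net)
  s <- numeric(nrow(nodes))
  if (nrow(net) > 0L) {
    inc <- rowsum(c(net$weight, net$weight), c(net$node_i, net$node_j))
    s[as.integer(rownames(inc))] <- inc[, 1L]
  }
  tibble(id = nodes$id, label = nodes$label, strength = s)
}

#' Dense adjacency matrix of a network
#'
#' @param net a [conn_network()]
#' @return symmetric `n_nodes x n_nodes` matrix with zero diagonal
#' @export
adjacency_matrix <- function(net) {
  n <- nrow(network_nodes(net))
  m <- matrix(0, n, n, dimnames = list(network_nodes(net)$label,
                                       network_nodes(net)$label))
  if (nrow(net) > 0L) {
    m[cbind(net$node_i, net$node_j)] <- net$weight
    m[cbind(net$node_j, net$node_i)] <- net$weight
  }
  m
}

#' Write / read a network as a TSV edge list
#'
#' The file carries `#`-prefixed header lines with metric, band, trial count,
#' normalization state, flags, and the node table, followed by a tab-separated
#' edge list `node_i node_j weight signed_value lag`.
#' `read_network(write_network(net))` reproduces the network up to float text
#' precision (17 significant digits are written, so doubles round-trip
#' exactly).
#'
#' @param net a [conn_network()]
#' @param path file path
#' @return `path` invisibly (`write`); the network (`read`)
#' @export
write_network <- function(net, path) {
  nodes <- network_nodes(net)
  b <- attr(net, "band")
  hdr <- c(
    "# connstream network v1",
    sprintf("# metric=%s", attr(net, "metric")),
    sprintf("# band=%s,%s", fmt_num(b[1L]), fmt_num(b[2L])),
    sprintf("# n_trials=%d", attr(net, "n_trials")),
    sprintf("# normalized=%d", as.integer(attr(net, "normalized"))),
    sprintf("# flags=%s", paste(attr(net, "flags"), collapse = ",")),
    vapply(seq_len(nrow(nodes)), function(i) {
      pos <- if (all(c("x", "y", "z") %in% names(nodes)) &&
                 !anyNA(unlist(nodes[i, c("x", "y", "z")]))) {
        sprintf("\t%s\t%s\t%s", fmt_num(nodes$x[i]), fmt_num(nodes$y[i]),
                fmt_num(nodes$z[i]))
      } else ""
      sprintf("# node\t%d\t%s%s", nodes$id[i], nodes$label[i], pos)
    }, character(1)),
    "node_i\tnode_j\tweight\tsigned_value\tlag")
  rows <- sprintf("%d\t%d\t%s\t%s\t%s",
                  net$node_i, net$node_j, fmt_num(net$weight),
                  fmt_num(net$signed_value),
                  ifelse(is.na(net$lag), "NA", as.character(net$lag)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1L] != "# connstream network v1") {
    data_error("line 1: not a connstream network file")
  }
  get1 <- function(key, lineno) {
    pat <- paste0("^# ", key, "=")
    hit <- grep(pat, lines)
    if (length(hit) != 1L) data_error(sprintf("line %d: missing '%s' header", lineno, key))
    sub(pat, "", lines[hit])
  }
  metric <- get1("metric", 2L)
  band <- suppressWarnings(as.numeric(strsplit(get1("band", 3L), ",")[[1L]]))
  n_trials <- as.integer(get1("n_trials", 4L))
  normalized <- get1("normalized", 5L) == "1"
  flags <- strsplit(get1("flags", 6L), ",")[[1L]]
  node_lines <- grep("^# node\t", lines)
  nodes <- purrr::map(node_lines, function(ln) {
    f <- strsplit(sub("^# node\t", "", lines[ln]), "\t")[[1L]]
    if (!length(f) %in% c(2L, 5L)) {
      data_error(sprintf("line %d: malformed node entry", ln))
    }
    tibble(id = as.integer(f[1L]), label = f[2L],
           x = if (length(f) == 5L) as.numeric(f[3L]) else NA_real_,
           y = if (length(f) == 5L) as.numeric(f[4L]) else NA_real_,
           z = if (length(f) == 5L) as.numeric(f[5L]) else NA_real_)
  })
  nodes <- dplyr::bind_rows(nodes)
  if (all(is.na(nodes$x))) nodes <- nodes[, c("id", "label")]
  hdr_row <- which(lines == "node_i\tnode_j\tweight\tsigned_value\tlag")
  if (length(hdr_row) != 1L) data_error("missing edge column header line")
  edge_lines <- lines[-seq_len(hdr_row)]
  edges <- purrr::map(seq_along(edge_lines), function(i) {
    f <- strsplit(edge_lines[i], "\t")[[1L]]
    if (length(f) != 5L) {
      data_error(sprintf("line %d: expected 5 tab-separated fields", hdr_row + i))
    }
    vals <- suppressWarnings(list(
      node_i = as.integer(f[1L]), node_j = as.integer(f[2L]),
      weight = as.numeric(f[3L]),
      signed_value = if (f[4L] == "NA") NA_real_ else as.numeric(f[4L]),
      lag = if (f[5L] == "NA") NA_integer_ else as.integer(f[5L])))
    if (is.na(vals$node_i) || is.na(vals$node_j) || is.na(vals$weight)) {
      data_error(sprintf("line %d: unparseable edge", hdr_row + i))
    }
    as_tibble(vals)
  })
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble(node_i = integer(), node_j = integer(), weight = numeric(),
           signed_value = numeric(), lag = integer())
  conn_network(edges, nodes, metric = metric, band = band,
               n_trials = n_trials, normalized = normalized, flags = flags)
}

#' Write a network as a square adjacency CSV
#' @param net a [conn_network()]
#' @param path file path
#' @return `path`, invisibly
#' @export
write_adjacency_csv <- function(net, path) {
  utils::write.csv(adjacency_matrix(net), path, row.names = TRUE)
  invisible(path)
}

# broom-style methods -------------------------------------------------------

#' Tidy a connectivity network
#'
#' @param x a [conn_network()]
#' @param ... unused
#' @return tibble of edges with node labels joined in
#' @exportS3Method generics::tidy
tidy.conn_network <- function(x, ...) {
  nodes <- network_nodes(x)
  as_tibble(x) |>
    dplyr::left_join(setNames(nodes[, c("id", "label")], c("node_i", "label_i")),
                     by = "node_i") |>
    dplyr::left_join(setNames(nodes[, c("id", "label")], c("node_j", "label_j")),
                     by = "node_j") |>
    dplyr::select("node_i", "node_j", "label_i", "label_j",
                  "weight", "signed_value", "lag")
}

#' One-row summary of a connectivity network
#'
#' @param x a [conn_network()]
#' @param ... unused
#' @return one-row tibble
#' @exportS3Method generics::glance
glance.conn_network <- function(x, ...) {
  b <- attr(x, "band")
  tibble(metric = attr(x, "metric"), n_nodes = nrow(network_nodes(x)),
         n_edges = nrow(x), n_trials = attr(x, "n_trials"),
         fmin = b[1L], fmax = b[2L],
         max_weight = if (nrow(x)) max(x$weight) else NA_real_,
         normalized = attr(x, "normalized"))
}

#' Plot a connectivity network as an adjacency heat map
#'
#' @param object a [conn_network()]
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.conn_network <- function(object, ...) {
  df <- as_tibble(object)
  df <- dplyr::bind_rows(df,
    tibble(node_i = df$node_j, node_j = df$node_i, weight = df$weight,
           signed_value = df$signed_value, lag = df$lag))
  ggplot(df, aes(x = .data$node_i, y = .data$node_j, fill = .data$weight)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, NA)) +
    labs(x = "node", y = "node", fill = attr(object, "metric"),
         title = sprintf("%s network, N = %d trials", attr(object, "metric"),
                         attr(object, "n_trials"))) +
    theme_minimal()
}
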