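#' Build the thresholded relevance network
#'
#' Events are nodes; an edge joins a pair whose TSRF correlation exceeds
#' `r_threshold` (strictly) and, when `require_significance` is on, whose
#' p-value is strictly below `alpha`. Each pair also gets a signed strength
#' band following the usual reporting convention: `high` for `|R| > 0.7`,
#' `moderate` for `0.4 <= |R| <= 0.7`, `weak` otherwise. Connected
#' components (isolated events as singletons) summarize co-evolving event
#' clusters.
#'
#' No multiple-testing correction is applied by default — the raw per-pair
#' p-values at `alpha` are used across all pairs, which inflates the
#' family-wise error rate over the 276 pairs of a 24-event panel; set
#' `p_adjust = "BH"` for a Benjamini-Hochberg corrected variant.
#'
#' @param R,p Symmetric correlation and p-value matrices (as from
#'   [correlation_matrix()]), or pass the list returned by
#'   [correlation_matrix()] as `R`.
#' @param r_threshold Correlation threshold for an edge (default 0.7,
#'   strict `>`).
#' @param alpha Significance level for an edge (default 0.05, strict `<`).
#' @param require_significance Require `p < alpha` in addition to
#'   `R > r_threshold` (default `TRUE`).
#' @param p_adjust Multiple-testing adjustment for the edge rule, as accepted
#'   by [stats::p.adjust()]; default `"none"`.
#' @return A `relevance_network`: list with `R`, `p`, `bands` (character
#'   matrix), `edges` (tibble `u`, `v`, `R`, `p`, `band`), `components`
#'   (named integer membership), `params`.
#' @export
build_network <- function(R, p = NULL, r_threshold = 0.7, alpha = 0.05,
                          require_significance = TRUE, p_adjust = "none") {
  if (is.list(R) && !is.matrix(R)) {
    p <- R$p
    R <- R$R
  }
  if (!isTRUE(all.equal(R, t(R))) || !isTRUE(all.equal(p, t(p)))) {
    stop("R and p must be symmetric matrices", call. = FALSE)
  }
  if (r_threshold < -1 || r_threshold > 1) {
    stop("r_threshold must lie in [-1, 1]", call. = FALSE)
  }
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  ids <- rownames(R)
  if (is.null(ids)) ids <- paste0("event_", seq_len(nrow(R)))

  bands <- matrix(band_label(R, sign = TRUE), nrow(R), ncol(R),
                  dimnames = list(ids, ids))
  ut <- upper.tri(R)
  p_rule <- p
  p_rule[ut] <- stats::p.adjust(p[ut], method = p_adjust)
  p_rule[lower.tri(p_rule)] <- t(p_rule)[lower.tri(p_rule)]
  keep <- R > r_threshold & (!require_significance | p_rule < alpha) & ut
  idx <- which(keep, arr.ind = TRUE)
  r_edge <- R[keep]
  edges <- tibble::tibble(u = ids[idx[, 1]], v = ids[idx[, 2]],
                          R = r_edge, p = p[keep],
                          band = band_label(r_edge, sign = TRUE))
  edges <- edges[order(match(edges$u, ids), match(edges$v, ids)), ]

  g <- igraph::graph_from_data_frame(edges[c("u", "v")], directed = FALSE,
                                     vertices = data.frame(name = ids))
  membership <- igraph::components(g)$membership[ids]
  structure(list(R = R, p = p, bands = bands, edges = edges,
                 components = membership,
                 params = list(r_threshold = r_threshold, alpha = alpha,
                               require_significance = require_significance,
                               p_adjust = p_adjust)),
            class = "relevance_network")
}

# signed strength band for a correlation value
band_label <- function(r, sign = TRUE) {
  a <- abs(r)
  lab <- ifelse(a > 0.7, "high", ifelse(a >= 0.4, "moderate", "weak"))
  if (sign) {
    lab <- ifelse(lab == "weak", "weak",
                  paste0(lab, ifelse(r >= 0, "+", "-")))
  }
  lab
}

#' @export
print.relevance_network <- function(x, ...) {
  sizes <- sort(table(x$components), decreasing = TRUE)
  cat(sprintf(
    "<relevance_network> %d events, %d edges (R > %g%s), %d components (sizes %s)\n",
    nrow(x$R), nrow(x$edges), x$params$r_threshold,
    if (x$params$require_significance)
      sprintf(", p < %g", x$params$alpha) else "",
    length(sizes), paste(as.integer(sizes), collapse = ", ")))
  invisible(x)
}

#' Write a relevance network to disk
#'
#' Emits the correlation and p-value matrices as CSV (event ids as row and
#' column headers), the edge list (`u,v,R,p,band`), a 0/1 adjacency matrix,
#' a component membership table, and optionally GraphML for visualization
#' tools.
#'
#' @param network A `relevance_network`.
#' @param dir Output directory (created if needed).
#' @param graphml Also write `network.graphml` (default `TRUE`).
#' @return Character vector of files written, invisibly.
#' @export
write_network <- function(network, dir, graphml = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  wcsv <- function(x, name, rn = FALSE) {
    path <- file.path(dir, name)
    utils::write.csv(x, path, row.names = rn)
    files <<- c(files, path)
  }
  wcsv(network$R, "correlation_R.csv", rn = TRUE)
  wcsv(network$p, "correlation_p.csv", rn = TRUE)
  wcsv(as.data.frame(network$edges), "edges.csv")
  adj <- 1 * network_adjacency(network)
  wcsv(adj, "adjacency.csv", rn = TRUE)
  wcsv(data.frame(event_id = names(network$components),
                  component = as.integer(network$components)),
       "components.csv")
  if (graphml) {
    g <- network_graph(network)
    path <- file.path(dir, "network.graphml")
    igraph::write_graph(g, path, format = "graphml")
    files <- c(files, path)
  }
  invisible(files)
}

network_adjacency <- function(network) {
  ids <- rownames(network$R)
  adj <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(network$edges)) {
    adj[cbind(network$edges$u, network$edges$v)] <- TRUE
    adj[cbind(network$edges$v, network$edges$u)] <- TRUE
  }
  adj
}

network_graph <- function(network) {
  igraph::graph_from_data_frame(
    as.data.frame(network$edges), directed = FALSE,
    vertices = data.frame(name = rownames(network$R)))
}
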