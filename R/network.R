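# Cross-kingdom association networks: all-pairs Spearman correlation with
# t-approximation p-values, BH-thresholded signed graphs, topology
# metrics (degree, BFS path length, components) and group comparison.

#' Spearman rank correlation of two vectors
#'
#' Midranks for ties, then the product-moment formula on the centered
#' ranks. Returns `NA` for constant vectors.
#'
#' @param x,y numeric vectors of equal length
#' @return rho in `[-1, 1]`, or `NA`
#' @export
spearman_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  den <- sqrt(sum(cx^2) * sum(cy^2))
  if (den == 0) return(NA_real_)
  sum(cx * cy) / den
}

#' All-pairs Spearman correlations across typed feature blocks
#'
#' Computes rho and a t-distribution approximate p-value for every
#' unordered pair of variables drawn from the supplied blocks. Pairs with
#' fewer complete observations than `min_complete`, or involving a
#' constant variable, are skipped (counts are reported via `message`).
#'
#' @param blocks named list of numeric matrices (samples x variables)
#'   with identical rownames; names give the node classes, e.g.
#'   `list(virus = ..., bacterium = ..., clinical = ...)`
#' @param min_complete minimum number of complete observation pairs
#'   (default 5)
#' @param include_within include within-block pairs (default `TRUE`;
#'   within-block pairs are excluded from clinical summaries downstream
#'   regardless)
#' @return `data.frame`: `node_a`, `node_b`, `class_a`, `class_b`,
#'   `rho`, `p`
#' @export
spearman_all_pairs <- function(blocks, min_complete = 5,
                               include_within = TRUE) {
  stopifnot(is.list(blocks), !is.null(names(blocks)))
  rn <- rownames(blocks[[1]])
  for (b in blocks) {
    if (!identical(rownames(b), rn)) {
      stop("all blocks must share identical sample rownames", call. = FALSE)
    }
  }
  M <- do.call(cbind, lapply(blocks, as.matrix))
  classes <- rep(names(blocks), vapply(blocks, ncol, integer(1)))
  ids <- unlist(lapply(blocks, colnames), use.names = FALSE)
  if (anyDuplicated(ids)) stop("variable ids must be unique across blocks",
                               call. = FALSE)
  p_all <- ncol(M)
  # midranks per column (complete data; NA handled pairwise below only if
  # present)
  has_na <- anyNA(M)
  R <- apply(M, 2, rank, ties.method = "average")
  const <- apply(M, 2, function(v) length(unique(v[!is.na(v)])) <= 1)
  out <- vector("list", p_all * (p_all - 1) / 2)
  skipped <- 0L
  idx <- 0L
  n <- nrow(M)
  Rc <- scale(R, center = TRUE, scale = FALSE)
  ss <- colSums(Rc^2)
  for (i in seq_len(p_all - 1)) {
    for (j in (i + 1):p_all) {
      if (!include_within && classes[i] == classes[j]) next
      idx <- idx + 1L
      if (const[i] || const[j]) {
        skipped <- skipped + 1L
        next
      }
      if (has_na) {
        cc <- complete.cases(M[, i], M[, j])
        if (sum(cc) < min_complete) {
          skipped <- skipped + 1L
          next
        }
        rho <- spearman_rho(M[cc, i], M[cc, j])
        nn <- sum(cc)
      } else {
        if (n < min_complete) {
          skipped <- skipped + 1L
          next
        }
        rho <- sum(Rc[, i] * Rc[, j]) / sqrt(ss[i] * ss[j])
        nn <- n
      }
      tstat <- rho * sqrt((nn - 2) / max(1 - rho^2, 1e-12))
      pval <- 2 * pt(-abs(tstat), df = nn - 2)
      out[[idx]] <- data.frame(node_a = ids[i], node_b = ids[j],
                               class_a = classes[i], class_b = classes[j],
                               rho = rho, p = pval,
                               stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0) {
    message(sprintf("%d pair(s) skipped (constant vector or < %d complete pairs)",
                    skipped, min_complete))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(node_a = character(0), node_b = character(0),
                      class_a = character(0), class_b = character(0),
                      rho = numeric(0), p = numeric(0))
  }
  rownames(res) <- NULL
  res
}

#' Build a thresholded signed correlation graph
#'
#' BH adjustment is applied jointly over all supplied pairs; an edge is
#' kept iff `|rho| > rho_min` and `q < q_max`. Node annotations
#' (class, optional taxon/family labels) are attached.
#'
#' @param correlations output of [spearman_all_pairs()]
#' @param rho_min absolute correlation threshold (default 0.4)
#' @param q_max BH-q threshold (default 0.05)
#' @param annotations optional `data.frame` with columns `id` and
#'   `annotation`
#' @return list of class `ck_graph`: `nodes` (`id`, `class`,
#'   `annotation`), `edges` (`node_a`, `node_b`, `rho`, `q`, `sign`),
#'   `thresholds`
#' @export
build_graph <- function(correlations, rho_min = 0.4, q_max = 0.05,
                        annotations = NULL) {
  cr <- correlations
  cr$q <- bh_adjust(cr$p)
  keep <- !is.na(cr$rho) & abs(cr$rho) > rho_min & !is.na(cr$q) &
    cr$q < q_max
  edges <- cr[keep, c("node_a", "node_b", "rho", "q"), drop = FALSE]
  edges$sign <- ifelse(edges$rho > 0, 1L, -1L)
  rownames(edges) <- NULL
  node_ids <- unique(c(cr$node_a, cr$node_b))
  node_cls <- c(setNames(cr$class_a, cr$node_a),
                setNames(cr$class_b, cr$node_b))
  nodes <- data.frame(id = node_ids, class = node_cls[node_ids],
                      annotation = NA_character_,
                      row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    nodes$annotation <- annotations$annotation[match(nodes$id,
                                                     annotations$id)]
  }
  structure(list(nodes = nodes, edges = edges,
                 thresholds = c(rho_min = rho_min, q_max = q_max)),
            class = "ck_graph")
}

#' @export
print.ck_graph <- function(x, ...) {
  cat(sprintf("ck_graph: %d candidate nodes, %d edges (|rho| > %.2f, q < %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$thresholds["rho_min"],
              x$thresholds["q_max"]))
  invisible(x)
}

# adjacency list over non-isolated nodes
.adjacency <- function(g) {
  ids <- sort(unique(c(g$edges$node_a, g$edges$node_b)))
  adj <- setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(g$edges))) {
    a <- g$edges$node_a[k]; b <- g$edges$node_b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# single-source BFS distances over an adjacency list (index-based)
.bfs_dists <- function(adj_idx, s, n) {
  dist <- rep(NA_integer_, n)
  dist[s] <- 0L
  queue <- s
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj_idx[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

#' Topology metrics of a correlation graph
#'
#' Average degree is `2E / N` over non-isolated nodes; average path
#' length is the unweighted shortest-path mean over connected pairs
#' (computed by breadth-first search within components); isolated
#' candidate nodes are excluded throughout.
#'
#' @param g a `ck_graph`
#' @return list of class `topology_report`: `n_nodes`, `n_edges`,
#'   `average_degree`, `average_path_length`, `n_components`,
#'   `n_positive`, `n_negative`
#' @export
topology <- function(g) {
  stopifnot(inherits(g, "ck_graph"))
  E <- nrow(g$edges)
  if (E == 0) {
    warning("empty graph: all-zero topology report")
    return(structure(list(n_nodes = 0L, n_edges = 0L, average_degree = 0,
                          average_path_length = 0, n_components = 0L,
                          n_positive = 0L, n_negative = 0L),
                     class = "topology_report"))
  }
  adj <- .adjacency(g)
  ids <- names(adj)
  n <- length(ids)
  adj_idx <- lapply(adj, function(v) match(v, ids))
  tot <- 0; npairs <- 0L
  comp <- rep(NA_integer_, n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    d <- .bfs_dists(adj_idx, s, n)
    reach <- which(!is.na(d) & d > 0)
    tot <- tot + sum(d[reach])
    npairs <- npairs + length(reach)
    if (is.na(comp[s])) {
      ncomp <- ncomp + 1L
      comp[!is.na(d)] <- ncomp
    }
  }
  structure(list(
    n_nodes = n, n_edges = E, average_degree = 2 * E / n,
    average_path_length = if (npairs > 0) tot / npairs else 0,
    n_components = ncomp,
    n_positive = sum(g$edges$sign > 0), n_negative = sum(g$edges$sign < 0)
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(paste0("topology: %d nodes, %d edges (%d+/%d-), avg degree %.2f, ",
                     "avg path length %.2f, %d component(s)\n"),
              x$n_nodes, x$n_edges, x$n_positive, x$n_negative,
              x$average_degree, x$average_path_length, x$n_components))
  invisible(x)
}

#' Highest-degree nodes of a graph
#'
#' @param g a `ck_graph`
#' @param top_k number of nodes to return (default 20; clamped to the
#'   number of non-isolated nodes)
#' @return `data.frame` with `node`, `class`, `degree`, sorted by
#'   descending degree then node id
#' @export
hub_ranking <- function(g, top_k = 20) {
  stopifnot(inherits(g, "ck_graph"))
  if (nrow(g$edges) == 0) {
    return(data.frame(node = character(0), class = character(0),
                      degree = integer(0)))
  }
  deg <- table(c(g$edges$node_a, g$edges$node_b))
  out <- data.frame(node = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out$class <- g$nodes$class[match(out$node, g$nodes$id)]
  out <- out[order(-out$degree, out$node), c("node", "class", "degree")]
  rownames(out) <- NULL
  head(out, top_k)
}

#' Side-by-side comparison of two correlation graphs
#'
#' Requires both graphs to have been built with identical thresholds.
#' Reports topology for each, per-metric differences (A minus B), and
#' the positive/negative counts of edges incident to clinical nodes in
#' each graph.
#'
#' @param g_a,g_b `ck_graph`s built with identical thresholds
#' @return list: `topology_a`, `topology_b`, `differences` (named
#'   numeric), `clinical_edge_signs` (2 x 2 counts)
#' @export
compare_networks <- function(g_a, g_b) {
  stopifnot(inherits(g_a, "ck_graph"), inherits(g_b, "ck_graph"))
  if (!isTRUE(all.equal(g_a$thresholds, g_b$thresholds))) {
    stop("graphs were built with different thresholds", call. = FALSE)
  }
  ta <- topology(g_a); tb <- topology(g_b)
  metrics <- c("n_nodes", "n_edges", "average_degree",
               "average_path_length", "n_components")
  diffs <- setNames(vapply(metrics, function(m) {
    as.numeric(ta[[m]]) - as.numeric(tb[[m]])
  }, numeric(1)), metrics)
  clin_signs <- function(g) {
    clin <- g$nodes$id[g$nodes$class == "clinical"]
    e <- g$edges[g$edges$node_a %in% clin | g$edges$node_b %in% clin, ]
    c(positive = sum(e$sign > 0), negative = sum(e$sign < 0))
  }
  list(topology_a = ta, topology_b = tb, differences = diffs,
       clinical_edge_signs = rbind(A = clin_signs(g_a), B = clin_signs(g_b)))
}
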