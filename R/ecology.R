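# Ecological statistics implemented from first principles: alpha
# diversity, sample-accumulation rarefaction, Bray-Curtis / Jaccard
# distances, principal coordinates analysis (Gower centering) and
# permutation-based PERMANOVA.

#' Per-sample alpha diversity
#'
#' Observed richness (presence count), Shannon index (natural log) and
#' Simpson index (1 - sum p^2), computed on the renormalized
#' relative-abundance rows.
#'
#' @param m an [abundance_matrix()]
#' @return `data.frame` with columns `sample_id`, `observed`, `shannon`,
#'   `simpson`
#' @export
alpha_diversity <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  v <- m$values
  observed <- rowSums(m$presence)
  shannon <- apply(v, 1, function(p) {
    p <- p[p > 0]
    if (length(p) == 0) 0 else -sum(p * log(p))
  })
  simpson <- apply(v, 1, function(p) {
    if (sum(p) == 0) 0 else 1 - sum(p^2)
  })
  empty <- rowSums(v) == 0
  if (any(empty)) warning(sprintf("%d empty sample(s): diversity set to 0",
                                  sum(empty)))
  data.frame(sample_id = sample_ids(m), observed = observed,
             shannon = shannon, simpson = simpson, row.names = NULL)
}

#' Sample-accumulation rarefaction curve
#'
#' Expected cumulative richness (number of distinct present features) as
#' samples are added in random order. The exact curve uses the
#' hypergeometric closed form
#' \eqn{E[S_k] = \sum_f 1 - \binom{n-m_f}{k} / \binom{n}{k}}
#' where \eqn{m_f} is the number of samples containing feature f; the
#' Monte-Carlo curve averages over `n_orders` random orderings.
#'
#' @param m an [abundance_matrix()]
#' @param group_mask logical or index vector selecting the sample group
#' @param n_orders number of random orderings (Monte-Carlo mode)
#' @param seed RNG seed for the orderings
#' @param exact if `TRUE`, use the closed form (no RNG)
#' @return `data.frame` with columns `k` (samples drawn) and `richness`
#' @export
rarefaction_curve <- function(m, group_mask = NULL, n_orders = 30,
                              seed = 1, exact = FALSE) {
  stopifnot(inherits(m, "abundance_matrix"))
  group_mask <- group_mask %||% rep(TRUE, nrow(m$values))
  pres <- m$presence[group_mask, , drop = FALSE]
  n <- nrow(pres)
  if (n < 1) stop("group must contain at least one sample", call. = FALSE)
  if (exact) {
    mf <- colSums(pres)
    rich <- sapply(seq_len(n), function(k) {
      sum(1 - exp(lchoose(n - mf, k) - lchoose(n, k)))
    })
  } else {
    rich <- with_seed(seed, {
      acc <- matrix(0, n_orders, n)
      for (o in seq_len(n_orders)) {
        ord <- sample.int(n)
        seen <- rep(FALSE, ncol(pres))
        for (k in seq_len(n)) {
          seen <- seen | pres[ord[k], ]
          acc[o, k] <- sum(seen)
        }
      }
      colMeans(acc)
    })
  }
  data.frame(k = seq_len(n), richness = rich)
}

#' Pairwise dissimilarity matrix
#'
#' Bray-Curtis (`sum |x - y| / sum (x + y)`) on abundances or Jaccard
#' (`1 - |intersection| / |union|`) on the presence mask. A pair of
#' all-zero samples gets distance 0 by convention.
#'
#' @param m an [abundance_matrix()]
#' @param metric `"bray_curtis"` or `"jaccard"`
#' @return symmetric numeric matrix with zero diagonal and attribute
#'   `metric`
#' @export
distance_matrix <- function(m, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  stopifnot(inherits(m, "abundance_matrix"))
  n <- nrow(m$values)
  d <- matrix(0, n, n, dimnames = list(sample_ids(m), sample_ids(m)))
  if (metric == "bray_curtis") {
    v <- m$values
    for (i in seq_len(n - 1)) {
      xi <- v[i, ]
      for (j in (i + 1):n) {
        denom <- sum(xi + v[j, ])
        d[i, j] <- d[j, i] <- if (denom == 0) 0 else
          sum(abs(xi - v[j, ])) / denom
      }
    }
  } else {
    p <- m$presence
    for (i in seq_len(n - 1)) {
      xi <- p[i, ]
      for (j in (i + 1):n) {
        un <- sum(xi | p[j, ])
        d[i, j] <- d[j, i] <- if (un == 0) 0 else
          1 - sum(xi & p[j, ]) / un
      }
    }
  }
  if (any(rowSums(m$values) == 0)) {
    message("all-zero sample(s) present: their pairwise distances follow ",
            "the zero convention")
  }
  attr(d, "metric") <- metric
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-d^2 / 2` followed by a symmetric
#' eigendecomposition. Coordinates are returned for positive eigenvalues
#' only (eigenvector scaled by the square root of its eigenvalue);
#' negative eigenvalues are reported but not corrected. Percent explained
#' is computed over the positive eigenvalues and sums to 100.
#'
#' @param d symmetric distance matrix (from [distance_matrix()])
#' @return list of class `ordination_result`: `coordinates` (samples x
#'   axes), `eigenvalues`, `pct_explained`
#' @export
pcoa <- function(d) {
  n <- nrow(d)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  a <- -0.5 * d^2
  rc <- rowMeans(a)
  b <- a - outer(rc, rep(1, n)) - outer(rep(1, n), rc) + mean(a)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCoA", seq_len(ncol(coords)))
  structure(list(
    coordinates = coords,
    eigenvalues = e$values,
    pct_explained = 100 * e$values[pos] / sum(e$values[pos])
  ), class = "ordination_result")
}

# pseudo-F and R2 from squared distances (distance-based one-way layout):
# SST = sum_{i<j} d2/n, SSW = sum_g sum_{i<j in g} d2/n_g
.permanova_stats <- function(d2, labels) {
  n <- nrow(d2)
  sst <- sum(d2) / (2 * n)
  groups <- unique(labels)
  ssw <- 0
  for (g in groups) {
    idx <- which(labels == g)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssa <- sst - ssw
  a <- length(groups)
  f <- (ssa / (a - 1)) / (ssw / (n - a))
  c(F = f, R2 = ssa / sst)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way distance-based pseudo-F test. The null distribution is built
#' by shuffling sample labels; the p-value uses the +1 correction,
#' `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`, so p is never 0.
#'
#' @param d symmetric distance matrix
#' @param labels group label per sample (length `nrow(d)`)
#' @param n_perm number of permutations (default 9999)
#' @param seed RNG seed for the permutations
#' @return list of class `permanova_result`: `pseudo_F`, `R2`, `p`,
#'   `n_permutations`
#' @export
permanova <- function(d, labels, n_perm = 9999, seed = 1) {
  labels <- as.character(labels)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2) {
    stop("PERMANOVA needs at least 2 groups", call. = FALSE)
  }
  d2 <- d^2
  obs <- .permanova_stats(d2, labels)
  count <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(labels)
      if (.permanova_stats(d2, perm)[["F"]] >= obs[["F"]]) cnt <- cnt + 1L
    }
    cnt
  })
  structure(list(
    pseudo_F = obs[["F"]], R2 = obs[["R2"]],
    p = (count + 1) / (n_perm + 1), n_permutations = n_perm
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p, x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA over all unordered group pairs
#'
#' Each pair is tested on its sub-matrix; p-values are Benjamini-Hochberg
#' adjusted over the set of pairs.
#'
#' @inheritParams permanova
#' @return `data.frame` with one row per pair: `group_a`, `group_b`,
#'   `pseudo_F`, `R2`, `p`, `q_bh`
#' @export
pairwise_permanova <- function(d, labels, n_perm = 999, seed = 1) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  pairs <- combn(groups, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    idx <- labels %in% c(ga, gb)
    r <- permanova(d[idx, idx, drop = FALSE], labels[idx],
                   n_perm = n_perm, seed = seed + k)
    data.frame(group_a = ga, group_b = gb, pseudo_F = r$pseudo_F,
               R2 = r$R2, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_bh <- bh_adjust(out$p)
  out
}
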