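# Differential-feature selection between two groups: Wilcoxon rank-sum
# (exact by enumeration for small tie-free samples, otherwise normal
# approximation with tie and continuity corrections), Benjamini-Hochberg
# FDR, fold-change and abundance filters, covariate-adjusted linear-model
# validation, Fisher occurrence tests for KO carriage, and descriptive
# host/family/lifestyle summaries.

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact p-value by enumeration of all label assignments when the pooled
#' sample size is at most 12 and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction. The
#' statistic is the rank sum W of `x`.
#'
#' @param x,y numeric vectors (each non-empty)
#' @param exact force the exact (`TRUE`) or approximate (`FALSE`) path;
#'   default `NULL` selects exact for tie-free pooled samples of size
#'   at most 12
#' @return list with `statistic` (rank sum of `x`) and `p` (two-sided)
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx < 1 || ny < 1) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = sum(rank(pooled)[seq_len(nx)]), p = 1))
  }
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  ties <- any(duplicated(pooled))
  use_exact <- exact %||% (n <= 12 && !ties)
  if (use_exact && ties) stop("exact p requires tie-free data", call. = FALSE)
  if (use_exact) {
    # enumerate all C(n, nx) assignments of ranks to group x
    combs <- combn(n, nx)
    ws <- colSums(matrix(r[combs], nrow = nx))
    ew <- nx * (n + 1) / 2
    p <- mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-12)
  } else {
    ew <- nx * (n + 1) / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / ((n) * (n - 1))
    vw <- nx * ny / 12 * ((n + 1) - tie_term)
    z <- (abs(w_obs - ew) - 0.5) / sqrt(vw)
    p <- min(1, 2 * pnorm(-max(z, 0)))
  }
  list(statistic = w_obs, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#' Order-preserving; `NA`s propagate and are excluded from `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]`
#' @return vector of adjusted q-values, same order as `p`
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  bh_step_up(p)
}

#' Pseudo-count fold change
#'
#' `(mean_a + eps) / (mean_b + eps)`: finite for zero means, negligible
#' effect otherwise. Vectorized.
#'
#' @param mean_a,mean_b non-negative group means
#' @param epsilon pseudo-count (default 1e-8, small relative to the
#'   abundance filter)
#' @return fold-change ratio(s)
#' @export
fold_change <- function(mean_a, mean_b, epsilon = 1e-8) {
  if (any(mean_a < 0) || any(mean_b < 0)) {
    stop("means must be non-negative", call. = FALSE)
  }
  (mean_a + epsilon) / (mean_b + epsilon)
}

#' Select differentially abundant features between two groups
#'
#' Per feature: Wilcoxon rank-sum p across all tested features, BH
#' adjustment, then a direction is assigned only when all three filters
#' pass: `q < q_max`, fold change beyond `fc_min` (either side), and
#' overall mean relative abundance above `abund_min`.
#'
#' @param m an [abundance_matrix()]
#' @param meta metadata `data.frame` with rownames matching sample ids
#' @param group_col metadata column holding exactly two group labels
#' @param fc_min minimum fold change (default 1.2)
#' @param q_max BH-q threshold (default 0.05)
#' @param abund_min minimum overall mean relative abundance (default
#'   1e-4, i.e. 0.01%)
#' @return `data.frame` of class `differential_table`: `feature_id`,
#'   `mean_a`, `mean_b`, `fold_change`, `p_raw`, `q_bh`, `direction`
#'   (`"<groupA>-enriched"`, `"<groupB>-enriched"` or `"ns"`),
#'   `validated` (`NA` until [covariate_validate()] is run). Attribute
#'   `groups` records the (A, B) label order.
#' @export
select_differential <- function(m, meta, group_col = "group",
                                fc_min = 1.2, q_max = 0.05,
                                abund_min = 1e-4) {
  stopifnot(inherits(m, "abundance_matrix"))
  g <- as.character(meta[sample_ids(m), group_col])
  groups <- sort(unique(g))
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  ia <- g == groups[1]; ib <- g == groups[2]
  if (sum(ia) < 3 || sum(ib) < 3) {
    warning("a group has fewer than 3 samples; tests are underpowered")
  }
  v <- m$values
  mean_a <- colMeans(v[ia, , drop = FALSE])
  mean_b <- colMeans(v[ib, , drop = FALSE])
  p_raw <- vapply(seq_len(ncol(v)), function(j) {
    wilcoxon_rank_sum(v[ia, j], v[ib, j])$p
  }, numeric(1))
  q <- bh_adjust(p_raw)
  fc <- fold_change(mean_a, mean_b)
  overall <- colMeans(v)
  dir <- rep("ns", ncol(v))
  sig <- !is.na(q) & q < q_max & overall > abund_min
  dir[sig & fc > fc_min] <- paste0(groups[1], "-enriched")
  dir[sig & fc < 1 / fc_min] <- paste0(groups[2], "-enriched")
  out <- data.frame(
    feature_id = feature_ids(m), mean_a = mean_a, mean_b = mean_b,
    fold_change = fc, p_raw = p_raw, q_bh = q, direction = dir,
    validated = NA, row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "groups") <- groups
  attr(out, "thresholds") <- c(fc_min = fc_min, q_max = q_max,
                               abund_min = abund_min)
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Validate differential features with covariate-adjusted linear models
#'
#' A simplified multivariable check: per feature, the total-sum-scaled
#' relative abundance is arcsine-square-root transformed and regressed by
#' ordinary least squares on the group indicator plus covariates. A
#' feature is `validated` when the group coefficient's BH-q (across
#' features) is below `q_max` and its sign agrees with the Wilcoxon
#' direction. Collinear covariates are dropped with a warning.
#'
#' @param m an [abundance_matrix()]
#' @param meta metadata with rownames matching sample ids
#' @param diff_table result of [select_differential()]
#' @param covariates metadata columns to adjust for
#' @param group_col metadata group column
#' @param q_max BH-q threshold for the group coefficient
#' @return the `differential_table` with `validated`, `lm_coef` and
#'   `lm_q` filled in
#' @export
covariate_validate <- function(m, meta, diff_table,
                               covariates = c("age", "sex", "BMI"),
                               group_col = "group", q_max = 0.05) {
  stopifnot(inherits(m, "abundance_matrix"),
            inherits(diff_table, "differential_table"))
  missing_cov <- setdiff(covariates, names(meta))
  if (length(missing_cov) > 0) {
    stop("covariate(s) not in metadata: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  groups <- attr(diff_table, "groups")
  g <- as.character(meta[sample_ids(m), group_col])
  df <- data.frame(.group = as.integer(g == groups[1]),
                   meta[sample_ids(m), covariates, drop = FALSE])
  mm <- stats::model.matrix(~ ., data = df)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    drop <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    warning("dropping collinear covariate column(s): ",
            paste(drop, collapse = ", "))
    mm <- mm[, qrm$pivot[seq_len(qrm$rank)], drop = FALSE]
  }
  y_all <- asin(sqrt(pmin(m$values, 1)))
  n <- nrow(mm); k <- ncol(mm)
  fit <- stats::lm.fit(mm, y_all)
  coefs <- fit$coefficients[".group", ]
  rss <- colSums(as.matrix(fit$residuals)^2)
  xtxi <- chol2inv(chol(crossprod(mm)))[which(colnames(mm) == ".group"),
                                        which(colnames(mm) == ".group")]
  se <- sqrt(rss / (n - k) * xtxi)
  tstat <- ifelse(se > 0, coefs / se, 0)
  p_lm <- 2 * pt(-abs(tstat), df = n - k)
  p_lm[se == 0] <- 1  # zero-variance features
  q_lm <- bh_adjust(p_lm)
  ord <- match(diff_table$feature_id, feature_ids(m))
  diff_table$lm_coef <- coefs[ord]
  diff_table$lm_q <- q_lm[ord]
  wilc_sign <- ifelse(diff_table$direction == paste0(groups[1], "-enriched"), 1,
                      ifelse(diff_table$direction == paste0(groups[2], "-enriched"),
                             -1, 0))
  diff_table$validated <- !is.na(diff_table$lm_q) &
    diff_table$lm_q < q_max &
    wilc_sign != 0 & sign(diff_table$lm_coef) == wilc_sign
  diff_table
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p by hypergeometric enumeration over all tables with the
#' observed margins; two-sided p sums the probabilities of tables no more
#' probable than the observed one (with a small relative tolerance).
#'
#' @param a,b,c,d cell counts: rows are groups, columns carrier / non-carrier
#' @return two-sided p-value
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative", call. = FALSE)
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  xs <- lo:hi
  probs <- dhyper(xs, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Fisher occurrence tests for KO carriage between enriched feature sets
#'
#' For each KEGG ortholog (KO) occurring in either set's catalog
#' annotations, a 2x2 table of carriage among group-A-enriched versus
#' group-B-enriched vOTUs is tested with the two-sided Fisher exact
#' test. BH adjustment spans all tested KOs; the returned table keeps
#' only KOs with occurrence rate above `min_rate` in at least one set and
#' `q < q_max`.
#'
#' @param enriched_a,enriched_b disjoint character vectors of vOTU ids
#' @param cat a vOTU catalog with `ko_set` list-column
#' @param min_rate minimum occurrence rate (default 0.05)
#' @param q_max BH-q threshold (default 0.01)
#' @return `data.frame`: `ko_id`, `count_a`, `n_a`, `count_b`, `n_b`,
#'   `p_fisher`, `q_bh`, `enriched_in`. Attribute `n_tested` records the
#'   BH family size; attribute `direction_counts` the unfiltered counts
#'   of KOs more frequent in each set.
#' @export
amg_occurrence_test <- function(enriched_a, enriched_b, cat,
                                min_rate = 0.05, q_max = 0.01) {
  if (length(enriched_a) == 0 || length(enriched_b) == 0) {
    stop("both enriched sets must be non-empty", call. = FALSE)
  }
  if (length(intersect(enriched_a, enriched_b)) > 0) {
    stop("enriched sets must be disjoint", call. = FALSE)
  }
  ko_a <- cat$ko_set[match(enriched_a, cat$votu_id)]
  ko_b <- cat$ko_set[match(enriched_b, cat$votu_id)]
  n_a <- length(enriched_a); n_b <- length(enriched_b)
  kos <- sort(unique(c(unlist(ko_a), unlist(ko_b))))
  if (length(kos) == 0) {
    return(data.frame(ko_id = character(0), count_a = integer(0),
                      n_a = integer(0), count_b = integer(0),
                      n_b = integer(0), p_fisher = numeric(0),
                      q_bh = numeric(0), enriched_in = character(0)))
  }
  count_a <- vapply(kos, function(k) sum(vapply(ko_a, function(s) k %in% s,
                                                logical(1))), integer(1))
  count_b <- vapply(kos, function(k) sum(vapply(ko_b, function(s) k %in% s,
                                                logical(1))), integer(1))
  p <- mapply(function(ca, cb) {
    fisher_exact_2x2(ca, n_a - ca, cb, n_b - cb)
  }, count_a, count_b)
  q <- bh_adjust(p)
  rate_a <- count_a / n_a; rate_b <- count_b / n_b
  out <- data.frame(
    ko_id = kos, count_a = count_a, n_a = n_a, count_b = count_b,
    n_b = n_b, p_fisher = p, q_bh = q,
    enriched_in = ifelse(rate_a >= rate_b, "A", "B"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  keep <- (rate_a > min_rate | rate_b > min_rate) & !is.na(q) & q < q_max
  res <- out[keep, , drop = FALSE]
  attr(res, "n_tested") <- length(kos)
  attr(res, "direction_counts") <- c(A = sum(rate_a > rate_b),
                                     B = sum(rate_b > rate_a))
  res
}

#' Descriptive host / family / lifestyle summary of selected features
#'
#' Contingency counts of catalog annotations per enrichment direction for
#' the features selected by [select_differential()]. Missing annotations
#' are tallied under `"unknown"`. Descriptive only: no inference.
#'
#' @param diff_table a `differential_table`
#' @param cat a vOTU catalog
#' @return list of three `data.frame`s (`host_genus`, `family`,
#'   `lifestyle`), each with columns `label`, `direction`, `count`
#' @export
host_family_summary <- function(diff_table, cat) {
  stopifnot(inherits(diff_table, "differential_table"))
  sel <- diff_table[diff_table$direction != "ns", , drop = FALSE]
  idx <- match(sel$feature_id, cat$votu_id)
  tally <- function(lab) {
    lab[is.na(lab) | lab == "unassigned"] <- "unknown"
    if (nrow(sel) == 0) {
      return(data.frame(label = character(0), direction = character(0),
                        count = integer(0)))
    }
    tb <- as.data.frame(table(label = lab, direction = sel$direction),
                        stringsAsFactors = FALSE)
    names(tb)[3] <- "count"
    tb[tb$count > 0, , drop = FALSE]
  }
  list(host_genus = tally(cat$host_genus[idx]),
       family = tally(cat$family[idx]),
       lifestyle = tally(cat$lifestyle[idx]))
}
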