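# Severity-gradient analysis: cumulative abundance of feature sets across
# ordered severity strata and detection of features with monotone
# severity trajectories.

#' An ordered severity scale
#'
#' @param levels severity labels in increasing order of severity
#'   (default MAP < MSAP < SAP)
#' @return named integer ranks of class `severity_order`
#' @export
severity_order <- function(levels = c("MAP", "MSAP", "SAP")) {
  if (length(levels) < 2) stop("need at least 2 levels", call. = FALSE)
  structure(setNames(seq_along(levels), levels), class = "severity_order")
}

#' Cumulative abundance of a feature set per sample, grouped by severity
#'
#' @param m an [abundance_matrix()]
#' @param feature_set character vector of feature ids (non-empty, all
#'   present in `m`)
#' @param meta metadata with rownames matching sample ids and a
#'   `severity` column
#' @param order a [severity_order()]
#' @return `data.frame`: `sample_id`, `severity`, `rank`,
#'   `cum_abundance`; samples without a severity label are dropped
#' @export
cumulative_set_abundance <- function(m, feature_set, meta,
                                     order = severity_order()) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (length(feature_set) == 0) stop("empty feature set", call. = FALSE)
  missing <- setdiff(feature_set, feature_ids(m))
  if (length(missing) > 0) {
    stop("feature(s) not in matrix: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  cum <- rowSums(m$values[, feature_set, drop = FALSE])
  sev <- as.character(meta[sample_ids(m), "severity"])
  keep <- !is.na(sev) & sev %in% names(order)
  data.frame(sample_id = sample_ids(m)[keep], severity = sev[keep],
             rank = unclass(order)[sev[keep]], cum_abundance = cum[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect features with monotone severity trajectories
#'
#' A feature is called monotone when (a) its severity-group means are
#' strictly ordered (increasing or decreasing along the scale) and (b)
#' the Spearman trend of per-sample abundance against severity rank is
#' significant after BH adjustment across features. Direction comes from
#' the ordering of the means.
#'
#' @param m an [abundance_matrix()]
#' @param meta metadata with a `severity` column
#' @param order a [severity_order()]
#' @param q_max BH-q threshold on the trend test (default 0.05)
#' @return `data.frame`: `feature_id`, one `mean_<level>` column per
#'   severity level, `monotone_direction` (`increasing` / `decreasing` /
#'   `none`), `trend_rho`, `trend_q`
#' @export
detect_monotone <- function(m, meta, order = severity_order(),
                            q_max = 0.05) {
  stopifnot(inherits(m, "abundance_matrix"))
  sev <- as.character(meta[sample_ids(m), "severity"])
  keep <- !is.na(sev) & sev %in% names(order)
  lev_present <- intersect(names(order), unique(sev[keep]))
  if (length(lev_present) < length(order)) {
    warning("severity level(s) absent from data: ",
            paste(setdiff(names(order), lev_present), collapse = ", "),
            "; proceeding on available levels")
  }
  if (length(lev_present) < 2) {
    stop("need at least 2 severity levels with samples", call. = FALSE)
  }
  v <- m$values[keep, , drop = FALSE]
  ranks <- unclass(order)[sev[keep]]
  gm <- sapply(lev_present, function(l) {
    colMeans(v[sev[keep] == l, , drop = FALSE])
  })
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1, dimnames = list(feature_ids(m), lev_present))
  rho <- vapply(seq_len(ncol(v)), function(j) spearman_rho(v[, j], ranks),
                numeric(1))
  n <- nrow(v)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[is.na(rho)] <- NA
  q <- bh_adjust(p)
  inc <- apply(gm, 1, function(x) all(diff(x) > 0))
  dec <- apply(gm, 1, function(x) all(diff(x) < 0))
  dir <- rep("none", ncol(v))
  sig <- !is.na(q) & q < q_max
  dir[inc & sig & !is.na(rho) & rho > 0] <- "increasing"
  dir[dec & sig & !is.na(rho) & rho < 0] <- "decreasing"
  out <- data.frame(feature_id = feature_ids(m), stringsAsFactors = FALSE)
  for (l in lev_present) out[[paste0("mean_", l)]] <- gm[, l]
  out$monotone_direction <- dir
  out$trend_rho <- rho
  out$trend_q <- q
  out
}

#' Severity classifiers from monotone features
#'
#' Fits one random-forest model per severity stratum. The default
#' contrast is each severity versus the control group (`"vs_control"`);
#' `"one_vs_rest"` contrasts each severity against all other labelled
#' samples.
#'
#' @param m an [abundance_matrix()] covering cases and controls
#' @param meta metadata with `group` and `severity` columns
#' @param selected character vector of feature ids to use
#' @param spec a [cv_spec()]
#' @param contrast `"vs_control"` or `"one_vs_rest"`
#' @param control_label group label of the control samples
#' @param order a [severity_order()]
#' @param ks optional feature counts for a per-contrast
#'   [feature_count_curve()]
#' @return named list (one entry per severity level) of classifier
#'   reports; each has the severity's `report` and optionally `curve`
#' @export
severity_models <- function(m, meta, selected, spec,
                            contrast = c("vs_control", "one_vs_rest"),
                            control_label = "HC", order = severity_order(),
                            ks = NULL) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(m, "abundance_matrix"))
  sev <- as.character(meta[sample_ids(m), "severity"])
  grp <- as.character(meta[sample_ids(m), "group"])
  X <- m$values[, selected, drop = FALSE]
  out <- list()
  for (l in names(order)) {
    if (contrast == "vs_control") {
      idx <- which((!is.na(sev) & sev == l) | grp == control_label)
      y <- as.integer(!is.na(sev[idx]) & sev[idx] == l)
    } else {
      idx <- which(!is.na(sev))
      y <- as.integer(sev[idx] == l)
    }
    if (length(unique(y)) < 2) {
      warning("severity level ", l, " has a single class; skipped")
      next
    }
    rep_l <- cross_validated_auc(X[idx, , drop = FALSE], y, spec)
    entry <- list(report = rep_l)
    if (!is.null(ks)) {
      entry$curve <- feature_count_curve(X[idx, , drop = FALSE], y, spec, ks)
    }
    out[[l]] <- entry
  }
  out
}
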