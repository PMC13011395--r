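# Alignment -> abundance profiling: best-hit resolution, breadth-of-
# coverage presence calling, reads-per-kilobase quantification and
# taxonomic aggregation.

#' Resolve each read to its single best alignment
#'
#' Keeps exactly one record per (sample, read): the highest alignment
#' score, with ties broken by the lexicographically smallest vOTU id — a
#' deterministic, documented stand-in for an aligner's opaque internal
#' tie-breaking. Records with malformed coordinates (`start < 0` or
#' `start >= end`) are dropped with a warning.
#'
#' @param records `data.frame` of alignment records with columns
#'   `read_id`, `sample_id`, `votu_id`, `start`, `end`, `score`.
#' @return the filtered `data.frame`, one row per (sample, read).
#' @export
resolve_best_hits <- function(records) {
  req <- c("read_id", "sample_id", "votu_id", "start", "end", "score")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  bad <- records$start < 0 | records$start >= records$end
  if (any(bad)) {
    warning(sprintf("dropping %d record(s) with malformed coordinates",
                    sum(bad)))
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records) == 0) return(records)
  ord <- order(records$sample_id, records$read_id, -records$score,
               records$votu_id)
  records <- records[ord, , drop = FALSE]
  keep <- !duplicated(records[, c("sample_id", "read_id")])
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# total length of the union of [start, end) intervals, by sweep over
# sorted starts (no per-base arrays)
interval_union_length <- function(start, end) {
  if (length(start) == 0) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  # an interval opens a new merged run when it starts after the running max
  # end of everything before it
  run_end <- cummax(end)
  new_run <- c(TRUE, start[-1] > run_end[-length(run_end)])
  run_id <- cumsum(new_run)
  starts <- tapply(start, run_id, function(s) s[1])
  ends <- tapply(end, run_id, max)
  sum(ends - starts)
}

#' Breadth of genome coverage per (sample, vOTU)
#'
#' Breadth is the fraction of genome positions covered by at least one
#' best-hit read, computed by interval merging. Used as the presence
#' criterion (a vOTU is called present when breadth is at least 10% by
#' default).
#'
#' @param records best-hit-resolved alignment records
#' @param cat a vOTU catalog with `votu_id` and `genome_length`
#' @return `data.frame` with columns `sample_id`, `votu_id`, `n_reads`,
#'   `breadth` (in `[0, 1]`).
#' @export
compute_breadth <- function(records, cat) {
  unknown <- setdiff(unique(records$votu_id), cat$votu_id)
  if (length(unknown) > 0) {
    stop("unknown vOTU id(s) in alignments: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0) {
    return(data.frame(sample_id = character(0), votu_id = character(0),
                      n_reads = integer(0), breadth = numeric(0)))
  }
  key <- interaction(records$sample_id, records$votu_id, drop = TRUE)
  idx <- split(seq_len(nrow(records)), key)
  res <- lapply(idx, function(i) {
    cov <- interval_union_length(records$start[i], records$end[i])
    data.frame(sample_id = records$sample_id[i[1]],
               votu_id = records$votu_id[i[1]],
               n_reads = length(i), covered = cov,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  glen <- cat$genome_length[match(out$votu_id, cat$votu_id)]
  out$breadth <- pmin(out$covered / glen, 1)
  out$covered <- NULL
  rownames(out) <- NULL
  out
}

#' Quantify vOTU relative abundances from best-hit alignments
#'
#' For each sample, read counts of present vOTUs (coverage breadth at
#' least `breadth_threshold`) are normalized by genome length (reads per
#' kilobase, RPK), scaled by the sample's total mapped reads, and
#' renormalized so abundances sum to 1. vOTUs failing the breadth filter
#' are zeroed before renormalization.
#'
#' @param records best-hit-resolved alignment records
#' @param cat a vOTU catalog
#' @param breadth_threshold minimum coverage breadth for presence
#'   (default 0.10)
#' @param samples optional character vector fixing the sample set (so
#'   empty samples appear as zero rows)
#' @return an [abundance_matrix()] at vOTU level over all catalog vOTUs
#' @export
quantify <- function(records, cat, breadth_threshold = 0.10,
                     samples = NULL) {
  br <- compute_breadth(records, cat)
  samples <- samples %||% sort(unique(records$sample_id))
  vals <- matrix(0, length(samples), nrow(cat),
                 dimnames = list(samples, cat$votu_id))
  pres <- matrix(FALSE, length(samples), nrow(cat),
                 dimnames = list(samples, cat$votu_id))
  if (nrow(br) > 0) {
    i <- match(br$sample_id, samples)
    j <- match(br$votu_id, cat$votu_id)
    ok <- !is.na(i)
    glen <- cat$genome_length[j]
    total <- tapply(br$n_reads, br$sample_id, sum)[br$sample_id]
    rpk <- br$n_reads / (glen / 1000)
    present <- br$breadth >= breadth_threshold
    vals[cbind(i[ok & present], j[ok & present])] <-
      (rpk / total)[ok & present]
    pres[cbind(i[ok & present], j[ok & present])] <- TRUE
  }
  empty <- rowSums(vals) == 0
  if (any(empty)) {
    message(sprintf("%d sample(s) with no present vOTU: zero row(s)",
                    sum(empty)))
  }
  abundance_matrix(vals, pres, level = "votu")
}

#' Aggregate a vOTU-level matrix to family or host-genus level
#'
#' Values are summed within each label; vOTUs without an assignment are
#' pooled into `"Unclassified"`. Row sums are preserved exactly.
#'
#' @param m an [abundance_matrix()] at vOTU level
#' @param cat a vOTU catalog
#' @param level `"family"` or `"host_genus"`
#' @return an [abundance_matrix()] at the aggregated level
#' @export
aggregate_level <- function(m, cat, level = c("family", "host_genus")) {
  level <- match.arg(level)
  stopifnot(inherits(m, "abundance_matrix"))
  if (m$level != "votu") stop("`m` must be at vOTU level", call. = FALSE)
  lab <- cat[[level]][match(feature_ids(m), cat$votu_id)]
  lab[is.na(lab) | lab == "unassigned"] <- "Unclassified"
  groups <- sort(unique(lab))
  vals <- sapply(groups, function(g) {
    rowSums(m$values[, lab == g, drop = FALSE])
  })
  pres <- sapply(groups, function(g) {
    rowSums(m$presence[, lab == g, drop = FALSE]) > 0
  })
  if (is.null(dim(vals))) {  # single sample
    vals <- matrix(vals, nrow = 1, dimnames = list(sample_ids(m), groups))
    pres <- matrix(pres, nrow = 1, dimnames = list(sample_ids(m), groups))
  }
  out_level <- if (level == "family") "family" else "genus"
  abundance_matrix(vals, pres, level = out_level, renormalize = FALSE)
}

#' Per-feature occurrence rate
#'
#' Fraction of (selected) samples in which a feature is called present.
#'
#' @param m an [abundance_matrix()]
#' @param group_mask logical or index vector selecting samples; default
#'   all samples
#' @return named numeric vector of occurrence fractions in `[0, 1]`
#' @export
prevalence <- function(m, group_mask = NULL) {
  stopifnot(inherits(m, "abundance_matrix"))
  group_mask <- group_mask %||% rep(TRUE, nrow(m$values))
  sel <- m$presence[group_mask, , drop = FALSE]
  if (nrow(sel) == 0) stop("empty sample selection", call. = FALSE)
  colMeans(sel)
}
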