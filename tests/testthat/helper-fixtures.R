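# shared fixtures: all built in code, small enough for fast tests

small_cfg <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_ap = 20, n_hc = 25, n_votus = 60,
                   n_bacteria = 15, reads_per_sample = 2000, ...)
}

small_cohort <- function(seed = 1, ...) {
  cfg <- small_cfg(seed, ...)
  cat <- generate_catalog(cfg)
  c(list(cfg = cfg, cat = cat), generate_cohort(cfg, cat))
}

# an abundance matrix built directly from a values matrix
am <- function(values, ...) {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  abundance_matrix(values, ...)
}

# minimal catalog for profiling tests
toy_catalog <- function(ids, lengths, family = NULL, host_genus = NULL) {
  n <- length(ids)
  cat <- data.frame(
    votu_id = ids, genome_length = lengths,
    family = family %||% rep("unassigned", n),
    lifestyle = rep("unknown", n), completeness = rep(90, n),
    host_genus = host_genus %||% rep(NA_character_, n),
    host_family = rep(NA_character_, n), stringsAsFactors = FALSE
  )
  cat$ko_set <- replicate(n, character(0), simplify = FALSE)
  class(cat) <- c("votu_catalog", "data.frame")
  cat
}

aln_rec <- function(read_id, votu_id, start, end, score = 100,
                    sample_id = "s1") {
  data.frame(read_id = read_id, sample_id = sample_id, votu_id = votu_id,
             start = start, end = end, score = score,
             stringsAsFactors = FALSE)
}

# metadata frame keyed by rownames, as the analysis functions expect
toy_meta <- function(sample_ids, group, severity = NULL, ...) {
  meta <- data.frame(sample_id = sample_ids, group = group,
                     stringsAsFactors = FALSE, ...)
  meta$severity <- severity %||% NA_character_
  rownames(meta) <- sample_ids
  meta
}

# all permutations of 1..n (for exhaustive-order oracles; n <= 5)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

# brute-force per-base coverage bitmap (oracle for interval-merge breadth)
bitmap_breadth <- function(start, end, genome_length) {
  covered <- logical(genome_length)
  for (i in seq_along(start)) covered[(start[i] + 1):end[i]] <- TRUE
  sum(covered) / genome_length
}
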