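# Readers and writers for the package's plain-text interchange formats:
# catalog TSV, abundance TSV (with a `# level=` header), metadata TSV,
# alignments as minimal SAM or a 5-column TSV dialect, ground-truth JSON,
# and graph/topology outputs.

#' Write / read a vOTU catalog as TSV
#'
#' The `ko_set` list-column is serialized as a comma-separated string.
#'
#' @param cat a `votu_catalog`
#' @param path output file
#' @return `write_catalog`: `path`, invisibly. `read_catalog`: a
#'   `votu_catalog`.
#' @export
write_catalog <- function(cat, path) {
  out <- cat
  out$ko_set <- vapply(cat$ko_set, paste, character(1), collapse = ",")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  df$ko_set <- lapply(strsplit(ifelse(is.na(df$ko_set), "", df$ko_set), ","),
                      function(x) x[nzchar(x)])
  class(df) <- c("votu_catalog", "data.frame")
  df
}

#' Write / read an abundance matrix as TSV
#'
#' Samples in rows, features in columns. A comment header records the
#' aggregation level and whether rows were renormalized after presence
#' filtering; the presence mask is implied by non-zero values.
#'
#' @param m an [abundance_matrix()]
#' @param path output file
#' @export
write_abundance <- function(m, path) {
  stopifnot(inherits(m, "abundance_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# level=%s renormalized=TRUE", m$level), con)
  df <- data.frame(sample_id = sample_ids(m), m$values,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  header <- readLines(path, n = 1)
  level <- sub(".*level=(\\S+).*", "\\1", header)
  if (!grepl("^#", header)) level <- "votu"
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$sample_id
  abundance_matrix(vals, level = level, renormalize = FALSE)
}

#' Write / read sample metadata as TSV
#' @param meta metadata `data.frame` with a `sample_id` column or rownames
#' @param path output file
#' @export
write_metadata <- function(meta, path) {
  if (!"sample_id" %in% names(meta)) {
    meta <- cbind(sample_id = rownames(meta), meta)
  }
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  rownames(meta) <- meta$sample_id
  meta
}

#' Write / read alignment records as 5-column TSV (one file per sample)
#'
#' Columns: `read_id`, `votu_id`, `start`, `end` (0-based half-open),
#' `score`. The sample id is taken from the argument (writer) or, by
#' default, the file name (reader).
#'
#' @param records alignment records `data.frame`
#' @param dir output directory (one `<sample_id>.aln.tsv` per sample)
#' @export
write_alignments_tsv <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in unique(records$sample_id)) {
    sub <- records[records$sample_id == sid,
                   c("read_id", "votu_id", "start", "end", "score")]
    write.table(sub, file.path(dir, paste0(sid, ".aln.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_alignments_tsv
#' @param path a single `.aln.tsv` file
#' @param sample_id sample id; default derived from the file name
#' @export
read_alignments_tsv <- function(path, sample_id = NULL) {
  sid <- sample_id %||% sub("\\.aln\\.tsv$", "", basename(path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  data.frame(read_id = df$read_id, sample_id = sid, votu_id = df$votu_id,
             start = df$start, end = df$end, score = df$score,
             stringsAsFactors = FALSE)
}

#' Write / read alignments as minimal SAM
#'
#' The writer emits `@HD`/`@SQ` headers from the catalog genome lengths
#' and one primary-mapped line per record (1-based POS, `<len>M` CIGAR,
#' alignment score in the `AS:i:` tag). The reader converts SAM's 1-based
#' closed coordinates back to the package's 0-based half-open convention;
#' it requires the Rsamtools package.
#'
#' @param records alignment records for one or more samples
#' @param cat the vOTU catalog (for `@SQ` lengths)
#' @param dir output directory (one `<sample_id>.sam` per sample)
#' @export
write_alignments_sam <- function(records, cat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in unique(records$sample_id)) {
    sub <- records[records$sample_id == sid, , drop = FALSE]
    used <- sort(unique(sub$votu_id))
    glen <- cat$genome_length[match(used, cat$votu_id)]
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", used, glen))
    len <- sub$end - sub$start
    # SEQ/QUAL omitted ("*"): only coordinates and scores matter here
    body <- sprintf("%s\t0\t%s\t%d\t42\t%dM\t*\t0\t0\t*\t*\tAS:i:%d",
                    sub$read_id, sub$votu_id, sub$start + 1L, len,
                    as.integer(sub$score))
    writeLines(c(hdr, body), file.path(dir, paste0(sid, ".sam")))
  }
  invisible(dir)
}

#' @rdname write_alignments_sam
#' @param path a single `.sam` file
#' @param sample_id sample id; default derived from the file name
#' @export
read_alignments_sam <- function(path, sample_id = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading SAM requires the Rsamtools package", call. = FALSE)
  }
  sid <- sample_id %||% sub("\\.sam$", "", basename(path))
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  par <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "qwidth", "cigar"), tag = "AS")
  x <- Rsamtools::scanBam(bam, param = par)[[1]]
  width <- as.integer(sub("M.*", "", x$cigar))
  data.frame(
    read_id = x$qname, sample_id = sid, votu_id = as.character(x$rname),
    start = x$pos - 1L, end = x$pos - 1L + width,
    score = as.numeric(x$tag$AS %||% rep(NA_real_, length(x$qname))),
    stringsAsFactors = FALSE
  )
}

#' Write / read ground truth as JSON
#' @param truth ground-truth list from [generate_cohort()]
#' @param path output file
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(
    differential_votus = as.list(truth$differential_votus),
    monotone_votus = as.list(truth$monotone_votus),
    planted_edges = truth$planted_edges
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(differential_votus = unlist(x$differential_votus) %||%
         setNames(character(0), character(0)),
       monotone_votus = unlist(x$monotone_votus) %||%
         setNames(character(0), character(0)),
       planted_edges = as.data.frame(x$planted_edges))
}

#' Write a correlation graph as edge-list TSV and GraphML
#'
#' @param g a `ck_graph`
#' @param prefix output path prefix; writes `<prefix>.edges.tsv`,
#'   `<prefix>.nodes.tsv` and `<prefix>.graphml`
#' @export
write_graph <- function(g, prefix) {
  stopifnot(inherits(g, "ck_graph"))
  write.table(g$edges, paste0(prefix, ".edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(g$nodes, paste0(prefix, ".nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  con <- file(paste0(prefix, ".graphml"), "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="class" for="node" attr.name="class" attr.type="string"/>',
    '  <key id="rho" for="edge" attr.name="rho" attr.type="double"/>',
    '  <graph edgedefault="undirected">'
  ), con)
  writeLines(sprintf('    <node id="%s"><data key="class">%s</data></node>',
                     g$nodes$id, g$nodes$class), con)
  if (nrow(g$edges) > 0) {
    writeLines(sprintf(
      '    <edge source="%s" target="%s"><data key="rho">%g</data></edge>',
      g$edges$node_a, g$edges$node_b, g$edges$rho), con)
  }
  writeLines(c("  </graph>", "</graphml>"), con)
  invisible(prefix)
}

#' Write a topology report as JSON
#' @param report a `topology_report`
#' @param path output file
#' @export
write_topology <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
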