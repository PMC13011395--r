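# Synthetic cohort generator: catalogs, abundance tables, alignments,
# metadata and ground truth with the statistical structure the downstream
# analyses assume (planted differential features, severity gradients, and
# cross-kingdom correlation edges).

# Viral families recurrently reported in human gut viromes; used to label
# the taxonomically assigned minority of vOTUs.
.VAP_FAMILIES <- c(
  "Microviridae", "Winoviridae", "Peduoviridae", "Guelinviridae",
  "Retroviridae", "Herelleviridae", "Phycodnaviridae", "Casjensviridae",
  "Siphoviridae", "Myoviridae"
)

# Candidate bacterial host genera (commensals and pathobionts) and their
# families, for host-prediction metadata.
.VAP_HOSTS <- data.frame(
  genus = c("Parabacteroides", "Escherichia", "Bacteroides", "Faecalicatena",
            "Faecalibacterium", "Blautia_A", "Roseburia", "Enterococcus",
            "Klebsiella", "Ruminococcus", "Veillonella", "Clostridium"),
  family = c("Tannerellaceae", "Enterobacteriaceae", "Bacteroidaceae",
             "Lachnospiraceae", "Ruminococcaceae", "Lachnospiraceae",
             "Lachnospiraceae", "Enterococcaceae", "Enterobacteriaceae",
             "Ruminococcaceae", "Veillonellaceae", "Clostridiaceae"),
  stringsAsFactors = FALSE
)

# Clinical biochemical analytes carried in the metadata (inflammatory,
# hepatobiliary and metabolic panels). Values are generated standardized
# (zero mean, unit variance); only rank structure matters downstream.
.VAP_CLINICAL <- c("WBC", "NEUT_pct", "ALT", "AST", "GGT", "ALP",
                   "TB", "DB", "CHOL", "TG", "GLU")

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the emulated cohort: 82 cases (AP) and 115 controls
#' (HC), severity strata MAP/MSAP/SAP in 38:25:19 proportion, roughly 85%
#' of vOTUs without family assignment, log-normal abundances with
#' independent zero-inflation, and planted differential / monotone /
#' correlation structure.
#'
#' @param seed integer seed; equal seeds give bit-identical output.
#' @param n_ap,n_hc number of case (AP) and control (HC) samples.
#' @param n_votus,n_bacteria,n_clinical numbers of viral features,
#'   bacterial taxa and clinical variables.
#' @param frac_differential fraction of vOTUs with a planted group effect.
#' @param planted_log2fc planted between-group log2 fold change (> 0);
#'   also sets the total severity-gradient span for monotone features.
#' @param frac_monotone fraction of vOTUs with a planted monotone severity
#'   trajectory (drawn from the differential set first).
#' @param sparsity per-cell probability of a structural zero.
#' @param dispersion log-normal sigma of per-sample abundance noise.
#' @param n_planted_edges number of planted cross-kingdom correlation
#'   edges (split between virus-bacterium and feature-clinical pairs).
#' @param planted_edge_rho target Spearman correlation of planted edges,
#'   in (0, 1).
#' @param unassigned_family_frac fraction of vOTUs left without a family.
#' @param reads_per_sample sequencing depth used by [generate_alignments()].
#' @param tie_frac fraction of reads given a tied secondary alignment.
#' @param read_length simulated read length in bp.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed,
                             n_ap = 82L, n_hc = 115L,
                             n_votus = 300L, n_bacteria = 40L,
                             n_clinical = 11L,
                             frac_differential = 0.2,
                             planted_log2fc = 2,
                             frac_monotone = 0.06,
                             sparsity = 0.2,
                             dispersion = 0.7,
                             n_planted_edges = 20L,
                             planted_edge_rho = 0.7,
                             unassigned_family_frac = 0.85,
                             reads_per_sample = 20000L,
                             tie_frac = 0.05,
                             read_length = 100L) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot_scalar_count(n_ap, "n_ap")
  stopifnot_scalar_count(n_hc, "n_hc")
  stopifnot_scalar_count(n_votus, "n_votus")
  stopifnot_scalar_count(n_bacteria, "n_bacteria")
  stopifnot_scalar_count(n_clinical, "n_clinical")
  stopifnot_proportion(frac_differential, "frac_differential")
  stopifnot_proportion(frac_monotone, "frac_monotone")
  stopifnot_proportion(sparsity, "sparsity")
  stopifnot_proportion(unassigned_family_frac, "unassigned_family_frac")
  stopifnot_proportion(tie_frac, "tie_frac")
  if (planted_log2fc <= 0) stop("`planted_log2fc` must be > 0", call. = FALSE)
  if (dispersion <= 0) stop("`dispersion` must be > 0", call. = FALSE)
  if (planted_edge_rho <= 0 || planted_edge_rho >= 1) {
    stop("`planted_edge_rho` must be in (0, 1)", call. = FALSE)
  }
  cfg <- list(
    seed = as.integer(seed), n_ap = as.integer(n_ap), n_hc = as.integer(n_hc),
    n_votus = as.integer(n_votus), n_bacteria = as.integer(n_bacteria),
    n_clinical = as.integer(n_clinical),
    frac_differential = frac_differential, planted_log2fc = planted_log2fc,
    frac_monotone = frac_monotone, sparsity = sparsity,
    dispersion = dispersion, n_planted_edges = as.integer(n_planted_edges),
    planted_edge_rho = planted_edge_rho,
    unassigned_family_frac = unassigned_family_frac,
    reads_per_sample = as.integer(reads_per_sample),
    tie_frac = tie_frac, read_length = as.integer(read_length)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic vOTU catalog
#'
#' Genome lengths are log-uniform on [2,000, 100,000] bp (viral genomes
#' span orders of magnitude); most entries carry no family assignment;
#' each vOTU carries 0-20 KEGG ortholog (KO) identifiers, a lifestyle
#' label and, for about 60% of entries, a predicted bacterial host genus.
#'
#' @param cfg a [synthetic_config()]
#' @return a `data.frame` of class `votu_catalog` with columns `votu_id`,
#'   `genome_length`, `family`, `lifestyle`, `completeness`, `host_genus`,
#'   `host_family` and list-column `ko_set`.
#' @export
generate_catalog <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_votus
    votu_id <- sprintf("vOTU_%05d", seq_len(n))
    genome_length <- as.integer(round(exp(runif(n, log(2000), log(100000)))))
    assigned <- runif(n) > cfg$unassigned_family_frac
    family <- rep("unassigned", n)
    family[assigned] <- sample(.VAP_FAMILIES, sum(assigned), replace = TRUE,
                               prob = c(8, 6, 4, 3, 2, 2, 2, 2, 3, 3))
    lifestyle <- sample(c("lytic", "temperate", "unknown"), n,
                        replace = TRUE, prob = c(0.45, 0.3, 0.25))
    completeness <- round(runif(n, 50, 100), 1)
    has_host <- runif(n) < 0.6
    hg <- rep(NA_character_, n)
    hg[has_host] <- sample(.VAP_HOSTS$genus, sum(has_host), replace = TRUE)
    hf <- .VAP_HOSTS$family[match(hg, .VAP_HOSTS$genus)]
    ko_pool <- sprintf("K%05d", sample.int(22000, 400))
    n_ko <- sample(0:20, n, replace = TRUE,
                   prob = c(4, rep(1, 20)))  # many vOTUs carry no AMG
    ko_set <- lapply(n_ko, function(k) {
      if (k == 0) character(0) else sort(sample(ko_pool, k))
    })
    cat <- data.frame(
      votu_id = votu_id, genome_length = genome_length, family = family,
      lifestyle = lifestyle, completeness = completeness,
      host_genus = hg, host_family = hf, stringsAsFactors = FALSE
    )
    cat$ko_set <- ko_set
    class(cat) <- c("votu_catalog", "data.frame")
    cat
  })
}

# normal scores of a vector using midranks; basis for rank-scale coupling
# of planted correlation edges
.normal_scores <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 0.5) / length(x))
}

# log-normal block of raw weights: base feature means + per-sample noise,
# rows closed to 1 downstream. Zeros are detection-limit dropouts: per
# feature, the lowest `sparsity` fraction of latent values is zeroed
# (absence calls in the profiled data come from an abundance-driven
# coverage-breadth rule, so dropout concentrates in low-abundance cells).
.lognormal_block <- function(n_samples, feat_ids, sample_ids, mu,
                             shift, dispersion, sparsity, protect = NULL) {
  n_feat <- length(feat_ids)
  logw <- matrix(rep(mu, each = n_samples), n_samples, n_feat) + shift +
    matrix(rnorm(n_samples * n_feat, sd = dispersion), n_samples, n_feat)
  w <- exp(logw)
  if (sparsity > 0) {
    n_zero <- round(sparsity * n_samples)
    for (j in seq_len(n_feat)) {
      if (j %in% protect) next
      w[order(w[, j])[seq_len(n_zero)], j] <- 0
    }
  }
  dimnames(w) <- list(sample_ids, feat_ids)
  w
}

#' Generate a synthetic two-group cohort with ground truth
#'
#' Produces a viral and a bacterial relative-abundance matrix, per-sample
#' metadata (group, severity, etiology, demographic covariates and
#' clinical analytes) and the full ground truth of planted effects.
#'
#' Differential vOTUs receive a symmetric group-mean shift of
#' `planted_log2fc` log2 units (before compositional renormalization).
#' Monotone vOTUs — drawn from the differential set first, AP-enriched
#' features increasing and HC-depleted decreasing — follow a geometric
#' gradient across MAP, MSAP, SAP whose total span is `planted_log2fc`
#' log2 units, centered on the middle stratum. Planted correlation edges
#' couple a partner variable to the normal scores of the realized viral
#' abundances so the achieved Spearman correlation tracks
#' `planted_edge_rho`; partner cells are exempt from zero-inflation so the
#' planted rank correlation is not attenuated.
#'
#' @param cfg a [synthetic_config()]
#' @param cat catalog from [generate_catalog()] under the same config
#' @return a list with elements `viral` and `bacterial`
#'   ([abundance_matrix()]), `metadata` (`data.frame`) and `truth`
#'   (list: `differential_votus`, `monotone_votus`, `planted_edges`).
#' @export
generate_cohort <- function(cfg, cat) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(cat, "votu_catalog"))
  if (nrow(cat) != cfg$n_votus) {
    stop("catalog does not match `cfg$n_votus`", call. = FALSE)
  }
  n_diff <- round(cfg$frac_differential * cfg$n_votus)
  if (cfg$frac_differential > 0 && n_diff < 1) {
    stop("frac_differential * n_votus < 1: no differential feature can be planted",
         call. = FALSE)
  }
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_ap + cfg$n_hc
    sample_ids <- c(sprintf("AP_%03d", seq_len(cfg$n_ap)),
                    sprintf("HC_%03d", seq_len(cfg$n_hc)))
    group <- rep(c("AP", "HC"), c(cfg$n_ap, cfg$n_hc))

    # severity 38:25:19 and etiology 51:12:7:12, the cohort's class balance
    sev_n <- round(cfg$n_ap * c(MAP = 38, MSAP = 25, SAP = 19) / 82)
    sev_n[1] <- cfg$n_ap - sum(sev_n[-1])
    severity <- rep(NA_character_, n)
    severity[group == "AP"] <- sample(rep(names(sev_n), sev_n))
    eti_n <- round(cfg$n_ap * c(ABP = 51, AHP = 12, APN = 7, other = 12) / 82)
    eti_n[1] <- cfg$n_ap - sum(eti_n[-1])
    etiology <- rep(NA_character_, n)
    etiology[group == "AP"] <- sample(rep(names(eti_n), eti_n))

    # demographics mirror the emulated cohort (cases younger, heavier,
    # more often female than controls)
    age <- ifelse(group == "AP", rnorm(n, 49.5, 16.0), rnorm(n, 57.4, 7.6))
    bmi <- ifelse(group == "AP", rnorm(n, 24.4, 3.17), rnorm(n, 23.0, 2.52))
    sex <- ifelse(runif(n) < ifelse(group == "AP", 0.57, 0.43),
                  "female", "male")

    # planted differential effects: symmetric shift in log space, planted
    # on baseline-matched feature pairs (features sorted by base mean,
    # adjacent pairs split one up / one down) so the total community load
    # of the planted sets is balanced between groups and renormalization
    # does not leak spurious differences into null features
    votus <- cat$votu_id
    mu_v <- rnorm(cfg$n_votus, 0, 1)  # base feature heterogeneity
    diff_ids <- if (n_diff > 0) sort(sample(votus, n_diff)) else character(0)
    diff_dir <- character(0)
    if (n_diff > 0) {
      ord <- diff_ids[order(mu_v[match(diff_ids, votus)])]
      dirs <- character(n_diff)
      for (k in seq_len(floor(n_diff / 2))) {
        pick <- sample(c("AP-enriched", "HC-enriched"))
        dirs[2 * k - 1] <- pick[1]
        dirs[2 * k] <- pick[2]
      }
      if (n_diff %% 2 == 1) dirs[n_diff] <- sample(c("AP-enriched",
                                                     "HC-enriched"), 1)
      diff_dir <- setNames(dirs, ord)[diff_ids]
    }
    half <- log(2) * cfg$planted_log2fc / 2
    shift <- matrix(0, n, cfg$n_votus, dimnames = list(sample_ids, votus))
    is_ap <- group == "AP"
    for (f in diff_ids) {
      s <- if (diff_dir[[f]] == "AP-enriched") half else -half
      shift[is_ap, f] <- s
      shift[!is_ap, f] <- -s
    }

    # planted monotone severity gradients, drawn from the differential set
    # first (balanced between enriched and depleted members) so
    # trajectories sit on disease-associated features
    n_mono <- round(cfg$frac_monotone * cfg$n_votus)
    mono_ids <- character(0)
    mono_dir <- character(0)
    if (n_mono > 0) {
      take <- min(n_mono, n_diff)
      up_pool <- names(diff_dir)[diff_dir == "AP-enriched"]
      dn_pool <- names(diff_dir)[diff_dir == "HC-enriched"]
      n_up_take <- min(ceiling(take / 2), length(up_pool))
      n_dn_take <- min(take - n_up_take, length(dn_pool))
      mono_ids <- c(if (n_up_take > 0) sample(up_pool, n_up_take),
                    if (n_dn_take > 0) sample(dn_pool, n_dn_take))
      mono_dir <- ifelse(diff_dir[mono_ids] == "AP-enriched",
                         "increasing", "decreasing")
      if (n_mono > length(mono_ids)) {
        extra <- sample(setdiff(votus, diff_ids), n_mono - length(mono_ids))
        mono_ids <- c(mono_ids, extra)
        mono_dir <- c(mono_dir, sample(c("increasing", "decreasing"),
                                       length(extra), replace = TRUE))
      }
      names(mono_dir) <- mono_ids
      sev_rank <- match(severity, c("MAP", "MSAP", "SAP"))  # NA for HC
      # trajectory scale: planted_log2fc log2 units per severity step,
      # anchored at the MAP/MSAP midpoint. Anchoring there keeps the
      # case/control contrast of differential features non-negative in
      # every stratum, and the balanced increasing/decreasing sets cancel
      # compositionally, so gradients do not distort null features after
      # renormalization.
      step <- log(2) * cfg$planted_log2fc
      for (f in mono_ids) {
        s <- if (mono_dir[[f]] == "increasing") step else -step
        add <- s * (sev_rank - 1.5)
        add[is.na(add)] <- 0
        shift[, f] <- shift[, f] + add
      }
    }

    wv <- .lognormal_block(n, votus, sample_ids, mu_v, shift,
                           cfg$dispersion, cfg$sparsity)

    # bacterial block
    bact_ids <- sprintf("bOTU_%03d", seq_len(cfg$n_bacteria))
    mu_b <- rnorm(cfg$n_bacteria, 0, 1)

    # planted edges: half virus-bacterium, half feature-clinical.
    # Viral partners are drawn (with replacement) from a small hub pool,
    # so a denser planted structure raises the average node degree, the
    # hub-dominated shape typical of microbiome co-occurrence networks.
    n_edge <- cfg$n_planted_edges
    n_vb <- floor(n_edge / 2)
    n_fc <- n_edge - n_vb
    hub_pool <- sample(votus, min(5L, cfg$n_votus))
    edge_v_vb <- if (n_vb > 0) sample(hub_pool, n_vb, replace = TRUE) else character(0)
    edge_b <- if (n_vb > 0) sample(bact_ids, min(n_vb, cfg$n_bacteria)) else character(0)
    n_vb <- length(edge_b)
    edge_v_vb <- edge_v_vb[seq_len(n_vb)]
    sign_vb <- sample(c(1, -1), n_vb, replace = TRUE)

    rho <- cfg$planted_edge_rho
    wv_rel <- wv / pmax(rowSums(wv), .Machine$double.xmin)

    protect_b <- match(edge_b, bact_ids)
    wb <- .lognormal_block(n, bact_ids, sample_ids, mu_b, 0,
                           cfg$dispersion, cfg$sparsity, protect = protect_b)
    # coupled bacteria: log-abundance is a rho-weighted mix of the viral
    # partner's normal scores and fresh noise, so the realized rank
    # correlation tracks the target
    for (k in seq_len(n_vb)) {
      j <- protect_b[k]
      z <- .normal_scores(wv_rel[, edge_v_vb[k]])
      wb[, j] <- exp(mu_b[j] + cfg$dispersion *
                       (sign_vb[k] * rho * z +
                          sqrt(1 - rho^2) * rnorm(n)))
    }

    # clinical analytes: standardized Gaussians; planted feature-clinical
    # edges couple an analyte to a feature's normal scores
    clin_names <- if (cfg$n_clinical <= length(.VAP_CLINICAL)) {
      .VAP_CLINICAL[seq_len(cfg$n_clinical)]
    } else {
      c(.VAP_CLINICAL,
        sprintf("CLIN_%02d", seq_len(cfg$n_clinical - length(.VAP_CLINICAL))))
    }
    clin <- matrix(rnorm(n * cfg$n_clinical), n, cfg$n_clinical,
                   dimnames = list(sample_ids, clin_names))
    n_fc <- min(n_fc, cfg$n_clinical)
    edge_clin <- if (n_fc > 0) sample(clin_names, n_fc) else character(0)
    # features already in a virus-bacterium edge are excluded so planted
    # edges stay conditionally independent (no indirect near-threshold
    # correlations leaking across blocks)
    pool_fc <- c(setdiff(votus, edge_v_vb), setdiff(bact_ids, edge_b))
    edge_f_fc <- if (n_fc > 0) sample(pool_fc, n_fc) else character(0)
    sign_fc <- sample(c(1, -1), n_fc, replace = TRUE)
    wb_rel <- wb / pmax(rowSums(wb), .Machine$double.xmin)
    for (k in seq_len(n_fc)) {
      src <- if (edge_f_fc[k] %in% votus) wv_rel[, edge_f_fc[k]] else
        wb_rel[, edge_f_fc[k]]
      z <- .normal_scores(src)
      clin[, edge_clin[k]] <- sign_fc[k] * rho * z +
        sqrt(1 - rho^2) * rnorm(n)
    }

    viral <- abundance_matrix(wv, level = "votu")
    bacterial <- abundance_matrix(wb, level = "species")

    metadata <- data.frame(
      sample_id = sample_ids, group = group, severity = severity,
      etiology = etiology, age = round(age, 1), sex = sex,
      BMI = round(bmi, 1), stringsAsFactors = FALSE
    )
    metadata <- cbind(metadata, as.data.frame(round(clin, 4)))
    rownames(metadata) <- sample_ids

    planted_edges <- rbind(
      if (n_vb > 0) data.frame(node_a = edge_v_vb, node_b = edge_b,
                               sign = sign_vb, stringsAsFactors = FALSE),
      if (n_fc > 0) data.frame(node_a = edge_f_fc, node_b = edge_clin,
                               sign = sign_fc, stringsAsFactors = FALSE)
    )
    if (is.null(planted_edges)) {
      planted_edges <- data.frame(node_a = character(0),
                                  node_b = character(0), sign = integer(0))
    }
    truth <- list(differential_votus = diff_dir,
                  monotone_votus = mono_dir,
                  planted_edges = planted_edges)
    list(viral = viral, bacterial = bacterial, metadata = metadata,
         truth = truth)
  })
}

#' Simulate read alignments from an abundance matrix
#'
#' Per sample, read counts per vOTU are multinomial with probabilities
#' proportional to abundance times genome length (longer genomes attract
#' proportionally more reads at equal molarity), read positions are
#' uniform along the genome, and a fraction `cfg$tie_frac` of reads
#' receives a tied-score secondary hit on another vOTU to exercise
#' best-hit resolution downstream.
#'
#' @param cfg a [synthetic_config()]
#' @param cat the matching catalog
#' @param abundance an [abundance_matrix()] over the catalog's vOTUs
#' @param reads_per_sample sequencing depth; defaults to the config value
#' @return a `data.frame` of alignment records: `read_id`, `sample_id`,
#'   `votu_id`, `start`, `end` (0-based half-open), `score`.
#' @export
generate_alignments <- function(cfg, cat, abundance,
                                reads_per_sample = cfg$reads_per_sample) {
  stopifnot(inherits(cfg, "synthetic_config"),
            inherits(cat, "votu_catalog"),
            inherits(abundance, "abundance_matrix"))
  if (!all(feature_ids(abundance) %in% cat$votu_id)) {
    stop("abundance features not all present in catalog", call. = FALSE)
  }
  with_seed(cfg$seed + 2L, {
    len <- cat$genome_length[match(feature_ids(abundance), cat$votu_id)]
    out <- vector("list", nrow(abundance$values))
    for (i in seq_len(nrow(abundance$values))) {
      sid <- sample_ids(abundance)[i]
      p <- abundance$values[i, ] * len
      if (sum(p) == 0) next  # empty sample: no reads
      counts <- as.integer(rmultinom(1, reads_per_sample, p))
      votu <- rep(feature_ids(abundance), counts)
      vlen <- rep(len, counts)
      rl <- pmin(cfg$read_length, vlen)
      start <- floor(runif(length(votu)) * (vlen - rl + 1))
      rec <- data.frame(
        read_id = sprintf("%s_r%06d", sid, seq_along(votu)),
        sample_id = sid, votu_id = votu,
        start = as.integer(start), end = as.integer(start + rl),
        score = 100, stringsAsFactors = FALSE
      )
      # tied secondary hits on a random other vOTU
      n_tie <- floor(cfg$tie_frac * nrow(rec))
      if (n_tie > 0 && ncol(abundance$values) > 1) {
        pick <- sample.int(nrow(rec), n_tie)
        alt_idx <- sample.int(length(len), n_tie, replace = TRUE)
        same <- cat$votu_id[match(rec$votu_id[pick], cat$votu_id)] ==
          feature_ids(abundance)[alt_idx]
        alt_idx[same] <- (alt_idx[same] %% length(len)) + 1L
        alt_len <- len[alt_idx]
        arl <- pmin(cfg$read_length, alt_len)
        astart <- floor(runif(n_tie) * (alt_len - arl + 1))
        sec <- data.frame(
          read_id = rec$read_id[pick], sample_id = sid,
          votu_id = feature_ids(abundance)[alt_idx],
          start = as.integer(astart), end = as.integer(astart + arl),
          score = 100, stringsAsFactors = FALSE
        )
        rec <- rbind(rec, sec)
      }
      out[[i]] <- rec
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
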