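# differential selection: Wilcoxon, BH, fold change, filters, covariate
# validation, Fisher occurrence tests, host summaries

test_that("Wilcoxon exact p by enumeration on small tie-free samples", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p, 1 / 3)                 # 2 of C(4,2) = 6 assignments
  expect_equal(r$statistic, 3)
  x <- c(5, 1, 5, 1)
  expect_equal(wilcoxon_rank_sum(x, x)$p, 1)
  expect_equal(wilcoxon_rank_sum(rep(2, 3), rep(2, 4))$p, 1)  # constant
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("normal approximation tracks the exact enumeration at n = 12", {
  set.seed(2)
  deltas <- replicate(60, {
    nx <- sample(3:9, 1)
    x <- rnorm(nx)
    y <- rnorm(12 - nx, mean = runif(1, -1, 1))
    exact <- wilcoxon_rank_sum(x, y, exact = TRUE)$p
    approx_p <- wilcoxon_rank_sum(x, y, exact = FALSE)$p
    abs(exact - approx_p)
  })
  expect_lt(max(deltas), 0.05)
})

test_that("Wilcoxon agrees with the stats oracle on larger samples with ties", {
  set.seed(3)
  for (i in 1:20) {
    x <- round(rexp(15), 1)
    y <- round(rexp(18, 0.7), 1)
    mine <- wilcoxon_rank_sum(x, y)$p
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("BH step-up: worked example, edge cases, oracle equivalence", {
  expect_equal(bh_adjust(c(0.01, 0.03, 0.04, 0.05)),
               c(0.04, 0.05, 0.05, 0.05))
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(0.123), 0.123)        # m = 1
  set.seed(4)
  for (i in 1:10) {
    p <- runif(sample(2:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))   # order-preserving
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold change uses a pseudo-count guard", {
  expect_equal(fold_change(0.02, 0.01), 2, tolerance = 1e-5)
  expect_equal(fold_change(0.3, 0.3), 1)
  expect_true(is.finite(fold_change(0.1, 0)))
  expect_gt(fold_change(0.1, 0), 1e6)
  expect_error(fold_change(-1, 1), "non-negative")
})

test_that("select_differential recovers planted features and controls FDR", {
  sens <- fdr <- numeric(0)
  for (s in 1:3) {
    cfg <- synthetic_config(seed = s, n_ap = 50, n_hc = 50, n_votus = 150,
                            frac_differential = 0.2, frac_monotone = 0.06)
    coh <- generate_cohort(cfg, generate_catalog(cfg))
    dt <- select_differential(coh$viral, coh$metadata)
    tr <- coh$truth$differential_votus
    sel <- dt$feature_id[dt$direction != "ns"]
    sens <- c(sens, mean(names(tr) %in% sel))
    fdr <- c(fdr, if (length(sel)) mean(!sel %in% names(tr)) else 0)
    # planted direction matches the reported direction
    hit <- intersect(sel, names(tr))
    expect_true(all(dt$direction[match(hit, dt$feature_id)] == tr[hit]))
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdr), 0.1)
})

test_that("abundance filter trumps fold change and labels swap with groups", {
  set.seed(6)
  n <- 20
  v <- cbind(big = c(rep(0.9, n), rep(0.3, n)),
             rare = c(rep(2e-5, n), rep(1e-6, n)))
  v <- cbind(v, filler = 1 - rowSums(v))
  rownames(v) <- paste0("s", 1:(2 * n))
  v <- v + matrix(runif(3 * 2 * n, 0, 1e-8), 2 * n)  # break ties
  m <- am(v, renormalize = TRUE)
  meta <- toy_meta(rownames(v), rep(c("AP", "HC"), each = n))
  dt <- select_differential(m, meta)
  # rare feature: huge FC but below the 0.01% abundance floor
  expect_equal(dt$direction[dt$feature_id == "rare"], "ns")
  expect_equal(dt$direction[dt$feature_id == "big"], "AP-enriched")
  # swapping group labels flips every assigned direction
  meta2 <- meta
  meta2$group <- ifelse(meta$group == "AP", "HC", "AP")
  dt2 <- select_differential(m, meta2)
  expect_equal(dt2$direction[dt2$feature_id == "big"], "HC-enriched")
})

test_that("covariate validation confirms clean effects, rejects confounded ones", {
  set.seed(7)
  n <- 60
  grp <- rep(c("AP", "HC"), each = n / 2)
  age_conf <- rnorm(n, 50, 6) + ifelse(grp == "AP", 8, 0)
  # f1: true group effect; f2: driven entirely by age, which is also
  # imbalanced across groups (confounding); remaining features: null
  # filler keeping the composition gentle
  f1 <- exp(rnorm(n, ifelse(grp == "AP", 1, 0), 0.3))
  f2 <- exp(0.05 * age_conf + rnorm(n, 0, 0.15))
  filler <- matrix(exp(rnorm(n * 10)), n)
  v <- cbind(f1 = f1, f2 = f2, filler)
  colnames(v)[3:12] <- paste0("nf", 1:10)
  rownames(v) <- paste0("s", 1:n)
  m <- am(v, renormalize = TRUE)
  meta <- toy_meta(rownames(v), grp, age = age_conf,
                   sex = sample(c("m", "f"), n, TRUE), BMI = rnorm(n, 24, 2))
  dt <- select_differential(m, meta)
  expect_equal(dt$direction[dt$feature_id == "f1"], "AP-enriched")
  expect_equal(dt$direction[dt$feature_id == "f2"], "AP-enriched")
  dt <- covariate_validate(m, meta, dt)
  expect_true(dt$validated[dt$feature_id == "f1"])
  expect_false(dt$validated[dt$feature_id == "f2"])
  expect_error(covariate_validate(m, meta, dt, covariates = "nope"), "nope")
})

test_that("majority of Wilcoxon-selected features survive covariate validation", {
  # covariates independent of group; planted effects at the default size
  cfg <- synthetic_config(seed = 8, n_ap = 50, n_hc = 50, n_votus = 150,
                          frac_differential = 0.2)
  coh <- generate_cohort(cfg, generate_catalog(cfg))
  meta <- coh$metadata
  set.seed(8)
  meta$age <- rnorm(nrow(meta), 50, 10)       # break group-covariate links
  meta$BMI <- rnorm(nrow(meta), 24, 3)
  meta$sex <- sample(meta$sex)
  dt <- select_differential(coh$viral, meta)
  dt <- covariate_validate(coh$viral, meta, dt)
  sel <- dt$direction != "ns"
  expect_gte(mean(dt$validated[sel]), 0.79)
})

test_that("Fisher exact 2x2 matches enumeration and the stats oracle", {
  expect_equal(fisher_exact_2x2(3, 0, 0, 3), 0.1, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  set.seed(9)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 5), 2)
    mine <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("AMG occurrence test filters by rate and q, reports directions", {
  ids <- sprintf("v%02d", 1:40)
  cat <- toy_catalog(ids, rep(5000L, 40))
  # K1 carried by most of set A, none of B; K2 balanced; K3 rare
  cat$ko_set <- lapply(seq_along(ids), function(i) {
    k <- character(0)
    if (i <= 20 && i <= 16) k <- c(k, "K00001")
    if (i %% 2 == 0) k <- c(k, "K00002")
    if (i == 1) k <- c(k, "K00003")
    k
  })
  res <- amg_occurrence_test(ids[1:20], ids[21:40], cat)
  expect_true("K00001" %in% res$ko_id)
  expect_false("K00002" %in% res$ko_id)   # identical carriage -> p = 1
  expect_false("K00003" %in% res$ko_id)   # too rare
  expect_equal(res$enriched_in[res$ko_id == "K00001"], "A")
  dc <- attr(res, "direction_counts")
  expect_equal(unname(dc["A"]), 2L)  # K00001 and the rare K00003
  expect_error(amg_occurrence_test(character(0), ids[1:2], cat), "non-empty")
  expect_error(amg_occurrence_test(ids[1:3], ids[2:5], cat), "disjoint")
})

test_that("host/family/lifestyle summaries conserve selected counts", {
  ids <- c("v1", "v2", "v3", "v4")
  cat <- toy_catalog(ids, rep(1000L, 4),
                     family = c("Fx", "Fx", "unassigned", "Fy"),
                     host_genus = c("Escherichia", "Escherichia", NA,
                                    "Blautia_A"))
  dt <- data.frame(feature_id = ids, mean_a = 1, mean_b = 1,
                   fold_change = 1, p_raw = 0.01, q_bh = 0.01,
                   direction = c("AP-enriched", "AP-enriched",
                                 "HC-enriched", "ns"),
                   validated = NA, stringsAsFactors = FALSE)
  class(dt) <- c("differential_table", "data.frame")
  s <- host_family_summary(dt, cat)
  hg <- s$host_genus
  expect_equal(hg$count[hg$label == "Escherichia" &
                          hg$direction == "AP-enriched"], 2L)
  expect_equal(hg$count[hg$label == "unknown"], 1L)
  expect_equal(sum(s$host_genus$count), 3L)   # = number of selected vOTUs
  expect_equal(sum(s$family$count), 3L)
  expect_equal(sum(s$lifestyle$count), 3L)
})
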