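# ecology: alpha diversity, rarefaction, distances, PCoA, PERMANOVA

test_that("alpha diversity closed forms on uniform and degenerate rows", {
  v <- rbind(rep(0.25, 4),        # uniform over 4
             c(1, 0, 0, 0),       # single feature
             rep(0.25, 4))
  m <- am(v)
  ad <- alpha_diversity(m)
  expect_equal(ad$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(ad$simpson[1], 0.75, tolerance = 1e-12)
  expect_equal(unlist(ad[2, c("observed", "shannon", "simpson")]),
               c(observed = 1, shannon = 0, simpson = 0))
  # Shannon maximal at uniform composition
  set.seed(1)
  for (i in 1:10) {
    p <- runif(6)
    p <- p / sum(p)
    mm <- am(matrix(p, 1))
    expect_lte(alpha_diversity(mm)$shannon, log(6) + 1e-12)
    expect_lt(alpha_diversity(mm)$simpson, 1)
  }
})

test_that("rarefaction reaches total richness and is monotone", {
  set.seed(7)
  v <- matrix(rbinom(8 * 30, 1, 0.4) * runif(240), 8, 30)
  m <- am(v)
  rc <- rarefaction_curve(m, n_orders = 20, seed = 3)
  expect_equal(rc$richness[8], sum(colSums(m$presence) > 0))
  expect_true(all(diff(rc$richness) >= 0))
  # disjoint presence sets: curve linear in k
  vd <- diag(4)
  md <- am(vd)
  rcd <- rarefaction_curve(md, exact = TRUE)
  expect_equal(rcd$richness, 1:4)
})

test_that("closed-form rarefaction equals exhaustive enumeration of 4! orders", {
  set.seed(11)
  pres <- matrix(runif(4 * 12) < 0.4, 4, 12)
  v <- pres * 1
  m <- am(v)
  perms <- matrix(unlist(lapply(combinat_perms(4), identity)), ncol = 4,
                  byrow = TRUE)
  oracle <- sapply(1:4, function(k) {
    mean(apply(perms, 1, function(ord) {
      sum(colSums(pres[ord[seq_len(k)], , drop = FALSE]) > 0)
    }))
  })
  exact <- rarefaction_curve(m, exact = TRUE)$richness
  expect_equal(exact, oracle, tolerance = 1e-12)
  # Monte-Carlo agrees with the closed form
  mc <- rarefaction_curve(m, n_orders = 500, seed = 1)$richness
  expect_equal(mc, oracle, tolerance = 0.15)
})

test_that("distances: identical, disjoint and partial-overlap cases", {
  v <- rbind(c(0.5, 0.5, 0, 0),
             c(0.5, 0.5, 0, 0),
             c(0, 0, 0.5, 0.5),
             c(0, 0.5, 0.5, 0))
  m <- am(v)
  d <- distance_matrix(m, "bray_curtis")
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 1)        # disjoint supports
  dj <- distance_matrix(m, "jaccard")
  expect_equal(dj[1, 2], 0)
  expect_equal(dj[1, 4], 2 / 3)   # {A,B} vs {B,C}
  # symmetry, zero diagonal, range on fuzzed data
  set.seed(3)
  mf <- am(matrix(rexp(6 * 10), 6, 10))
  for (metric in c("bray_curtis", "jaccard")) {
    df <- distance_matrix(mf, metric)
    expect_equal(df, t(df))
    expect_equal(unname(diag(df)), rep(0, 6))
    expect_true(all(df >= 0 & df <= 1))
  }
})

test_that("distance implementations match vegan on fuzzed compositions", {
  skip_if_not_installed("vegan")
  set.seed(9)
  v <- matrix(rexp(8 * 20), 8, 20)
  v[runif(160) < 0.3] <- 0
  v <- v / rowSums(v)
  m <- am(v)
  expect_equal(unname(distance_matrix(m, "bray_curtis")),
               unname(as.matrix(vegan::vegdist(v, "bray"))),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(distance_matrix(m, "jaccard")),
               unname(as.matrix(vegan::vegdist((v > 0) * 1, "jaccard"))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCoA closed forms and distance reconstruction", {
  # two points at distance 1: coordinates +/- 0.5 on axis 1
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa(d2)
  expect_equal(sort(ord$coordinates[, 1]), c(-0.5, 0.5), tolerance = 1e-9,
               ignore_attr = TRUE)
  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  e3 <- pcoa(d3)$eigenvalues
  expect_equal(e3[1], e3[2], tolerance = 1e-9)
  # Euclidean-embeddable distances are reproduced exactly
  set.seed(4)
  x <- matrix(rnorm(6 * 3), 6)
  de <- as.matrix(dist(x))
  rec <- as.matrix(dist(pcoa(de)$coordinates))
  expect_equal(unname(rec), unname(de), tolerance = 1e-8)
  # percent explained sums to 100 over positive eigenvalues
  expect_equal(sum(pcoa(de)$pct_explained), 100, tolerance = 1e-9)
})

test_that("PERMANOVA R2 = 1 on a separated toy and matches hand computation", {
  # two groups of duplicated points at between-group distance 1:
  # SST = 8 * 1 / 8... computed by hand: within distances 0 -> SSW = 0
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  r <- permanova(d, c("g1", "g1", "g2", "g2"), n_perm = 999, seed = 1)
  expect_equal(r$R2, 1)
  # 2 of the 6 distinct labelings reproduce the split, so p -> 1/3
  expect_gt(r$p, 0.2)
  expect_lt(r$p, 0.5)
})

test_that("PERMANOVA matches vegan::adonis2 statistics", {
  skip_if_not_installed("vegan")
  set.seed(5)
  v <- matrix(rexp(20 * 15), 20, 15)
  v <- v / rowSums(v)
  g <- rep(c("a", "b"), each = 10)
  m <- am(v)
  d <- distance_matrix(m, "bray_curtis")
  mine <- permanova(d, g, n_perm = 99, seed = 1)
  ve <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(mine$pseudo_F, ve$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ve$R2[1], tolerance = 1e-10)
})

test_that("Monte-Carlo PERMANOVA p agrees with full enumeration at n = 6", {
  set.seed(6)
  x <- matrix(rnorm(6 * 2), 6)
  x[4:6, 1] <- x[4:6, 1] + 1.5
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3)
  # enumeration oracle over all C(6,3) = 20 labelings
  d2 <- d^2
  f_of <- function(lab) {
    sst <- sum(d2) / 12
    ssw <- sum(sapply(c("a", "b"), function(gg) {
      idx <- which(lab == gg)
      sum(d2[idx, idx]) / (2 * length(idx))
    }))
    ((sst - ssw) / 1) / (ssw / 4)
  }
  labelings <- combn(6, 3)
  fs <- apply(labelings, 2, function(ix) {
    lab <- rep("b", 6)
    lab[ix] <- "a"
    f_of(lab)
  })
  p_enum <- mean(fs >= f_of(g) - 1e-12)
  r <- permanova(d, g, n_perm = 1999, seed = 2)
  se <- sqrt(p_enum * (1 - p_enum) / 1999)
  expect_lt(abs(r$p - p_enum), 2 * se + 1e-3)
})

test_that("permutation p is reproducible and R2 ignores sample order", {
  set.seed(8)
  v <- matrix(rexp(12 * 10), 12, 10)
  m <- am(v)
  d <- distance_matrix(m)
  g <- rep(c("a", "b"), 6)
  r1 <- permanova(d, g, n_perm = 199, seed = 42)
  r2 <- permanova(d, g, n_perm = 199, seed = 42)
  expect_identical(r1$p, r2$p)
  perm <- sample(12)
  r3 <- permanova(d[perm, perm], g[perm], n_perm = 199, seed = 42)
  expect_equal(r1$R2, r3$R2, tolerance = 1e-12)
})

test_that("pairwise PERMANOVA covers all pairs with BH >= raw p", {
  set.seed(10)
  v <- matrix(rexp(18 * 8), 18, 8)
  m <- am(v)
  d <- distance_matrix(m)
  g <- rep(c("x", "y", "z"), each = 6)
  pw <- pairwise_permanova(d, g, n_perm = 99, seed = 1)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$q_bh >= pw$p - 1e-15))
  expect_error(permanova(d, rep("x", 18)), "2 groups")
})
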