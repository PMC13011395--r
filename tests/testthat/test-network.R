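# cross-kingdom networks: Spearman, graph building, topology, hubs,
# group comparison

test_that("Spearman: monotone, anti-monotone and oracle equivalence", {
  x <- c(1, 4, 9, 16, 25)
  expect_equal(spearman_rho(x, sqrt(x)), 1)
  expect_equal(spearman_rho(x, -x^3), -1)
  expect_true(is.na(spearman_rho(rep(1, 5), x)))
  set.seed(61)
  for (i in 1:30) {
    a <- sample(round(rnorm(20), 1))   # ties likely
    b <- round(rnorm(20), 1)
    expect_equal(spearman_rho(a, b),
                 stats::cor(rank(a), rank(b)),  # rank-then-Pearson oracle
                 tolerance = 1e-12)
  }
})

test_that("all-pairs correlations cover blocks and skip constants", {
  set.seed(62)
  n <- 30
  blocks <- list(
    virus = matrix(rnorm(n * 4), n,
                   dimnames = list(paste0("s", 1:n), paste0("v", 1:4))),
    clinical = matrix(rnorm(n * 2), n,
                      dimnames = list(paste0("s", 1:n), c("ALT", "GLU")))
  )
  blocks$virus[, 2] <- 1  # constant
  expect_message(cors <- spearman_all_pairs(blocks), "skipped")
  # 6 variables -> 15 pairs, 5 involving the constant are skipped
  expect_equal(nrow(cors), 10)
  expect_true(all(cors$p >= 0 & cors$p <= 1))
  cross <- spearman_all_pairs(blocks, include_within = FALSE)
  expect_true(all(cross$class_a != cross$class_b))
})

test_that("graph building applies both thresholds and is threshold-monotone", {
  set.seed(63)
  n <- 50
  v <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("v", 1:5)))
  v[, 2] <- v[, 1] * 0.9 + rnorm(n, 0, 0.3)   # one strong pair
  rownames(v) <- paste0("s", 1:n)
  cors <- spearman_all_pairs(list(virus = v))
  g <- build_graph(cors, rho_min = 0.4, q_max = 0.05)
  expect_true(nrow(g$edges) >= 1)
  expect_true(all(abs(g$edges$rho) > 0.4 & g$edges$q < 0.05))
  expect_true(all(g$edges$node_a != g$edges$node_b))   # no self-loops
  # raising rho_min never adds edges
  g2 <- build_graph(cors, rho_min = 0.6, q_max = 0.05)
  key <- function(g) paste(g$edges$node_a, g$edges$node_b)
  expect_true(all(key(g2) %in% key(g)))
  # all weak correlations -> empty edge set
  weak <- cors
  weak$rho <- weak$rho * 0.01
  expect_equal(nrow(build_graph(weak)$edges), 0)
  # BH q >= raw p on every tested pair
  cq <- cors
  cq$q <- bh_adjust(cq$p)
  expect_true(all(cq$q >= cq$p - 1e-15))
})

test_that("planted edges are recovered with high recall and precision", {
  rec <- prec <- numeric(0)
  for (s in 1:3) {
    cfg <- synthetic_config(seed = 70 + s, n_ap = 50, n_hc = 50,
                            n_votus = 60, n_bacteria = 20,
                            frac_differential = 0, frac_monotone = 0,
                            n_planted_edges = 16)
    coh <- generate_cohort(cfg, generate_catalog(cfg))
    clin_cols <- setdiff(colnames(coh$metadata),
                         c("sample_id", "group", "severity", "etiology",
                           "age", "sex", "BMI"))
    clin <- as.matrix(coh$metadata[rownames(coh$viral$values), clin_cols])
    cors <- spearman_all_pairs(list(virus = coh$viral$values,
                                    bacterium = coh$bacterial$values,
                                    clinical = clin),
                               include_within = FALSE)
    g <- build_graph(cors)
    pe <- coh$truth$planted_edges
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    found <- key(g$edges$node_a, g$edges$node_b)
    want <- key(pe$node_a, pe$node_b)
    rec <- c(rec, mean(want %in% found))
    prec <- c(prec, if (length(found)) mean(found %in% want) else 1)
    # planted signs agree
    hit <- match(want, found)
    expect_true(all(g$edges$sign[na.omit(hit)] ==
                      pe$sign[!is.na(hit)]))
  }
  expect_gte(mean(rec), 0.9)
  expect_gte(mean(prec), 0.9)
})

test_that("topology closed forms: triangle and 3-node path", {
  mk_graph <- function(edges_df, classes = NULL) {
    ids <- unique(c(edges_df$node_a, edges_df$node_b))
    cors <- data.frame(node_a = edges_df$node_a, node_b = edges_df$node_b,
                       class_a = "virus", class_b = "virus",
                       rho = edges_df$rho, p = 1e-10)
    build_graph(cors, rho_min = 0.4, q_max = 0.05)
  }
  tri <- mk_graph(data.frame(node_a = c("a", "b", "a"),
                             node_b = c("b", "c", "c"), rho = 0.9))
  tt <- topology(tri)
  expect_equal(tt$average_degree, 2)
  expect_equal(tt$average_path_length, 1)
  expect_equal(tt$n_components, 1L)
  path <- mk_graph(data.frame(node_a = c("a", "b"), node_b = c("b", "c"),
                              rho = c(0.9, -0.9)))
  tp <- topology(path)
  expect_equal(tp$average_path_length, 4 / 3)
  expect_equal(tp$n_positive, 1L)
  expect_equal(tp$n_negative, 1L)
  empty <- mk_graph(data.frame(node_a = "a", node_b = "b", rho = 0.1))
  expect_warning(te <- topology(empty), "empty")
  expect_equal(te$n_edges, 0L)
})

test_that("path length and components match igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(64)
  for (i in 1:15) {
    n <- sample(5:12, 1)
    npair <- n * (n - 1) / 2
    pairs <- t(combn(paste0("n", 1:n), 2))
    keep <- runif(npair) < 0.3
    if (!any(keep)) keep[1] <- TRUE
    cors <- data.frame(node_a = pairs[keep, 1], node_b = pairs[keep, 2],
                       class_a = "virus", class_b = "virus",
                       rho = 0.9, p = 1e-12)
    g <- build_graph(cors)
    mine <- topology(g)
    ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE)
    expect_equal(mine$average_path_length,
                 igraph::mean_distance(ig, unconnected = TRUE),
                 tolerance = 1e-12)
    expect_equal(mine$n_components,
                 igraph::components(ig)$no)
    expect_equal(mine$average_degree, mean(igraph::degree(ig)),
                 tolerance = 1e-12)
  }
})

test_that("hub ranking orders by degree with deterministic ties", {
  star <- data.frame(node_a = "hub", node_b = paste0("leaf", 1:5),
                     class_a = "bacterium", class_b = "virus",
                     rho = 0.8, p = 1e-12)
  g <- build_graph(star)
  hr <- hub_ranking(g)
  expect_equal(hr$node[1], "hub")
  expect_equal(hr$degree[1], 5L)
  expect_equal(hr$node[-1], sort(paste0("leaf", 1:5)))  # lexicographic ties
  expect_equal(nrow(hub_ranking(g, top_k = 100)), 6)    # clamped
})

test_that("network comparison reports differences and enforces thresholds", {
  set.seed(65)
  mk <- function(p_edge, seed) {
    pairs <- t(combn(paste0("n", 1:10), 2))
    set.seed(seed)
    keep <- runif(nrow(pairs)) < p_edge
    keep[1] <- TRUE
    cors <- data.frame(node_a = pairs[keep, 1], node_b = pairs[keep, 2],
                       class_a = "virus", class_b = "clinical",
                       rho = 0.9, p = 1e-12)
    build_graph(cors)
  }
  ga <- mk(0.5, 1); gb <- mk(0.2, 2)
  cmp <- compare_networks(ga, gb)
  expect_equal(cmp$differences[["n_edges"]],
               nrow(ga$edges) - nrow(gb$edges))
  expect_equal(cmp$topology_a$n_edges, nrow(ga$edges))
  same <- compare_networks(ga, ga)
  expect_true(all(same$differences == 0))
  gc <- build_graph(data.frame(node_a = "a", node_b = "b",
                               class_a = "virus", class_b = "virus",
                               rho = 0.9, p = 1e-12), rho_min = 0.3)
  expect_error(compare_networks(ga, gc), "thresholds")
})

test_that("denser planted structure yields higher average degree", {
  deg <- function(n_edges, seed) {
    cfg <- synthetic_config(seed = seed, n_ap = 40, n_hc = 40,
                            n_votus = 40, n_bacteria = 15,
                            frac_differential = 0, frac_monotone = 0,
                            n_planted_edges = n_edges)
    coh <- generate_cohort(cfg, generate_catalog(cfg))
    cors <- spearman_all_pairs(list(virus = coh$viral$values,
                                    bacterium = coh$bacterial$values),
                               include_within = FALSE)
    topology(build_graph(cors))$average_degree
  }
  wins <- sum(sapply(1:3, function(s) deg(24, 80 + s) > deg(4, 90 + s)))
  expect_gte(wins, 2)
})
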