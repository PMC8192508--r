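# Subnetwork extraction, variance filtering, partial correlation and edge
# mode-of-action assignment.

test_that("subnetwork extraction keeps exactly the input-output path nodes", {
  edges <- tibble::tibble(
    source = c("in1", "m", "in1", "x"),
    target = c("m", "out1", "d", "y"))
  sub <- suppressMessages(extract_subnetwork(edges, "in1", "out1"))
  expect_setequal(sub$nodes$node_id, c("in1", "m", "out1"))
  expect_equal(nrow(sub$edges), 2)

  # node downstream of inputs but with no route to an output is excluded
  edges2 <- tibble::tibble(source = c("in1", "in1", "m"),
                           target = c("m", "dead", "out1"))
  sub2 <- extract_subnetwork(edges2, "in1", "out1")
  expect_false("dead" %in% sub2$nodes$node_id)

  expect_error(extract_subnetwork(
    tibble::tibble(source = "a", target = "b"), "in1", "out1"))
})

test_that("extraction agrees with brute-force simple-path enumeration", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 30
    nodes <- paste0("n", 1:n)
    edges <- tibble::tibble(
      source = sample(nodes, 60, replace = TRUE),
      target = sample(nodes, 60, replace = TRUE)) %>%
      dplyr::filter(source != target) %>% dplyr::distinct()
    inputs <- sample(nodes, 3)
    outputs <- sample(setdiff(nodes, inputs), 3)

    # independent oracle: hand-rolled breadth-first closure over the edge
    # list (forward from inputs, backward from outputs)
    bfs <- function(start, e) {
      seen <- start
      repeat {
        nxt <- unique(e$target[e$source %in% seen])
        grown <- union(seen, nxt)
        if (length(grown) == length(seen)) return(seen)
        seen <- grown
      }
    }
    down_o <- bfs(inputs, edges)
    up_o <- bfs(outputs, edges[, c(2, 1)] |> setNames(c("source", "target")))
    expected <- union(union(inputs, outputs), intersect(down_o, up_o))
    got <- tryCatch(
      suppressMessages(extract_subnetwork(edges, inputs, outputs)),
      error = function(e) NULL)
    if (is.null(got)) {
      # extraction only errors when no input-output path exists
      expect_length(setdiff(expected, union(inputs, outputs)), 0)
    } else {
      # extraction may keep path-less inputs/outputs only if they touch kept
      # edges; the path nodes themselves must match exactly
      expect_setequal(setdiff(got$nodes$node_id, union(inputs, outputs)),
                      setdiff(expected, union(inputs, outputs)))
    }
  }
})

test_that("variance filter removes exactly the lower tail", {
  set.seed(5)
  mu <- matrix(100, 20, 30, dimnames = list(sprintf("G%02d", 1:20), NULL))
  k <- toy_counts(mu)
  # give each gene a distinct variance by scaling rows
  m <- as.matrix(k[, -1])
  m <- round(sweep(m - 100, 1, seq(0.1, 4, length.out = 20), "*")) + 100
  m[m < 0] <- 0
  k[, -1] <- tibble::as_tibble(as.data.frame(m))
  kept <- variance_filter(k, k$gene_id, fraction = 0.05)
  expect_equal(length(kept), 19)

  # brute-force sort-and-cut oracle
  norm <- normalize_log2(k)
  v <- apply(as.matrix(norm[, -1]), 1, var)
  expect_setequal(kept, k$gene_id[rank(v, ties.method = "first") > 1])

  # equal variances: strict inequality removes nothing
  flat <- toy_counts(matrix(100, 5, 10, dimnames = list(paste0("F", 1:5), NULL)))
  m2 <- as.matrix(flat[, -1]); m2[] <- rep(c(90, 110), length.out = length(m2))
  flat[, -1] <- tibble::as_tibble(as.data.frame(m2))
  expect_setequal(variance_filter(flat, flat$gene_id), flat$gene_id)
})

test_that("partial correlation matches its closed forms", {
  set.seed(1)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  # no controls: plain Pearson
  pc <- partial_correlation(x, y)
  expect_equal(pc$rho, cor(x, y), tolerance = 1e-12)
  expect_equal(pc$p, cor.test(x, y)$p.value, tolerance = 1e-12)

  # deterministic residual: target = TF1 - TF2 exactly, control TF2
  tf1 <- rnorm(40); tf2 <- rnorm(40)
  target <- tf1 - tf2
  expect_equal(partial_correlation(target, tf1, cbind(tf2))$rho, 1,
               tolerance = 1e-10)

  # precision-matrix oracle on 5 correlated Gaussians
  S <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  L <- chol(S)
  Z <- matrix(rnorm(5 * 2000), ncol = 5) %*% L
  P <- solve(cor(Z))
  expected <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  got <- partial_correlation(Z[, 1], Z[, 2], Z[, 3:5])$rho
  expect_equal(got, expected, tolerance = 1e-10)

  # collinear controls are pruned instead of failing
  c1 <- rnorm(40)
  pc2 <- partial_correlation(rnorm(40), rnorm(40), cbind(c1, 2 * c1))
  expect_equal(pc2$n_controls, 1)
})


# constructed counts need a bed of stable housekeeping genes so the
# median-of-ratios size factors do not absorb the planted TF signals
with_housekeeping <- function(mu, n_hk = 60) {
  hk <- matrix(exp(7), n_hk, ncol(mu),
               dimnames = list(paste0("HK", seq_len(n_hk)), NULL))
  rbind(mu, hk)
}

test_that("edge sign assignment recovers planted regulation directions", {
  set.seed(7)
  hits <- purrr::map_lgl(1:20, function(rep) {
    n <- 200
    tf1 <- rnorm(n); tf2 <- rnorm(n)
    target <- 2 * tf1 - 3 * tf2 + rnorm(n, 0, 0.5)
    mu <- with_housekeeping(exp(rbind(TF1 = 5 + 0.3 * tf1, TF2 = 5 + 0.3 * tf2,
                                      G = 5 + 0.25 * target)))
    k <- toy_counts(mu)
    sub <- extract_subnetwork(
      tibble::tibble(source = c("TF1", "TF2"), target = c("G", "G")),
      c("TF1", "TF2"), "G")
    net <- assign_edge_signs(sub, k)
    all(net$edges$sign[net$edges$source == "TF1"] == 1,
        net$edges$sign[net$edges$source == "TF2"] == -1)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("a single-regulator edge takes the plain correlation sign", {
  set.seed(11)
  n <- 120
  tf <- rnorm(n)
  mu <- with_housekeeping(exp(rbind(TF1 = 5 + 0.4 * tf, G = 5 - 0.35 * tf)))
  k <- toy_counts(mu)
  sub <- extract_subnetwork(tibble::tibble(source = "TF1", target = "G"),
                            "TF1", "G")
  net <- assign_edge_signs(sub, k)
  norm <- normalize_log2(k)
  r <- cor(as.numeric(norm[norm$gene_id == "TF1", -1]),
           as.numeric(norm[norm$gene_id == "G", -1]))
  expect_equal(net$edges$sign, sign(r))
  expect_equal(net$edges$sign, -1)
})

test_that("a TF linked only through a confounder is dropped", {
  set.seed(13)
  n <- 200
  tf1 <- rnorm(n)
  tf2 <- 0.9 * tf1 + rnorm(n, 0, sqrt(1 - 0.81))  # correlated with TF1 only
  target <- 1.5 * tf1 + rnorm(n, 0, 0.4)
  # deep counts so the observed confounder is an essentially noiseless control
  mu <- with_housekeeping(exp(rbind(TF1 = 8 + 0.4 * tf1, TF2 = 8 + 0.4 * tf2,
                                    G = 8 + 0.3 * target)))
  k <- toy_counts(mu)
  sub <- extract_subnetwork(
    tibble::tibble(source = c("TF1", "TF2"), target = c("G", "G")),
    c("TF1", "TF2"), "G")
  net <- suppressMessages(assign_edge_signs(sub, k))
  expect_true("TF1" %in% net$edges$source)
  expect_false("TF2" %in% net$edges$source)
})

test_that("sign assignment reaches a path-membership fixed point", {
  res <- fixture_pipeline()
  net <- res$network
  inputs <- net$nodes$node_id[net$nodes$role == "input"]
  outputs <- net$nodes$node_id[net$nodes$role == "output"]
  again <- extract_subnetwork(net$edges, inputs, outputs)
  expect_setequal(again$nodes$node_id, net$nodes$node_id)
  expect_equal(nrow(again$edges), nrow(net$edges))
})

test_that("retained edge count is monotone in the significance threshold", {
  sim <- fixture_study()
  res <- fixture_pipeline()
  inputs <- res$network$nodes$node_id[res$network$nodes$role == "input"]
  outputs0 <- res$degs$gene_id[res$degs$is_deg]
  sub <- suppressMessages(extract_subnetwork(sim$canonical_edges, inputs, outputs0))
  strict <- suppressMessages(assign_edge_signs(sub, sim$counts, p_threshold = 0.005))
  loose <- suppressMessages(assign_edge_signs(sub, sim$counts, p_threshold = 0.05))
  expect_lte(nrow(strict$edges), nrow(loose$edges))
  # and the stricter edge set is nested in the looser one
  key <- function(e) paste(e$source, e$target)
  expect_true(all(key(strict$edges) %in% key(loose$edges)))
})

test_that("network edge signs match the planted truth on synthetic studies", {
  sim <- fixture_study()
  res <- fixture_pipeline()
  m <- dplyr::inner_join(sim$network$edges, res$network$edges,
                         by = c("source", "target"), suffix = c("_true", "_hat"))
  expect_gt(nrow(m), 20)
  expect_gte(mean(m$sign_true == m$sign_hat), 0.9)
})
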