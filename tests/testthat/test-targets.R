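# Per-sample DACs, consistency classification, input influence and the
# reverse-target perturbation scan.

# small fully specified network + beta fixture used by several tests:
# in1 -> m (+1), m -> out1 (+1), m -> out2 (-1)
toy_network <- function(sign_m_out1 = 1) {
  e <- tibble::tibble(source = c("in1", "m", "m"),
                      target = c("m", "out1", "out2"),
                      sign = c(1, sign_m_out1, -1))
  signed_grn(e, tibble::tibble(
    node_id = c("in1", "m", "out1", "out2"),
    role = c("input", "intermediate", "output", "output"),
    is_tf = c(TRUE, TRUE, FALSE, FALSE)))
}

toy_links <- function() {
  tibble::tibble(chrom = "chr1", pos = 100L, tf_gene_id = "in1", r = 0.9,
                 representative = TRUE)
}

toy_trend_beta <- function(co) {
  # beta rises linearly with age at the linked position
  toy_beta(matrix(seq(0.2, 0.8, length.out = nrow(co)), nrow = 1),
           samples = co$sample_id, pos = 100L)
}

test_that("sample DACs are zero at cohort means and scale linearly", {
  co <- toy_cohort(9, ages = seq(25, 65, length.out = 9))
  b <- toy_trend_beta(co)
  act <- compute_sample_dacs(toy_network(), b, toy_links(), co)
  # the middle sample sits at the cohort mean -> zero everywhere
  expect_equal(max(abs(act[, "S5"])), 0)

  # doubling the input doubles all activities: replace beta by a matrix with
  # doubled z-scores is equivalent to scaling b; check via decomposition
  wm <- build_weight_matrix(toy_network())
  sig <- methylation_to_input(b, toy_links(), "S9")
  bb <- setNames(numeric(4), wm$nodes); bb["in1"] <- sig$b_value
  x1 <- solve_steady_state(wm$W, bb)
  x2 <- solve_steady_state(wm$W, 2 * bb)
  expect_equal(x2, 2 * x1)

  # batched per-sample solve equals stacking single-sample solves
  single <- vapply(co$sample_id, function(s) {
    sg <- methylation_to_input(b, toy_links(), s)
    bs <- setNames(numeric(4), wm$nodes); bs["in1"] <- sg$b_value
    solve_steady_state(wm$W, bs)[rownames(act)]
  }, numeric(4))
  expect_equal(act, single, tolerance = 1e-12)
})

test_that("DAC classification follows the sign of the edge path", {
  co <- toy_cohort(30, ages = seq(22, 72, length.out = 30))
  b <- toy_trend_beta(co)
  degs <- tibble::tibble(gene_id = c("out1", "out2"),
                         lfc_per_year = c(0.02, -0.02),
                         p = 0, p_adj = 0, is_deg = TRUE, fallback = FALSE)
  act <- compute_sample_dacs(toy_network(), b, toy_links(), co)
  dac <- dac_age_association(act, co, degs, toy_network())
  expect_equal(dac$class, c("consistent", "consistent"))

  # flipping the only edge into out1 flips its classification
  act2 <- compute_sample_dacs(toy_network(sign_m_out1 = -1), b, toy_links(), co)
  dac2 <- dac_age_association(act2, co, degs, toy_network(sign_m_out1 = -1))
  expect_equal(dac2$class[dac2$gene_id == "out1"], "inconsistent")
})

test_that("DAC-age association is calibrated under permuted ages", {
  sim <- fixture_study()
  res <- fixture_pipeline()
  degs <- res$degs
  set.seed(314)
  rates <- purrr::map_dbl(1:30, function(i) {
    co <- sim$cohort
    co$age <- sample(co$age)
    dac <- dac_age_association(res$activities, co, degs, res$network)
    mean(dac$class != "nonsignificant")
  })
  # clustered t-interval over permutations (outputs within one permutation
  # are correlated, so a plain binomial CI would be too narrow)
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.05), qt(0.995, length(rates) - 1) * se + 0.02)
})

test_that("input influence normalises to 1 and adds up across inputs", {
  co <- toy_cohort(20, ages = seq(25, 70, length.out = 20))
  b <- toy_trend_beta(co)
  infl <- suppressWarnings(input_influence(toy_network(), b, toy_links(), co))
  # single input: full influence on every output with any signal
  expect_equal(unname(infl$influence["in1", "out1"]), 1)
  expect_equal(unname(colSums(infl$influence)), c(1, 1), tolerance = 1e-10)

  # slope additivity on the full synthetic pipeline
  sim <- fixture_study()
  res <- fixture_pipeline()
  reps <- dplyr::filter(tibble::as_tibble(res$links), representative,
                        tf_gene_id %in%
                          res$network$nodes$node_id[res$network$nodes$role == "input"])
  inf2 <- suppressWarnings(
    input_influence(res$network, adjust_sex(sim$beta, sim$cohort), reps, sim$cohort))
  outputs <- res$network$nodes$node_id[res$network$nodes$role == "output"]
  samples <- colnames(res$activities)
  age <- sim$cohort$age[match(samples, sim$cohort$sample_id)]
  age_c <- age - mean(age)
  for (g in outputs[1:5]) {
    tot <- sum((res$activities[g, ] - mean(res$activities[g, ])) * age_c) /
      sum(age_c^2)
    expect_equal(sum(inf2$slope[, g]), tot, tolerance = 1e-10)
  }
  expect_equal(unname(colSums(inf2$influence)), rep(1, length(outputs)),
               tolerance = 1e-10)
})

test_that("a node opposing every DEG reverses them all under the scan", {
  # m2 inhibits both outputs which both rise in aging
  e <- tibble::tibble(source = c("in1", "m2", "m2"),
                      target = c("m2", "o1", "o2"), sign = c(1, -1, -1))
  net <- signed_grn(e, tibble::tibble(
    node_id = c("in1", "m2", "o1", "o2"),
    role = c("input", "intermediate", "output", "output"),
    is_tf = c(TRUE, TRUE, FALSE, FALSE)))
  val <- tibble::tibble(gene_id = c("o1", "o2"), r_age = 0.5, p = 0.001,
                        dac_direction = 1, lfc_direction = 1,
                        class = "consistent")
  scan <- perturb_node_scan(net, val)
  up <- dplyr::filter(tibble::as_tibble(scan), perturb_sign == 1)
  expect_equal(up$n_reversed, 2L)

  # antisymmetry: the -1 row reverses the complementary set (here: none),
  # and the two reversed sets are disjoint
  dn <- dplyr::filter(tibble::as_tibble(scan), perturb_sign == -1)
  expect_equal(dn$n_reversed, 0L)
  expect_length(intersect(up$reversed_ids[[1]], dn$reversed_ids[[1]]), 0)
})

test_that("the scan equals brute-force node-by-node solves on a toy network", {
  set.seed(23)
  nodes <- paste0("v", 1:15)
  e <- tibble::tibble(source = sample(nodes[1:8], 25, replace = TRUE),
                      target = sample(nodes, 25, replace = TRUE)) %>%
    dplyr::filter(source != target) %>% dplyr::distinct()
  e$sign <- sample(c(-1, 1), nrow(e), replace = TRUE)
  roles <- tibble::tibble(
    node_id = nodes,
    role = c("input", "input", rep("intermediate", 6), rep("output", 7)),
    is_tf = nodes %in% e$source)
  net <- signed_grn(e, roles)
  val <- tibble::tibble(gene_id = nodes[9:15],
                        lfc_direction = sample(c(-1, 1), 7, replace = TRUE),
                        class = "consistent")
  scan <- perturb_node_scan(net, val)
  wm <- build_weight_matrix(net)
  for (i in seq_len(nrow(scan))) {
    b <- setNames(numeric(15), wm$nodes)
    b[scan$node_id[i]] <- scan$perturb_sign[i]
    x <- solve_steady_state(wm$W, b)[val$gene_id]
    expect_equal(scan$n_reversed[i],
                 sum(sign(x) == -val$lfc_direction & abs(x) > 1e-9))
  }
})

test_that("target ranking reproduces the top-5% candidate arithmetic", {
  # a 235-node network with 22 inputs and 46 outputs leaves 167 intermediates
  # and exactly floor(0.05 * 167) = 8 candidates
  set.seed(31)
  scores <- tibble::tibble(
    node_id = rep(sprintf("m%03d", 1:167), each = 2),
    perturb_sign = rep(c(1, -1), 167),
    n_reversed = sample(0:22, 334, replace = TRUE),
    tiebreak_mass = runif(334),
    reversed_ids = vector("list", 334))
  attr(scores, "n_intermediate") <- 167L
  class(scores) <- c("target_scan", class(scores))
  ranked <- rank_targets(scores)
  expect_equal(sum(ranked$candidate), 8)
  expect_equal(nrow(ranked), 167)
  expect_equal(235 - 22 - 46, 167)

  # all-tied scores resolve deterministically by node id
  tied <- scores
  tied$n_reversed <- 5L
  tied$tiebreak_mass <- 1
  r2 <- rank_targets(tied)
  expect_equal(r2$node_id, sort(r2$node_id))

  # ranking is invariant to row order
  perm <- scores[sample.int(nrow(scores)), ]
  attr(perm, "n_intermediate") <- 167L
  class(perm) <- c("target_scan", class(perm))
  expect_equal(tibble::as_tibble(rank_targets(perm)),
               tibble::as_tibble(ranked))
})

test_that("scan scores are invariant to the perturbation magnitude", {
  net <- toy_network()
  val <- tibble::tibble(gene_id = c("out1", "out2"),
                        lfc_direction = c(1, -1), class = "consistent")
  scan <- perturb_node_scan(net, val)
  wm <- build_weight_matrix(net)
  for (i in seq_len(nrow(scan))) {
    b <- setNames(numeric(4), wm$nodes)
    b[scan$node_id[i]] <- 10 * scan$perturb_sign[i]   # rescaled perturbation
    x <- solve_steady_state(wm$W, b)[val$gene_id]
    expect_equal(scan$n_reversed[i],
                 sum(sign(x) == -val$lfc_direction & abs(x) > 1e-9))
  }
})
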