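# Signal flow analysis on a signed gene regulatory network.
#
# The model is linear: each node's steady-state activity balances the damped
# sum of its regulators' activities against its own basal input,
#   x = alpha * W %*% x + (1 - alpha) * b,
# where W[i, j] = sign(j -> i) / in_degree(i). Because every row of |W| sums
# to at most 1, alpha * W is a contraction for alpha < 1 and the fixed point
#   x = (1 - alpha) * (I - alpha W)^{-1} b
# is unique. alpha (default 0.5) trades off upstream signal flow against
# basal activity.

#' Construct a signed regulatory network object
#'
#' @param edges Tibble with columns `source`, `target`, `sign` (+1/-1) and
#'   optionally edge statistics.
#' @param nodes Optional tibble with columns `node_id`, `role`
#'   (`input`/`intermediate`/`output`) and `is_tf`. If omitted, nodes are
#'   derived from the edges with role `intermediate`.
#' @return A `signed_grn` object (list of `edges` and `nodes` tibbles).
#' @export
signed_grn <- function(edges, nodes = NULL) {
  stopifnot(all(c("source", "target") %in% names(edges)))
  if (!"sign" %in% names(edges)) edges$sign <- NA_real_
  if (is.null(nodes)) {
    nodes <- tibble(
      node_id = union(edges$source, edges$target),
      role = "intermediate",
      is_tf = union(edges$source, edges$target) %in% edges$source
    )
  }
  structure(list(edges = as_tibble(edges), nodes = as_tibble(nodes)),
            class = "signed_grn")
}

#' @export
print.signed_grn <- function(x, ...) {
  cat(sprintf("<signed_grn> %d nodes (%d input, %d intermediate, %d output), %d edges\n",
              nrow(x$nodes), sum(x$nodes$role == "input"),
              sum(x$nodes$role == "intermediate"), sum(x$nodes$role == "output"),
              nrow(x$edges)))
  invisible(x)
}

#' Build the normalised signed weight matrix of a network
#'
#' `W[i, j] = sign(j -> i) / in_degree(i)` for every edge `j -> i`; rows of
#' nodes with no regulators are zero. Under this normalisation the row sums
#' of `|W|` are at most 1, so damped propagation converges for any
#' `alpha < 1`.
#'
#' @param network A `signed_grn` object or an edge tibble with
#'   `source`, `target`, `sign`; self-loops are not allowed.
#' @return A list with `W` (node x node matrix, dimnames set) and `nodes`
#'   (character vector of node ids in matrix order).
#' @export
build_weight_matrix <- function(network) {
  edges <- if (inherits(network, "signed_grn")) network$edges else as_tibble(network)
  nodes <- if (inherits(network, "signed_grn")) network$nodes$node_id else
    union(edges$source, edges$target)
  if (any(edges$source == edges$target)) abort_fmt("network must not contain self-loops")
  if (any(is.na(edges$sign)) || !all(edges$sign %in% c(-1, 1))) {
    abort_fmt("every edge needs a sign in {-1, +1} to build the weight matrix")
  }
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    ti <- match(edges$target, nodes)
    si <- match(edges$source, nodes)
    d_in <- tabulate(ti, nbins = n)
    W[cbind(ti, si)] <- edges$sign / d_in[ti]
  }
  list(W = W, nodes = nodes)
}

#' Solve the steady state of a signal flow problem
#'
#' Computes `x = (1 - alpha) * (I - alpha W)^{-1} b` by a direct linear
#' solve. `b` may be a vector (one input pattern) or a matrix with one
#' column per pattern; the solution is linear in `b`.
#'
#' @param W Normalised weight matrix from [build_weight_matrix()].
#' @param b Basal input vector (or matrix of column vectors) aligned with the
#'   rows of `W`.
#' @param alpha Damping parameter in `[0, 1)`; default 0.5.
#' @return Steady-state activity, same shape as `b`.
#' @export
#' @examples
#' W <- matrix(c(0, 1, 0, 0), 2, 2, dimnames = list(c("B", "A"), c("B", "A")))
#' solve_steady_state(W, c(B = 0, A = 1), alpha = 0.5)
solve_steady_state <- function(W, b, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha < 1)
  n <- nrow(W)
  A <- diag(n) - alpha * W
  x <- tryCatch(solve(A, (1 - alpha) * b),
                error = function(e) abort_fmt("singular signal-flow system: %s", conditionMessage(e)))
  if (is.matrix(b)) dimnames(x) <- dimnames(b) else names(x) <- names(b)
  x
}

#' Iterative (Jacobi) signal propagation
#'
#' Fixed-point iteration `x <- alpha W x + (1 - alpha) b` from `x0 = b`,
#' stopped when the sup-norm update falls below `tol`. Serves as an
#' independent check of the direct solver: for `alpha < 1` the map is a
#' contraction with rate at most `alpha`, so both must agree.
#'
#' @inheritParams solve_steady_state
#' @param tol Convergence tolerance on the sup norm of the update.
#' @param max_iter Iteration cap.
#' @return Activity vector at convergence.
#' @export
propagate_iterative <- function(W, b, alpha = 0.5, tol = 1e-12, max_iter = 10000) {
  stopifnot(alpha >= 0, alpha < 1)
  x <- b
  for (i in seq_len(max_iter)) {
    x_new <- alpha * as.vector(W %*% x) + (1 - alpha) * b
    if (max(abs(x_new - x)) < tol) {
      names(x_new) <- names(b)
      return(x_new)
    }
    x <- x_new
  }
  abort_fmt("signal propagation did not converge within %d iterations", max_iter)
}

#' Decompose steady-state activity into per-input contributions
#'
#' Solves the system once per input node with the basal vector masked to that
#' input alone. By linearity the columns sum to the full solution.
#'
#' @inheritParams solve_steady_state
#' @param input_nodes Character vector of node ids on which `b` is supported.
#' @return Matrix (nodes x inputs) of contributions; `rowSums()` equals the
#'   joint steady state.
#' @export
decompose_contributions <- function(W, b, input_nodes, alpha = 0.5) {
  nodes <- rownames(W)
  stopifnot(all(input_nodes %in% nodes))
  off <- setdiff(nodes[b != 0], input_nodes)
  if (length(off) > 0) abort_fmt("b has support outside input_nodes: %s", off[1])
  B <- matrix(0, length(nodes), length(input_nodes),
              dimnames = list(nodes, input_nodes))
  B[cbind(match(input_nodes, nodes), seq_along(input_nodes))] <- b[match(input_nodes, nodes)]
  solve_steady_state(W, B, alpha = alpha)
}

#' Convert per-sample methylation to network input signals
#'
#' For each representative DMP-TF link, the sample's beta value is expressed
#' as a cohort Z-score for that position, scaled to `[-1, 1]` by the maximum
#' absolute Z over samples (max-abs scaling), and signed by the direction of
#' the methylation-expression correlation of the link: the basal input at the
#' linked TF is `v * sign(r)`.
#'
#' @param beta Beta-value tibble (`chrom`, `pos`, samples) over the cohort.
#' @param links Representative DMP-TF link tibble (from [link_dmp_to_tf()],
#'   rows with `representative = TRUE`), with columns `chrom`, `pos`,
#'   `tf_gene_id`, `r`.
#' @param sample Sample id (column of `beta`) to convert.
#' @return Tibble with one row per link: `dmp_id`, `tf_gene_id`, `z`, `v`,
#'   `b_value`. Positions with zero cohort SD contribute 0 with a warning.
#' @export
methylation_to_input <- function(beta, links, sample) {
  if (!sample %in% names(beta)) abort_fmt("sample '%s' not in beta matrix", sample)
  key <- paste(beta$chrom, beta$pos)
  idx <- match(paste(links$chrom, links$pos), key)
  if (any(is.na(idx))) abort_fmt("link position missing from beta matrix")
  m <- tbl_to_matrix(beta, c("chrom", "pos"))[idx, , drop = FALSE]
  mu <- rowMeans(m)
  sdev <- apply(m, 1, sd)
  zero_sd <- sdev == 0
  if (any(zero_sd)) {
    rlang::warn(sprintf("%d position(s) with zero cohort SD; input set to 0", sum(zero_sd)))
    sdev[zero_sd] <- 1
  }
  Z <- (m - mu) / sdev
  zmax <- apply(abs(Z), 1, max)
  zmax[zmax == 0] <- 1
  z <- Z[, sample]
  v <- z / zmax
  v[zero_sd] <- 0
  tibble(
    dmp_id = paste0(links$chrom, ":", links$pos),
    tf_gene_id = links$tf_gene_id,
    z = unname(z), v = unname(v),
    b_value = unname(v) * sign(links$r)
  )
}

# Build a basal-input matrix (nodes x samples) from representative links.
# Multiple links mapping to one TF are averaged (possible only via config
# override; representative selection normally yields one per TF).
input_matrix_from_links <- function(beta, links, nodes, samples) {
  B <- matrix(0, length(nodes), length(samples), dimnames = list(nodes, samples))
  for (s in samples) {
    sig <- methylation_to_input(beta, links, s)
    agg <- stats::aggregate(b_value ~ tf_gene_id, data = sig, FUN = mean)
    keep <- agg$tf_gene_id %in% nodes
    B[agg$tf_gene_id[keep], s] <- agg$b_value[keep]
  }
  B
}
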