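# Reconstruction of the aging-related subnetwork from a canonical regulatory
# network: path-based subnetwork extraction between DMP-derived input TFs and
# DEG outputs, a low-variance gene filter, and partial-correlation mode-of-
# action assignment for every retained edge.

reachable_from <- function(g, ids) {
  ids <- intersect(ids, igraph::V(g)$name)
  if (length(ids) == 0) return(character(0))
  unique(unlist(lapply(
    igraph::ego(g, order = igraph::vcount(g), nodes = ids, mode = "out"),
    function(v) v$name)))
}

#' Extract the input-output subnetwork of a canonical network
#'
#' Keeps the input TFs, the output DEGs, and every node lying on a directed
#' path from some input to some output (reachable from an input AND able to
#' reach an output). Kept edges are canonical edges on such paths: the source
#' must be an input or input-reachable and the target an output or
#' output-co-reachable, with both endpoints kept. Self-loops are removed.
#' Inputs/outputs absent from the canonical network are logged and dropped.
#'
#' @param edges Canonical edge tibble (`source`, `target`, optional `sign`).
#' @param inputs Character vector of input TF gene ids.
#' @param outputs Character vector of output DEG gene ids.
#' @return A `signed_grn` with node roles set (`input`/`output` beats
#'   `intermediate`; an id in both `inputs` and `outputs` is `input`).
#' @export
extract_subnetwork <- function(edges, inputs, outputs) {
  edges <- as_tibble(edges)
  if (!"sign" %in% names(edges)) edges$sign <- NA_real_
  edges <- filter(edges, .data$source != .data$target)
  all_nodes <- union(edges$source, edges$target)
  absent <- setdiff(union(inputs, outputs), all_nodes)
  if (length(absent) > 0) {
    rlang::inform(sprintf("%d input/output id(s) absent from the canonical network dropped",
                          length(absent)))
  }
  inputs <- intersect(inputs, all_nodes)
  outputs <- intersect(outputs, all_nodes)
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     vertices = all_nodes)
  down <- reachable_from(g, inputs)                       # inputs + descendants
  up <- reachable_from(igraph::reverse_edges(g), outputs) # outputs + ancestors
  kept_nodes <- union(union(inputs, outputs), intersect(down, up))
  kept <- edges %>%
    filter(.data$source %in% kept_nodes, .data$target %in% kept_nodes,
           .data$source %in% down, .data$target %in% up)
  # drop kept nodes isolated by edge filtering (inputs/outputs may remain)
  connected <- union(kept$source, kept$target)
  kept_nodes <- intersect(kept_nodes, union(connected, union(inputs, outputs)))
  if (nrow(kept) == 0) {
    abort_fmt("no input->output paths: %d inputs and %d outputs present but disconnected",
              length(inputs), length(outputs))
  }
  nodes <- tibble(
    node_id = kept_nodes,
    role = case_when(kept_nodes %in% inputs ~ "input",
                     kept_nodes %in% outputs ~ "output",
                     TRUE ~ "intermediate"),
    is_tf = kept_nodes %in% kept$source
  )
  signed_grn(kept, nodes)
}

#' Filter out low-variance genes
#'
#' Removes, from a candidate node set, the genes whose normalised-expression
#' variance falls strictly below the `fraction` quantile of the variances of
#' that set (default: the lower 5%). With all-equal variances nothing is
#' removed.
#'
#' @param expression Raw counts tibble (normalised internally) or an already
#'   normalised tibble when `normalize = FALSE`.
#' @param nodes Character vector of candidate gene ids.
#' @param fraction Quantile cut (default 0.05).
#' @param normalize Whether to size-factor-normalise first (default TRUE).
#' @return Character vector: the retained gene ids (genes without expression
#'   rows are dropped with a message).
#' @export
variance_filter <- function(expression, nodes, fraction = 0.05, normalize = TRUE) {
  norm <- if (normalize) normalize_log2(expression) else expression
  present <- intersect(nodes, norm$gene_id)
  if (length(present) < length(nodes)) {
    rlang::inform(sprintf("%d node(s) without expression rows dropped",
                          length(nodes) - length(present)))
  }
  m <- tbl_to_matrix(norm, "gene_id")[match(present, norm$gene_id), , drop = FALSE]
  v <- apply(m, 1, var)
  cut <- quantile(v, fraction, type = 7, names = FALSE)
  present[v >= cut]
}

#' Partial correlation given a set of controls
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' least-squares projection onto the controls plus an intercept. Collinear
#' controls are pruned by QR rank detection. The P value uses the
#' t-transform on `n - 2 - n_controls` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @param controls Optional numeric matrix (columns = control variables).
#' @return A list with `rho`, `p`, `n_controls` (after pruning).
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- 0
  if (!is.null(controls) && NCOL(controls) > 0) {
    C <- cbind(1, as.matrix(controls))
    qr_c <- qr(C)
    if (qr_c$rank < ncol(C)) {
      C <- C[, qr_c$pivot[seq_len(qr_c$rank)], drop = FALSE]
      qr_c <- qr(C)
    }
    k <- ncol(C) - 1
    x <- qr.resid(qr_c, x)
    y <- qr.resid(qr_c, y)
  } else {
    x <- x - mean(x); y <- y - mean(y)
  }
  if (n - 2 - k < 1) abort_fmt("not enough samples for %d controls", k)
  sx <- sqrt(sum(x^2)); sy <- sqrt(sum(y^2))
  if (sx == 0 || sy == 0) return(list(rho = NA_real_, p = NA_real_, n_controls = k))
  rho <- sum(x * y) / (sx * sy)
  rho <- pmin(1, pmax(-1, rho))
  tt <- rho * sqrt((n - 2 - k) / max(1 - rho^2, .Machine$double.eps))
  p <- if (abs(rho) >= 1) 0 else 2 * pt(-abs(tt), df = n - 2 - k)
  list(rho = rho, p = p, n_controls = k)
}

#' Assign edge modes of action from expression
#'
#' For every canonical edge `TF -> g` of the subnetwork, the controls are the
#' other TFs with kept edges into `g`. The edge is retained only if BOTH the
#' plain Pearson correlation and the partial correlation of the TF-target
#' expression pair are significant (`p < p_threshold`); its sign is the sign
#' of the partial correlation. Nodes isolated by edge removal are dropped and
#' the input-output path condition is re-enforced to a fixed point.
#'
#' When the control count would exhaust the degrees of freedom
#' (`n_controls >= n - 4`), only the `n - 5` controls with the largest
#' absolute plain correlation to the target are kept (logged).
#'
#' @param subnetwork `signed_grn` from [extract_subnetwork()].
#' @param expression Raw counts tibble (normalised internally).
#' @param p_threshold Significance threshold applied to both tests.
#' @return A `signed_grn` whose edges carry `sign`, `pearson_r`, `pearson_p`,
#'   `partial_r`, `partial_p`.
#' @export
assign_edge_signs <- function(subnetwork, expression, p_threshold = 0.05) {
  norm <- normalize_log2(expression)
  emat <- tbl_to_matrix(norm, "gene_id")
  rownames(emat) <- norm$gene_id
  n <- ncol(emat)
  edges <- subnetwork$edges
  missing <- setdiff(union(edges$source, edges$target), rownames(emat))
  if (length(missing) > 0) {
    abort_fmt("node '%s' has no expression row; filter the network first", missing[1])
  }
  capped <- 0L
  stats_list <- purrr::map(seq_len(nrow(edges)), function(i) {
    tf <- edges$source[i]; g <- edges$target[i]
    others <- setdiff(edges$source[edges$target == g], tf)
    y <- emat[g, ]; x <- emat[tf, ]
    r <- suppressWarnings(cor(x, y))
    if (is.na(r)) return(list(pearson_r = NA_real_, pearson_p = NA_real_,
                              partial_r = NA_real_, partial_p = NA_real_))
    p_plain <- pearson_p(r, n)
    if (length(others) >= n - 4) {
      ord <- order(-abs(apply(emat[others, , drop = FALSE], 1, function(z)
        suppressWarnings(cor(z, y)))))
      others <- others[ord][seq_len(max(0, n - 5))]
      capped <<- capped + 1L
    }
    ctrl <- if (length(others) > 0) t(emat[others, , drop = FALSE]) else NULL
    pc <- partial_correlation(x, y, ctrl)
    list(pearson_r = r, pearson_p = p_plain, partial_r = pc$rho, partial_p = pc$p)
  })
  if (capped > 0) rlang::inform(sprintf("controls capped for %d edge(s)", capped))
  st <- purrr::map_dfr(stats_list, as_tibble)
  edges <- bind_cols(edges[, c("source", "target")], st)
  undef <- !stats::complete.cases(edges[, c("pearson_p", "partial_p")])
  if (any(undef)) {
    rlang::inform(sprintf("%d edge(s) with undefined statistics removed", sum(undef)))
  }
  kept <- edges %>%
    filter(!undef, .data$pearson_p < p_threshold, .data$partial_p < p_threshold) %>%
    mutate(sign = sign(.data$partial_r))
  if (nrow(kept) == 0) abort_fmt("no edge survived the significance filters")

  inputs <- subnetwork$nodes$node_id[subnetwork$nodes$role == "input"]
  outputs <- subnetwork$nodes$node_id[subnetwork$nodes$role == "output"]
  # re-enforce path membership to a fixed point
  prev_n <- -1L
  net <- NULL
  while (nrow(kept) != prev_n) {
    prev_n <- nrow(kept)
    net <- extract_subnetwork(kept, inputs, outputs)
    kept <- net$edges
  }
  net
}
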