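# Downstream of the signal-flow engine: per-sample activities, DAC (direction
# of activity change) classification of output DEGs against their RNA-seq
# directions, per-input influence decomposition, and the +/-1 intermediate-
# node perturbation scan that ranks reverse-aging candidate targets.

#' Per-sample steady-state activities over the network
#'
#' For every cohort sample the methylation state of the representative DMPs
#' is converted to basal TF inputs ([methylation_to_input()]) and the
#' steady state solved in one batched linear solve. Samples missing from the
#' beta matrix are skipped with a warning.
#'
#' @param network Reconstructed `signed_grn`.
#' @param beta Sex-adjusted beta tibble.
#' @param links Representative `dmp_tf_link` rows.
#' @param cohort Cohort tibble.
#' @param alpha Damping (default 0.5).
#' @return Numeric matrix, network nodes x samples.
#' @export
compute_sample_dacs <- function(network, beta, links, cohort, alpha = 0.5) {
  links <- filter(as_tibble(links), .data$representative)
  wm <- build_weight_matrix(network)
  present <- intersect(cohort$sample_id, sample_cols(beta, c("chrom", "pos")))
  if (length(present) < nrow(cohort)) {
    rlang::warn(sprintf("%d cohort sample(s) missing from the beta matrix skipped",
                        nrow(cohort) - length(present)))
  }
  B <- input_matrix_from_links(beta, links, wm$nodes, present)
  solve_steady_state(wm$W, B, alpha = alpha)
}

#' Classify output DEGs by DAC-age association
#'
#' Per output DEG, the Pearson correlation of its per-sample activity with
#' age. A gene is `nonsignificant` when `p >= p_threshold`; otherwise
#' `consistent` if the activity trend's sign matches the gene's RNA-seq
#' `lfc_per_year` sign and `inconsistent` if it opposes it. Constant
#' activities are recorded with `r_age = 0`, `nonsignificant`.
#'
#' @param activities Node x sample matrix from [compute_sample_dacs()].
#' @param cohort Cohort tibble.
#' @param degs `aging_deg` tibble (supplies `lfc_per_year` per gene).
#' @param network Reconstructed `signed_grn` (defines the output nodes).
#' @param p_threshold Significance threshold (default 0.05).
#' @return Tibble (class `aging_dac`): `gene_id`, `r_age`, `p`,
#'   `dac_direction`, `lfc_direction`, `class`.
#' @export
dac_age_association <- function(activities, cohort, degs, network,
                                p_threshold = 0.05) {
  outputs <- network$nodes$node_id[network$nodes$role == "output"]
  missing <- setdiff(outputs, rownames(activities))
  if (length(missing) > 0) abort_fmt("output node '%s' absent from activities", missing[1])
  age <- cohort$age[match(colnames(activities), cohort$sample_id)]
  deg_tbl <- as_tibble(degs)
  out <- purrr::map_dfr(outputs, function(g) {
    a <- activities[g, ]
    if (sd(a) == 0) {
      r <- 0; p <- 1
    } else {
      r <- cor(a, age)
      p <- pearson_p(r, length(age))
    }
    lfc <- deg_tbl$lfc_per_year[match(g, deg_tbl$gene_id)]
    tibble(gene_id = g, r_age = r, p = p,
           dac_direction = sign(r),
           lfc_direction = sign(lfc))
  })
  out$class <- case_when(
    out$p >= p_threshold ~ "nonsignificant",
    out$dac_direction == out$lfc_direction ~ "consistent",
    TRUE ~ "inconsistent"
  )
  new_result(out, "aging_dac")
}

#' Relative influence of each input on each output DEG
#'
#' Per sample, the steady state is decomposed into per-input contributions;
#' for each (input, output) pair the age slope of the contribution is taken
#' across samples, and influences are normalised per output to
#' `|slope| / sum |slope|` (columns sum to 1). By linearity the input slopes
#' sum to the slope of the total activity.
#'
#' @param network Reconstructed `signed_grn`.
#' @param beta Sex-adjusted beta tibble.
#' @param links Representative `dmp_tf_link` rows.
#' @param cohort Cohort tibble.
#' @param alpha Damping (default 0.5).
#' @return List with `slope` and `influence` matrices (inputs x outputs) and
#'   the per-sample `contributions` array (nodes x inputs x samples).
#' @export
input_influence <- function(network, beta, links, cohort, alpha = 0.5) {
  links <- filter(as_tibble(links), .data$representative)
  wm <- build_weight_matrix(network)
  inputs <- network$nodes$node_id[network$nodes$role == "input"]
  outputs <- network$nodes$node_id[network$nodes$role == "output"]
  samples <- intersect(cohort$sample_id, sample_cols(beta, c("chrom", "pos")))
  age <- cohort$age[match(samples, cohort$sample_id)]
  B <- input_matrix_from_links(beta, links, wm$nodes, samples)
  contrib <- array(0, dim = c(length(wm$nodes), length(inputs), length(samples)),
                   dimnames = list(wm$nodes, inputs, samples))
  for (s in seq_along(samples)) {
    b <- B[, s]
    contrib[, , s] <- decompose_contributions(wm$W, b, inputs, alpha = alpha)
  }
  age_c <- age - mean(age)
  denom <- sum(age_c^2)
  slope <- matrix(0, length(inputs), length(outputs),
                  dimnames = list(inputs, outputs))
  for (g in outputs) {
    cg <- contrib[g, , , drop = FALSE][1, , ]   # inputs x samples
    if (length(inputs) == 1) cg <- matrix(cg, nrow = 1)
    slope[, g] <- as.vector((cg - rowMeans(cg)) %*% age_c) / denom
  }
  tot <- colSums(abs(slope))
  influence <- sweep(abs(slope), 2, ifelse(tot == 0, 1, tot), "/")
  if (any(tot == 0)) {
    rlang::warn(sprintf("%d output(s) with all-zero input slopes flagged", sum(tot == 0)))
  }
  list(slope = slope, influence = influence, contributions = contrib)
}

#' Scan intermediate nodes with unit perturbations
#'
#' Every intermediate node (not a DMP input, not a DEG output) is perturbed
#' with basal input +1 and -1 in turn; the steady state is solved and, among
#' the validated (class-consistent) DEGs, the genes whose activity sign
#' opposes their aging direction with `|x| > epsilon` are counted as
#' reversed. By linearity the -1 scan is the exact negation of the +1 scan.
#'
#' @param network Reconstructed `signed_grn`.
#' @param validated_degs `aging_dac` tibble; rows with `class ==
#'   "consistent"` define the reversal criterion.
#' @param alpha Damping (default 0.5).
#' @param epsilon Activity magnitude below which a "reversal" is treated as
#'   numerically zero (default 1e-9).
#' @return Tibble (class `target_scan`) with one row per (node, sign):
#'   `node_id`, `perturb_sign`, `n_reversed`, `tiebreak_mass`, `reversed_ids`.
#' @export
perturb_node_scan <- function(network, validated_degs, alpha = 0.5, epsilon = 1e-9) {
  inter <- network$nodes$node_id[network$nodes$role == "intermediate"]
  if (length(inter) == 0) abort_fmt("network has no intermediate nodes")
  val <- filter(as_tibble(validated_degs), .data$class == "consistent")
  if (nrow(val) == 0) abort_fmt("no validated (consistent) DEGs to reverse")
  wm <- build_weight_matrix(network)
  B <- matrix(0, length(wm$nodes), length(inter), dimnames = list(wm$nodes, inter))
  B[cbind(match(inter, wm$nodes), seq_along(inter))] <- 1
  X <- solve_steady_state(wm$W, B, alpha = alpha)   # +1 scans; -1 is -X
  aging_dir <- setNames(val$lfc_direction, val$gene_id)
  out <- purrr::map_dfr(seq_along(inter), function(i) {
    purrr::map_dfr(c(1, -1), function(sg) {
      x <- sg * X[names(aging_dir), i]
      rev <- sign(x) == -aging_dir & abs(x) > epsilon
      tibble(node_id = inter[i], perturb_sign = sg,
             n_reversed = sum(rev),
             tiebreak_mass = sum(abs(x[rev])),
             reversed_ids = list(names(aging_dir)[rev]))
    })
  })
  attr(out, "n_intermediate") <- length(inter)
  attr(out, "n_validated") <- nrow(val)
  new_result(out, "target_scan")
}

#' Rank intermediate nodes as reverse-aging candidate targets
#'
#' Per node the better of its two perturbation signs is kept (more DEGs
#' reversed; ties by larger total reversed activity mass, then by node id).
#' Nodes are ranked by `n_reversed` descending with the same tie rules, and
#' the top `floor(top_fraction * n_intermediate)` nodes (minimum 1) are
#' flagged as candidates.
#'
#' @param scores `target_scan` tibble from [perturb_node_scan()].
#' @param top_fraction Fraction of intermediate nodes to flag (default 0.05).
#' @return Tibble (class `target_rank`): `node_id`, `perturb_sign`,
#'   `n_reversed`, `tiebreak_mass`, `rank`, `candidate`.
#' @export
rank_targets <- function(scores, top_fraction = 0.05) {
  if (nrow(scores) == 0) abort_fmt("empty score table")
  n_inter <- attr(scores, "n_intermediate") %||% length(unique(scores$node_id))
  best <- as_tibble(scores) %>%
    group_by(.data$node_id) %>%
    arrange(desc(.data$n_reversed), desc(.data$tiebreak_mass),
            .data$perturb_sign, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(desc(.data$n_reversed), desc(.data$tiebreak_mass), .data$node_id) %>%
    mutate(rank = row_number())
  n_cand <- max(1L, floor(top_fraction * n_inter))
  best$candidate <- best$rank <= n_cand
  out <- select(best, "node_id", "perturb_sign", "n_reversed",
                "tiebreak_mass", "rank", "candidate")
  new_result(out, "target_rank")
}
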