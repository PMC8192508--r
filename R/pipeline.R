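# End-to-end orchestration: markers -> network -> signal flow -> targets ->
# drug screen, with one parameter list carrying every tunable threshold.

#' Default pipeline parameters
#'
#' All thresholds of the analysis with their defaults: raw-P DMP cutoff
#' 0.05, BH-adjusted DEG cutoff 0.05, 5 kb DMP-TF window, link P 0.05,
#' lower-5% variance filter, edge P 0.05 (applied to both the plain and the
#' partial correlation), damping alpha 0.5, DAC P 0.05, top-5% candidate
#' fraction, and tertile boundaries 100/3 and 200/3.
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  defaults <- list(
    p_dmp = 0.05, alpha_deg = 0.05, window = 5000, p_link = 0.05,
    var_fraction = 0.05, p_edge = 0.05, alpha = 0.5, p_dac = 0.05,
    top_fraction = 0.05, lower_tertile = 100 / 3, upper_tertile = 200 / 3
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) abort_fmt("unknown pipeline parameter: %s", unknown[1])
  modifyList(defaults, over)
}

#' Run the full aging signal-flow analysis
#'
#' Sex-adjusts the beta matrix, calls DMPs and DEGs, links DMPs to nearby TF
#' genes and picks representatives, extracts and sign-assigns the
#' aging-related subnetwork from the canonical edge list, computes per-sample
#' steady-state activities, classifies output DEG DACs, scans intermediate
#' nodes for reverse-aging targets and, when perturbagen profiles are given,
#' screens drugs against the validated DEG signature.
#'
#' @param cohort Cohort tibble.
#' @param beta Raw beta tibble.
#' @param counts Raw counts tibble.
#' @param annotation Gene annotation tibble.
#' @param canonical_edges Canonical network edge tibble (`source`, `target`).
#' @param profiles Optional long perturbation profile tibble.
#' @param params List from [pipeline_params()].
#' @return A list with elements `dmps`, `degs`, `links`, `network`,
#'   `activities`, `dac`, `scan`, `targets`, and (if profiles were given)
#'   `screen` and `signature`.
#' @export
run_aging_pipeline <- function(cohort, beta, counts, annotation,
                               canonical_edges, profiles = NULL,
                               params = pipeline_params()) {
  beta_adj <- adjust_sex(beta, cohort)
  dmps <- call_dmps(beta_adj, cohort, p_threshold = params$p_dmp)
  degs <- call_degs(counts, cohort, alpha_adj = params$alpha_deg)
  links <- link_dmp_to_tf(dmps, annotation, beta_adj, counts,
                          window = params$window, p_threshold = params$p_link)
  reps <- filter(as_tibble(links), .data$representative)
  if (nrow(reps) == 0) abort_fmt("no representative DMP-TF links; cannot define network inputs")
  input_tfs <- unique(reps$tf_gene_id)
  output_degs <- degs$gene_id[degs$is_deg]
  if (length(output_degs) == 0) abort_fmt("no DEGs called; cannot define network outputs")

  sub <- extract_subnetwork(canonical_edges, input_tfs, output_degs)
  keep_nodes <- variance_filter(counts, sub$nodes$node_id,
                                fraction = params$var_fraction)
  edges_kept <- filter(sub$edges, .data$source %in% keep_nodes,
                       .data$target %in% keep_nodes)
  sub <- extract_subnetwork(edges_kept, intersect(input_tfs, keep_nodes),
                            intersect(output_degs, keep_nodes))
  network <- assign_edge_signs(sub, counts, p_threshold = params$p_edge)

  net_links <- filter(reps, .data$tf_gene_id %in%
                        network$nodes$node_id[network$nodes$role == "input"])
  activities <- compute_sample_dacs(network, beta_adj, net_links, cohort,
                                    alpha = params$alpha)
  dac <- dac_age_association(activities, cohort, degs, network,
                             p_threshold = params$p_dac)
  scan <- perturb_node_scan(network, dac, alpha = params$alpha)
  targets <- rank_targets(scan, top_fraction = params$top_fraction)

  out <- list(dmps = dmps, degs = degs, links = links, network = network,
              activities = activities, dac = dac, scan = scan,
              targets = targets)
  if (!is.null(profiles)) {
    val <- filter(as_tibble(dac), .data$class == "consistent")
    sig_tbl <- if (nrow(val) > 0) val else as_tibble(dac)
    signature <- setNames(sig_tbl$lfc_direction, sig_tbl$gene_id)
    signature <- signature[signature != 0]
    out$signature <- signature
    out$screen <- screen_drugs(profiles, signature,
                               lower_tertile = params$lower_tertile,
                               upper_tertile = params$upper_tertile)
  }
  out
}
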