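# Synthetic multi-omics study generator. Emulates an aging blood cohort:
# ages 20-74, CpG beta values with age trends on the logit scale, a signed
# TF->target regulatory network, negative-binomial expression counts driven
# through that network by methylation-coupled TF activities, and perturbagen
# modZ profiles with planted signature-reversing drugs. Every planted effect
# is recorded in a ground-truth object so recovery is measurable.

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic study generator. The
#' defaults define the reference study conditions used throughout the test
#' suite: 100 samples aged 20-74, 2,000 CpGs of which 10% are true DMPs with
#' age slopes near 0.004 beta-units/year and logit-scale noise SD 0.3, a
#' 300-gene network with 60 TFs, 15% true DEGs with log2 fold changes near
#' 0.02/year, NB dispersion 0.02, 30% inhibitory edges, and 12 drugs of which
#' 2 are planted signature reversers.
#'
#' @param seed Integer seed (mandatory); all generator stages derive their
#'   random streams from it.
#' @param n_samples Cohort size (>= 4).
#' @param age_range Two-element numeric, years; ages are uniform on it.
#' @param n_cpg Number of CpG positions.
#' @param frac_dmp Fraction of CpGs given a true age slope.
#' @param dmp_slope_range Magnitude range of DMP slopes, beta-units/year
#'   (converted to the logit scale at each position's baseline); sign random.
#' @param methyl_noise_sd Logit-scale noise SD of beta values.
#' @param sex_effect_sd SD of per-position additive sex offsets (logit scale).
#' @param expr_sex_sd SD of per-gene additive sex offsets in the expression
#'   log-mean (natural-log scale).
#' @param n_genes,n_tf Gene universe size and number of TFs (`n_tf <= n_genes`).
#' @param frac_input_tf Fraction of TFs that receive DMP-coupled inputs.
#' @param frac_deg Fraction of genes planted as true DEGs (network outputs).
#' @param deg_lfc_range Magnitude range of DEG effects, log2 fold change per
#'   year; direction follows the network-propagated age trend.
#' @param nb_dispersion Negative-binomial dispersion (`var = mu + disp*mu^2`).
#' @param network_model `"scale_free"` (preferential attachment) or
#'   `"erdos_renyi"` (uniform parent choice).
#' @param frac_negative_edges Probability an edge is inhibitory.
#' @param coupling_r Target absolute correlation between a driver DMP's
#'   methylation and its TF's activity.
#' @param tf_age_leak Fraction of the methylation age trend passed into TF
#'   activities (the rest of the coupling is the age-orthogonal
#'   sample-to-sample variation); output age trends are carried by the
#'   planted DEG effects.
#' @param network_effect_scale Coefficient of propagated activity in the
#'   expression log-mean (natural-log units per activity unit).
#' @param model_mismatch_sd Extra lognormal noise SD added to expression
#'   means (0 = generative model matches the inference model exactly).
#' @param alpha Damping used when propagating activities into expression.
#' @param n_drugs,n_reverser_drugs Number of perturbagens and how many are
#'   planted signature reversers (`n_reverser_drugs <= n_drugs`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_samples = 100,
                       age_range = c(20, 74),
                       n_cpg = 2000,
                       frac_dmp = 0.1,
                       dmp_slope_range = c(0.003, 0.005),
                       methyl_noise_sd = 0.3,
                       sex_effect_sd = 0.15,
                       expr_sex_sd = 0.1,
                       n_genes = 300,
                       n_tf = 60,
                       frac_input_tf = 0.2,
                       frac_deg = 0.15,
                       deg_lfc_range = c(0.015, 0.025),
                       nb_dispersion = 0.02,
                       network_model = c("scale_free", "erdos_renyi"),
                       frac_negative_edges = 0.3,
                       coupling_r = 0.7,
                       tf_age_leak = 0.25,
                       network_effect_scale = 2.5,
                       model_mismatch_sd = 0,
                       alpha = 0.5,
                       n_drugs = 12,
                       n_reverser_drugs = 2) {
  if (missing(seed) || is.null(seed) || is.na(seed)) abort_fmt("sim_config requires a seed")
  network_model <- match.arg(network_model)
  cfg <- list(
    seed = as.integer(seed), n_samples = n_samples, age_range = age_range,
    n_cpg = n_cpg, frac_dmp = frac_dmp, dmp_slope_range = dmp_slope_range,
    methyl_noise_sd = methyl_noise_sd, sex_effect_sd = sex_effect_sd,
    expr_sex_sd = expr_sex_sd,
    n_genes = n_genes, n_tf = n_tf, frac_input_tf = frac_input_tf,
    frac_deg = frac_deg, deg_lfc_range = deg_lfc_range,
    nb_dispersion = nb_dispersion, network_model = network_model,
    frac_negative_edges = frac_negative_edges, coupling_r = coupling_r,
    tf_age_leak = tf_age_leak, network_effect_scale = network_effect_scale,
    model_mismatch_sd = model_mismatch_sd, alpha = alpha,
    n_drugs = n_drugs, n_reverser_drugs = n_reverser_drugs
  )
  fracs <- c(cfg$frac_dmp, cfg$frac_deg, cfg$frac_negative_edges, cfg$frac_input_tf)
  if (any(fracs < 0 | fracs > 1)) abort_fmt("fractions must lie in [0, 1]")
  if (cfg$n_tf > cfg$n_genes) abort_fmt("n_tf must not exceed n_genes")
  if (cfg$n_tf < 2) abort_fmt("need at least 2 TFs")
  if (cfg$n_reverser_drugs > cfg$n_drugs) abort_fmt("n_reverser_drugs must not exceed n_drugs")
  if (abs(cfg$seed) > 2^31 - 1e4) abort_fmt("seed too large")
  if (cfg$alpha < 0 || cfg$alpha >= 1) abort_fmt("alpha must lie in [0, 1)")
  structure(cfg, class = "sim_config")
}

stage_seed <- function(config, stage) {
  offs <- c(cohort = 101L, network = 202L, methylation = 303L,
            expression = 404L, perturbation = 505L)
  set.seed(config$seed + offs[[stage]])
}

#' Generate a synthetic cohort table
#'
#' Ages are uniform on `config$age_range`; sex is Bernoulli(0.5); smoking is
#' simulated among males only at the rate observed in small blood cohorts
#' (about a third of males), and is deliberately not adjusted for downstream.
#'
#' @param config A [sim_config()].
#' @return A cohort tibble (`sample_id`, `age`, `sex`, `smoking`).
#' @export
generate_cohort <- function(config) {
  if (config$n_samples < 4) abort_fmt("need at least 4 samples")
  stage_seed(config, "cohort")
  n <- config$n_samples
  cohort <- tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = runif(n, config$age_range[1], config$age_range[2]),
    sex = sample(c("male", "female"), n, replace = TRUE)
  )
  cohort$smoking <- ifelse(cohort$sex == "male" & runif(n) < 1 / 3,
                           "smoker", "non_smoker")
  validate_cohort(cohort)
  cohort
}

# Gene annotation layout: genes tiled along one chromosome, 10 kb bodies at
# 100 kb spacing, + strand, TSS at body start. CpGs for DMPs sit within 5 kb
# of their coupled TF's TSS; null CpGs fall in intergenic gaps.
make_annotation <- function(tf_ids, gene_ids) {
  all_ids <- c(tf_ids, gene_ids)
  n <- length(all_ids)
  start <- 100000L * seq_len(n)
  tibble(
    gene_id = all_ids, chrom = "chr1", tss = start,
    body_start = start, body_end = start + 10000L,
    strand = "+", is_tf = all_ids %in% tf_ids
  )
}

#' Generate the ground-truth signed regulatory network
#'
#' Builds a layered directed network in which only TFs have outgoing edges:
#' DMP-coupled input TFs regulate intermediate TFs, intermediate TFs regulate
#' output genes (the planted DEGs) and bystander genes. Edge signs are
#' inhibitory with probability `frac_negative_edges`. One intermediate hub is
#' planted as a reverser: it regulates most outputs directly and is verified,
#' by solving the signal-flow system, to reverse at least 60% of planted DEG
#' directions when perturbed against its own aging trend; generation retries
#' with fresh signs until the check passes (capped).
#'
#' DEG effect directions are set to the sign of the network-propagated age
#' trend at each output, so methylation inputs, network structure and
#' expression trends are mutually coherent.
#'
#' @param config A [sim_config()].
#' @return A list with `network` (a `signed_grn` with true roles),
#'   `annotation` (gene annotation tibble) and `truth` (ground-truth list:
#'   `cpg` table with planted slopes and TF couplings, `deg` table with
#'   signed log2-per-year effects, `input_tfs`, `reverser_node`,
#'   `reverser_sign`, `input_trend`).
#' @export
generate_true_network <- function(config) {
  stage_seed(config, "network")
  n_tf <- config$n_tf
  tf_ids <- sprintf("TF%03d", seq_len(n_tf))
  gene_ids <- sprintf("GEN%04d", seq_len(config$n_genes - n_tf))
  n_input <- max(2L, round(config$frac_input_tf * n_tf))
  input_tfs <- tf_ids[seq_len(n_input)]
  inter_tfs <- setdiff(tf_ids, input_tfs)
  n_deg <- max(1L, round(config$frac_deg * config$n_genes))
  if (n_deg > length(gene_ids)) abort_fmt("frac_deg too large for the non-TF gene pool")
  outputs <- sample(gene_ids, n_deg)
  bystanders <- setdiff(gene_ids, outputs)
  annotation <- make_annotation(tf_ids, gene_ids)

  pick_parents <- function(pool, k, weight) {
    k <- min(k, length(pool))
    if (config$network_model == "scale_free") {
      w <- weight[pool] + 1
      sample(pool, k, prob = w / sum(w))
    } else sample(pool, k)
  }

  for (attempt in seq_len(25)) {
    out_deg <- setNames(numeric(n_tf), tf_ids)
    src <- character(0); tgt <- character(0)
    # planted reverser: an intermediate hub fed directly (and only) by two
    # input TFs, so no other intermediate sits upstream of it and inherits
    # its output coverage in the perturbation scan; its two parent edges are
    # signed below so their aging-trend contributions cancel exactly
    reverser <- sample(inter_tfs, 1)
    rev_parents <- sample(input_tfs, 2)
    # input/earlier-intermediate TFs -> intermediate TFs
    for (i in seq_along(inter_tfs)) {
      this <- inter_tfs[i]
      if (this == reverser) {
        p <- rev_parents
      } else {
        pool <- c(input_tfs, setdiff(inter_tfs[seq_len(i - 1)], reverser))
        k <- sample(1:3, 1, prob = c(0.5, 0.35, 0.15))
        p <- pick_parents(pool, k, out_deg)
      }
      src <- c(src, p); tgt <- c(tgt, rep(this, length(p)))
      out_deg[p] <- out_deg[p] + 1
    }
    # the reverser regulates ~90% of outputs directly
    rev_out <- sample(outputs, max(1L, round(0.9 * length(outputs))))
    src <- c(src, rep(reverser, length(rev_out))); tgt <- c(tgt, rev_out)
    out_deg[reverser] <- out_deg[reverser] + length(rev_out)
    # intermediate TFs -> outputs (1-2 additional parents each)
    for (g in outputs) {
      k <- sample(1:2, 1)
      p <- pick_parents(setdiff(inter_tfs, reverser), k, out_deg)
      src <- c(src, p); tgt <- c(tgt, rep(g, length(p)))
      out_deg[p] <- out_deg[p] + 1
    }
    # TFs -> bystander genes (pruned later by the pipeline)
    for (g in bystanders) {
      if (runif(1) < 0.5) {
        p <- pick_parents(tf_ids, sample(1:2, 1), out_deg)
        src <- c(src, p); tgt <- c(tgt, rep(g, length(p)))
        out_deg[p] <- out_deg[p] + 1
      }
    }
    edges <- tibble(source = src, target = tgt) %>% distinct()
    edges$sign <- ifelse(runif(nrow(edges)) < config$frac_negative_edges, -1, 1)

    nodes <- tibble(
      node_id = c(tf_ids, gene_ids),
      role = case_when(
        c(tf_ids, gene_ids) %in% input_tfs ~ "input",
        c(tf_ids, gene_ids) %in% outputs ~ "output",
        TRUE ~ "intermediate"
      ),
      is_tf = c(tf_ids, gene_ids) %in% tf_ids
    )
    net <- signed_grn(edges, nodes)
    wm <- build_weight_matrix(net)

    # input aging trends: direction each input TF's activity moves per year
    dmp_sign <- sample(c(-1, 1), n_input, replace = TRUE)
    coupling_sign <- sample(c(-1, 1), n_input, replace = TRUE)
    input_trend <- setNames(dmp_sign * coupling_sign, input_tfs)

    # sign the reverser's two parent edges so their trend contributions
    # cancel: the reverser is trend-neutral (its activity carries no age
    # component), so orienting its out-edges below cannot distort the
    # propagated aging directions or the downstream DAC classification
    s1 <- sample(c(-1, 1), 1)
    s2 <- -s1 * input_trend[rev_parents[1]] * input_trend[rev_parents[2]]
    edges$sign[edges$source == rev_parents[1] & edges$target == reverser] <- s1
    edges$sign[edges$source == rev_parents[2] & edges$target == reverser] <- s2

    b_trend <- setNames(numeric(length(wm$nodes)), wm$nodes)
    b_trend[input_tfs] <- input_trend
    net <- signed_grn(edges, nodes)
    wm <- build_weight_matrix(net)
    x_trend <- solve_steady_state(wm$W, b_trend, alpha = config$alpha)

    # planted direction per output: the propagated trend's sign; outputs
    # whose +/-1 path contributions cancel exactly get a random direction
    # (their DACs are pure noise downstream and fall out as nonsignificant)
    eff_sign <- sign(x_trend[outputs])
    zero <- eff_sign == 0
    eff_sign[zero] <- sample(c(-1, 1), sum(zero), replace = TRUE)

    # orient the reverser's direct edges against the planted aging trend;
    # the reverser is trend-neutral, so this cannot alter the trend itself
    rev_edge <- which(edges$source == reverser & edges$target %in% outputs)
    edges$sign[rev_edge] <- -eff_sign[match(edges$target[rev_edge], outputs)]
    net <- signed_grn(edges, nodes)
    wm <- build_weight_matrix(net)

    # verify the planted reverser with the solver: a batched +1 scan over all
    # intermediate TFs (the -1 scan is its negation by linearity); accept only
    # when the reverser reverses >= 60% of planted DEG directions AND strictly
    # tops every other intermediate with a margin, so recovery through the
    # inferred network is a fair test
    B <- matrix(0, length(wm$nodes), length(inter_tfs),
                dimnames = list(wm$nodes, inter_tfs))
    B[cbind(match(inter_tfs, wm$nodes), seq_along(inter_tfs))] <- 1
    Xs <- solve_steady_state(wm$W, B, alpha = config$alpha)
    n_rev <- vapply(inter_tfs, function(m) {
      x <- Xs[outputs, m]
      max(sum(sign(x) == -eff_sign & abs(x) > 1e-9),
          sum(sign(-x) == -eff_sign & abs(x) > 1e-9))
    }, 1L)
    x_r <- Xs[outputs, reverser]
    pos_cnt <- sum(sign(x_r) == -eff_sign & abs(x_r) > 1e-9)
    neg_cnt <- sum(sign(-x_r) == -eff_sign & abs(x_r) > 1e-9)
    best <- list(sign = if (pos_cnt >= neg_cnt) 1 else -1,
                 frac = max(pos_cnt, neg_cnt) / length(outputs))
    runner_up <- max(n_rev[setdiff(inter_tfs, reverser)])
    if (best$frac >= 0.6 &&
        n_rev[reverser] >= runner_up + max(2, ceiling(0.1 * length(outputs)))) {
      lfc <- runif(n_deg, config$deg_lfc_range[1], config$deg_lfc_range[2]) * eff_sign

      # CpG layout: planted DMPs within 5 kb of their coupled input TF's TSS
      n_dmp <- round(config$frac_dmp * config$n_cpg)
      tf_of_dmp <- input_tfs[rep_len(seq_len(n_input), n_dmp)]
      tss <- annotation$tss[match(tf_of_dmp, annotation$gene_id)]
      dmp_pos <- integer(n_dmp)
      driver_idx <- integer(0)
      for (ix in split(seq_len(n_dmp), tf_of_dmp)) {
        dmp_pos[ix] <- tss[ix] + sample(seq(-4900, -100, by = 50), length(ix))
        # one driver DMP per input TF actually drives the TF's activity
        driver_idx <- c(driver_idx, ix[1])
      }
      slope_beta <- runif(n_dmp, config$dmp_slope_range[1], config$dmp_slope_range[2])
      slope_sign <- dmp_sign[match(tf_of_dmp, input_tfs)]
      # null CpGs in intergenic space, far from any TSS
      n_null <- config$n_cpg - n_dmp
      null_pos <- sample(seq(20000, 90000, by = 10), n_null) +
        100000L * sample.int(config$n_genes, n_null, replace = TRUE)
      cpg <- tibble(
        cpg_id = sprintf("cpg%05d", seq_len(config$n_cpg)),
        chrom = "chr1",
        pos = c(dmp_pos, null_pos),
        slope_beta = c(slope_beta * slope_sign, numeric(n_null)),
        tf_gene_id = c(tf_of_dmp, rep(NA_character_, n_null)),
        is_dmp = rep(c(TRUE, FALSE), c(n_dmp, n_null)),
        driver = FALSE
      )
      cpg$driver[driver_idx] <- TRUE
      if (anyDuplicated(cpg$pos)) next

      truth <- list(
        cpg = cpg,
        deg = tibble(gene_id = outputs, lfc_per_year = lfc),
        input_tfs = input_tfs,
        input_trend = input_trend,
        coupling_sign = setNames(coupling_sign, input_tfs),
        reverser_node = reverser,
        reverser_sign = best$sign,
        reverser_frac = best$frac
      )
      return(list(network = net, annotation = annotation, truth = truth))
    }
  }
  abort_fmt("could not generate a network with a verified reverser in 25 attempts")
}

#' Simulate the methylation beta matrix
#'
#' Beta values follow `plogis(intercept + slope * (age - mid) + sex_offset +
#' noise)` with noise on the logit scale, so all betas stay strictly inside
#' (0, 1). Planted DMP slopes (given in beta-units/year) are converted to the
#' logit scale at each position's baseline; null positions have slope zero.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_true_network()] (`$truth`).
#' @return A beta-value tibble (`chrom`, `pos`, one column per sample),
#'   sorted by position.
#' @export
simulate_methylation <- function(cohort, config, truth) {
  if (nrow(cohort) == 0) abort_fmt("cohort is empty")
  stage_seed(config, "methylation")
  cpg <- truth$cpg
  n_pos <- nrow(cpg)
  n <- nrow(cohort)
  base_beta <- runif(n_pos, 0.25, 0.75)
  intercept <- qlogis(base_beta)
  slope_logit <- cpg$slope_beta / (base_beta * (1 - base_beta))
  sex_off <- rnorm(n_pos, 0, config$sex_effect_sd)
  mid <- mean(config$age_range)
  is_f <- as.numeric(cohort$sex == "female")
  eta <- outer(intercept, rep(1, n)) +
    outer(slope_logit, cohort$age - mid) +
    outer(sex_off, is_f) +
    matrix(rnorm(n_pos * n, 0, config$methyl_noise_sd), n_pos, n)
  beta <- plogis(eta)
  out <- bind_cols(tibble(chrom = cpg$chrom, pos = cpg$pos),
                   as_tibble(setNames(as.data.frame(beta), cohort$sample_id)))
  dplyr::arrange(out, .data$chrom, .data$pos)
}

# Per-sample input-TF activities from realised driver-DMP methylation:
# standardised logit-beta with the age component attenuated by tf_age_leak,
# then degraded to the target coupling correlation. The leak keeps TF
# expression coupled to methylation sample-to-sample while the bulk of the
# age trend in expression is carried by the planted DEG effects; with a
# desk-scale BH burden a fully age-coupled TF layer would itself be called
# differentially expressed wholesale, erasing the intermediate-node layer.
tf_activity_matrix <- function(beta, cohort, config, truth) {
  drivers <- truth$cpg[truth$cpg$driver, ]
  key <- paste(beta$chrom, beta$pos)
  idx <- match(paste(drivers$chrom, drivers$pos), key)
  m <- qlogis(as.matrix(beta[idx, cohort$sample_id, drop = FALSE]))
  z <- t(scale(t(m)))
  age_c <- cohort$age - mean(cohort$age)
  bhat <- as.vector(z %*% age_c) / sum(age_c^2)
  zhat <- outer(bhat, age_c)
  z_tilde <- config$tf_age_leak * zhat + (z - zhat)
  z_tilde <- t(scale(t(z_tilde)))
  r <- config$coupling_r
  eps <- matrix(rnorm(length(z)), nrow(z), ncol(z))
  act <- truth$coupling_sign[drivers$tf_gene_id] * (r * z_tilde + sqrt(1 - r^2) * eps)
  rownames(act) <- drivers$tf_gene_id
  colnames(act) <- cohort$sample_id
  act
}

#' Simulate the expression count matrix
#'
#' Input-TF activities are derived from the realised methylation of their
#' driver DMPs (attenuated to `coupling_r`), propagated through the true
#' network with the same damped linear rule as the signal-flow engine, and
#' added to each gene's log mean together with the planted per-year log2
#' fold change (true DEGs only), a per-gene sex offset and a per-sample
#' library size factor. Counts are negative-binomial with dispersion
#' `nb_dispersion` (Poisson in the zero-dispersion limit).
#'
#' @param cohort Cohort tibble.
#' @param network True `signed_grn` from [generate_true_network()].
#' @param methylation Beta tibble from [simulate_methylation()].
#' @param config A [sim_config()].
#' @param truth Ground-truth list.
#' @return A counts tibble (`gene_id`, one integer column per sample).
#' @export
simulate_expression <- function(cohort, network, methylation, config, truth) {
  stage_seed(config, "expression")
  wm <- build_weight_matrix(network)
  n <- nrow(cohort)
  act <- tf_activity_matrix(methylation, cohort, config, truth)
  B <- matrix(0, length(wm$nodes), n, dimnames = list(wm$nodes, cohort$sample_id))
  B[rownames(act), ] <- act
  X <- solve_steady_state(wm$W, B, alpha = config$alpha)

  genes <- wm$nodes
  baseline <- rnorm(length(genes), log(500), 0.7)
  sex_coef <- rnorm(length(genes), 0, config$expr_sex_sd)
  libsize <- runif(n, 0.7, 1.4)
  mid <- mean(config$age_range)
  lfc_ln <- setNames(numeric(length(genes)), genes)
  lfc_ln[truth$deg$gene_id] <- truth$deg$lfc_per_year * log(2)
  is_f <- as.numeric(cohort$sex == "female")

  log_mu <- baseline + config$network_effect_scale * X +
    outer(lfc_ln, cohort$age - mid) + outer(sex_coef, is_f) +
    matrix(log(libsize), length(genes), n, byrow = TRUE)
  if (config$model_mismatch_sd > 0) {
    log_mu <- log_mu + matrix(rnorm(length(log_mu), 0, config$model_mismatch_sd),
                              nrow(log_mu), ncol(log_mu))
  }
  mu <- exp(log_mu)
  counts <- if (config$nb_dispersion <= 0) {
    matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
           nrow(mu), ncol(mu))
  }
  bind_cols(tibble(gene_id = genes),
            as_tibble(setNames(as.data.frame(counts), cohort$sample_id)))
}

#' Simulate perturbagen expression profiles
#'
#' Every drug receives 2-4 dose/time conditions of standard-normal modZ
#' noise over the full gene universe. Each planted reverser drug has exactly
#' one condition in which every planted DEG's modZ opposes its aging
#' direction with magnitude deep in the outer tertile.
#'
#' @param truth Ground-truth list from [generate_true_network()].
#' @param config A [sim_config()].
#' @param genes Character vector: profile gene universe (defaults to the
#'   network gene universe recorded in the truth's DEG/CpG tables plus ids
#'   passed here by [simulate_aging_study()]).
#' @return A long profile tibble (`gene_id`, `drug`, `dose`, `time`, `modz`)
#'   plus attribute `reverser_drugs`.
#' @export
simulate_perturbation_profiles <- function(truth, config, genes) {
  stage_seed(config, "perturbation")
  if (config$n_drugs < config$n_reverser_drugs) abort_fmt("n_drugs < n_reverser_drugs")
  drugs <- sprintf("drug%02d", seq_len(config$n_drugs))
  reversers <- sample(drugs, config$n_reverser_drugs)
  doses <- c("0.1uM", "1uM", "10uM"); times <- c("6h", "24h")
  out <- purrr::map_dfr(drugs, function(d) {
    n_cond <- sample(2:4, 1)
    combos <- expand.grid(dose = doses, time = times, stringsAsFactors = FALSE)
    combos <- combos[sample.int(nrow(combos), n_cond), ]
    purrr::map_dfr(seq_len(n_cond), function(i) {
      tibble(gene_id = genes, drug = d, dose = combos$dose[i],
             time = combos$time[i], modz = rnorm(length(genes)))
    })
  })
  for (d in reversers) {
    conds <- distinct(out[out$drug == d, c("dose", "time")])
    pick <- conds[sample.int(nrow(conds), 1), ]
    sel <- out$drug == d & out$dose == pick$dose & out$time == pick$time &
      out$gene_id %in% truth$deg$gene_id
    eff <- truth$deg$lfc_per_year[match(out$gene_id[sel], truth$deg$gene_id)]
    out$modz[sel] <- -sign(eff) * runif(sum(sel), 3, 5)
  }
  attr(out, "reverser_drugs") <- reversers
  out
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper: cohort, true network and annotation, methylation,
#' expression and perturbation profiles in one call. The canonical network
#' handed to the inference pipeline is the true topology with signs removed
#' (edge direction only), as a canonical regulatory network would provide.
#'
#' @param config A [sim_config()].
#' @return A list: `cohort`, `annotation`, `beta`, `counts`,
#'   `canonical_edges` (unsigned), `network` (true signed network),
#'   `profiles`, `truth`.
#' @export
simulate_aging_study <- function(config) {
  cohort <- generate_cohort(config)
  gt <- generate_true_network(config)
  beta <- simulate_methylation(cohort, config, gt$truth)
  counts <- simulate_expression(cohort, gt$network, beta, config, gt$truth)
  profiles <- simulate_perturbation_profiles(gt$truth, config, genes = gt$network$nodes$node_id)
  canonical <- gt$network$edges %>% mutate(sign = NA_real_)
  list(cohort = cohort, annotation = gt$annotation, beta = beta,
       counts = counts, canonical_edges = canonical, network = gt$network,
       profiles = profiles, truth = c(gt$truth,
                                      list(reverser_drugs = attr(profiles, "reverser_drugs"))))
}
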