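# Aging marker identification: sex adjustment, age-correlation DMP calling
# (raw P, deliberately without multiple-testing correction, as is usual when
# CpG counts dwarf the cohort), an NB-GLM DEG caller with BH correction, the
# 5 kb DMP-to-TF linkage with representative selection, and hypergeometric
# overlap enrichment against known marker panels.

#' Adjust a beta matrix for sex
#'
#' Location-only two-group adjustment: per position, each sex group's mean is
#' shifted to the pooled mean and the result clipped back into `[0, 1]`.
#' After adjustment the per-position sex-mean difference is ~0. If either sex
#' group has fewer than 2 samples the adjustment is skipped with a warning.
#'
#' @param beta Beta tibble (`chrom`, `pos`, samples).
#' @param cohort Cohort tibble covering the samples.
#' @return Adjusted beta tibble, same shape.
#' @export
adjust_sex <- function(beta, cohort) {
  validate_cohort(cohort)
  samp <- sample_cols(beta, c("chrom", "pos"))
  missing <- setdiff(samp, cohort$sample_id)
  if (length(missing) > 0) abort_fmt("samples missing from cohort: %s", missing[1])
  sex <- cohort$sex[match(samp, cohort$sample_id)]
  if (min(table(factor(sex, levels = c("male", "female")))) < 2) {
    rlang::warn("a sex group has < 2 samples; sex adjustment skipped")
    return(beta)
  }
  m <- tbl_to_matrix(beta, c("chrom", "pos"))
  pooled <- rowMeans(m)
  for (g in unique(sex)) {
    cols <- sex == g
    m[, cols] <- m[, cols] - (rowMeans(m[, cols, drop = FALSE]) - pooled)
  }
  m2 <- matrix(pmin(1, pmax(0, m)), nrow(m), ncol(m), dimnames = dimnames(m))
  bind_cols(beta[, c("chrom", "pos")], as_tibble(as.data.frame(m2)))
}

#' Call age-associated differentially methylated positions
#'
#' Per CpG position, Pearson correlation between beta value and age, with
#' the two-sided t-transform P value. Positions with zero variance are
#' untestable and excluded (counted in the `n_untestable` attribute). No
#' multiple-testing correction is applied at this stage.
#'
#' @param beta Sex-adjusted beta tibble.
#' @param cohort Cohort tibble.
#' @param p_threshold Raw P threshold for the DMP flag (default 0.05).
#' @return Tibble (class `aging_dmp`) with `feature_id`, `chrom`, `pos`,
#'   `r`, `p`, `direction`, `is_dmp`.
#' @export
call_dmps <- function(beta, cohort, p_threshold = 0.05) {
  validate_cohort(cohort)
  samp <- sample_cols(beta, c("chrom", "pos"))
  if (length(samp) < 4) abort_fmt("need at least 4 samples to call DMPs")
  age <- cohort$age[match(samp, cohort$sample_id)]
  if (any(is.na(age))) abort_fmt("beta matrix contains samples absent from the cohort")
  m <- tbl_to_matrix(beta, c("chrom", "pos"))
  r <- row_cor(m, age)
  out <- tibble(
    feature_id = paste0(beta$chrom, ":", beta$pos),
    chrom = beta$chrom, pos = beta$pos, r = r
  )
  n_untestable <- sum(is.na(r))
  out <- filter(out, !is.na(.data$r))
  out$p <- pearson_p(out$r, length(samp))
  out$direction <- sign(out$r)
  out$is_dmp <- out$p < p_threshold
  attr(out, "n_untestable") <- n_untestable
  new_result(out, "aging_dmp")
}

# Median-of-ratios size factors (reference = geometric mean over samples,
# computed on genes expressed in every sample).
size_factors <- function(m) {
  lg <- log(m)
  ref <- rowMeans(lg)
  use <- is.finite(ref)
  if (!any(use)) abort_fmt("no gene is expressed in every sample; cannot size-normalise")
  sf <- apply(lg[use, , drop = FALSE] - ref[use], 2, function(x) exp(median(x)))
  sf / exp(mean(log(sf)))
}

#' Size-factor-normalised log2 expression
#'
#' `log2(count / size_factor + 1)` with median-of-ratios size factors; the
#' scale used for all correlation-based analyses downstream.
#'
#' @param counts Counts tibble (`gene_id`, samples).
#' @return Tibble of the same shape with normalised values.
#' @export
normalize_log2 <- function(counts) {
  m <- tbl_to_matrix(counts, "gene_id")
  sf <- size_factors(m)
  norm <- log2(sweep(m, 2, sf, "/") + 1)
  bind_cols(counts[, "gene_id"], as_tibble(as.data.frame(norm)))
}

fit_gene_nb <- function(y, age, sex_f, log_sf, disp) {
  fam <- MASS::negative.binomial(theta = 1 / disp)
  fit <- tryCatch(
    suppressWarnings(glm(y ~ age + sex_f + offset(log_sf), family = fam)),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged) {
    # dispersion fixed at 1: the NB variance is carried by theta, so the
    # Wald statistic is normal
    cf <- summary(fit, dispersion = 1)$coefficients
    return(list(beta_ln = cf["age", "Estimate"], p = cf["age", "Pr(>|z|)"],
                fallback = FALSE))
  }
  # Gaussian fallback on log2-normalised counts
  z <- log2(y / exp(log_sf) + 1)
  fit2 <- lm(z ~ age + sex_f)
  cf <- summary(fit2)$coefficients
  list(beta_ln = cf["age", "Estimate"] * log(2), p = cf["age", "Pr(>|t|)"],
       fallback = TRUE)
}

#' Call age-associated differentially expressed genes
#'
#' Per gene, a negative-binomial GLM with log link on the design
#' `~ age + sex` with a library-size offset (median-of-ratios size factors).
#' The per-gene dispersion is estimated by method of moments on normalised
#' counts (`var = mu + disp * mu^2`), floored at 1e-8. The age coefficient is
#' tested by a Wald test and P values are Benjamini-Hochberg adjusted across
#' tested genes. All-zero genes are excluded; non-converging fits fall back
#' to a Gaussian model on `log2(normalised + 1)` with a flag.
#'
#' @param counts Raw counts tibble (`gene_id`, samples).
#' @param cohort Cohort tibble.
#' @param alpha_adj Adjusted-P threshold for the DEG flag (default 0.05).
#' @return Tibble (class `aging_deg`) with `gene_id`, `lfc_per_year`
#'   (log2/year), `p`, `p_adj`, `is_deg`, `fallback`.
#' @export
call_degs <- function(counts, cohort, alpha_adj = 0.05) {
  validate_cohort(cohort)
  samp <- sample_cols(counts, "gene_id")
  if (length(samp) < 6) abort_fmt("need at least 6 samples to call DEGs")
  ord <- match(samp, cohort$sample_id)
  if (any(is.na(ord))) abort_fmt("counts contain samples absent from the cohort")
  age <- cohort$age[ord]
  sex_f <- as.numeric(cohort$sex[ord] == "female")
  m <- tbl_to_matrix(counts, "gene_id")
  keep <- rowSums(m) > 0
  n_dropped <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  ids <- counts$gene_id[keep]
  sf <- size_factors(m)
  log_sf <- log(sf)
  q <- sweep(m, 2, sf, "/")
  mu_hat <- rowMeans(q)
  v_hat <- apply(q, 1, var)
  disp <- pmax((v_hat - mu_hat) / mu_hat^2, 1e-8)

  fits <- purrr::map(seq_len(nrow(m)), function(i) {
    fit_gene_nb(m[i, ], age, sex_f, log_sf, disp[i])
  })
  out <- tibble(
    gene_id = ids,
    lfc_per_year = purrr::map_dbl(fits, "beta_ln") / log(2),
    p = pmin(purrr::map_dbl(fits, "p"), 1),
    fallback = purrr::map_lgl(fits, "fallback")
  )
  if (any(out$fallback)) {
    rlang::inform(sprintf("%d gene(s) used the Gaussian fallback fit", sum(out$fallback)))
  }
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$is_deg <- out$p_adj < alpha_adj
  attr(out, "n_dropped") <- n_dropped
  new_result(out, "aging_deg")
}

# Distance from a point to the TSS or to the gene-body interval
# [body_start, body_end), whichever is smaller; 0 inside the body.
cpg_gene_distance <- function(pos, tss, body_start, body_end) {
  d_tss <- abs(pos - tss)
  d_body <- ifelse(pos < body_start, body_start - pos,
                   ifelse(pos >= body_end, pos - body_end + 1L, 0L))
  pmin(d_tss, d_body)
}

#' Link DMPs to nearby transcription-factor genes
#'
#' Candidate pairs are DMPs whose position lies within `window` bp of a TF
#' gene's TSS or gene body (inclusive). For each candidate the Pearson
#' correlation between beta values and size-factor-normalised log2
#' expression across shared samples is computed; links with `p <
#' p_threshold` are kept, and per TF gene the link with the smallest P (ties:
#' larger `|r|`, then lexicographic DMP id) is marked `representative`.
#'
#' @param dmps `aging_dmp` tibble (rows flagged `is_dmp` are linked).
#' @param annotation Gene annotation tibble with `is_tf`.
#' @param beta Sex-adjusted beta tibble.
#' @param expression Raw counts tibble (normalised internally).
#' @param window Maximum CpG-gene distance in bp (default 5000, inclusive).
#' @param p_threshold Link significance threshold (default 0.05).
#' @return Tibble (class `dmp_tf_link`): `dmp_id`, `chrom`, `pos`,
#'   `tf_gene_id`, `distance`, `r`, `p`, `representative`.
#' @export
link_dmp_to_tf <- function(dmps, annotation, beta, expression,
                           window = 5000, p_threshold = 0.05) {
  tfs <- filter(annotation, .data$is_tf)
  dm <- filter(as_tibble(dmps), .data$is_dmp)
  norm <- normalize_log2(expression)
  shared <- intersect(sample_cols(beta, c("chrom", "pos")),
                      sample_cols(norm, "gene_id"))
  if (length(shared) < 4) abort_fmt("need >= 4 shared samples for DMP-TF linkage")
  bkey <- paste(beta$chrom, beta$pos)
  bmat <- tbl_to_matrix(beta, c("chrom", "pos"))[, shared, drop = FALSE]
  emat <- tbl_to_matrix(norm, "gene_id")[, shared, drop = FALSE]
  rownames(emat) <- norm$gene_id

  tf_tbl <- tfs %>%
    select(tf_gene_id = "gene_id", tf_chrom = "chrom", "tss", "body_start",
           "body_end")
  cand <- tidyr::crossing(
    dm %>% select(dmp_id = "feature_id", "chrom", "pos"),
    tf_tbl
  ) %>%
    filter(.data$chrom == .data$tf_chrom) %>%
    mutate(distance = cpg_gene_distance(.data$pos, .data$tss, .data$body_start,
                                        .data$body_end)) %>%
    filter(.data$distance <= window) %>%
    select(-"tf_chrom", -"tss", -"body_start", -"body_end")

  no_expr <- setdiff(unique(cand$tf_gene_id), rownames(emat))
  if (length(no_expr) > 0) {
    rlang::warn(sprintf("%d TF gene(s) without expression rows skipped", length(no_expr)))
    cand <- filter(cand, !.data$tf_gene_id %in% no_expr)
  }
  if (nrow(cand) == 0) {
    return(new_result(tibble(dmp_id = character(), chrom = character(),
                             pos = integer(), tf_gene_id = character(),
                             distance = integer(), r = double(), p = double(),
                             representative = logical()), "dmp_tf_link"))
  }
  bi <- match(paste(cand$chrom, cand$pos), bkey)
  cand$r <- purrr::map2_dbl(bi, cand$tf_gene_id, function(i, g) {
    suppressWarnings(cor(bmat[i, ], emat[g, ]))
  })
  cand <- filter(cand, !is.na(.data$r))
  cand$p <- pearson_p(cand$r, length(shared))
  links <- filter(cand, .data$p < p_threshold)
  links <- links %>%
    group_by(.data$tf_gene_id) %>%
    arrange(.data$p, desc(abs(.data$r)), .data$dmp_id, .by_group = TRUE) %>%
    mutate(representative = row_number() == 1) %>%
    ungroup() %>%
    select("dmp_id", "chrom", "pos", "tf_gene_id", "distance", "r", "p",
           "representative")
  new_result(links, "dmp_tf_link")
}

#' Hypergeometric overlap enrichment
#'
#' Upper-tail probability `P(X >= k)` for drawing `selected_n` features from
#' a population of `population_n` containing `marker_n` members of a known
#' marker panel and observing `overlap_k` of them, computed in log space so
#' extreme enrichments do not underflow.
#'
#' @param population_n Population size N.
#' @param marker_n Number of panel markers K in the population.
#' @param selected_n Number of selected features n.
#' @param overlap_k Observed overlap k.
#' @return A one-row tibble: `population_n`, `marker_n`, `selected_n`,
#'   `overlap_k`, `p`, `log10_p`.
#' @export
#' @examples
#' overlap_enrichment(2682537, 32, 222032, 32)
overlap_enrichment <- function(population_n, marker_n, selected_n, overlap_k) {
  if (overlap_k > min(marker_n, selected_n) || selected_n > population_n ||
      marker_n > population_n || any(c(population_n, marker_n, selected_n, overlap_k) < 0)) {
    abort_fmt("inconsistent counts for hypergeometric enrichment")
  }
  log_p <- phyper(overlap_k - 1, marker_n, population_n - marker_n, selected_n,
                  lower.tail = FALSE, log.p = TRUE)
  tibble(population_n = population_n, marker_n = marker_n,
         selected_n = selected_n, overlap_k = overlap_k,
         p = exp(log_p), log10_p = log_p / log(10))
}
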