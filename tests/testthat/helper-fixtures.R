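# Shared fixtures. The default simulated study is cached per test session so
# several test files can reuse it without re-simulating.

fixture_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_aging_study(sim_config(seed = 777))
    }
    cache
  }
})

fixture_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- fixture_study()
      cache <<- suppressMessages(suppressWarnings(
        run_aging_pipeline(sim$cohort, sim$beta, sim$counts, sim$annotation,
                           sim$canonical_edges, profiles = sim$profiles)))
    }
    cache
  }
})

# small deterministic beta tibble: n_pos x samples
toy_beta <- function(values, samples = paste0("S", seq_len(ncol(values))),
                     chrom = "chr1", pos = seq_len(nrow(values)) * 100L) {
  out <- tibble::as_tibble(as.data.frame(values))
  names(out) <- samples
  dplyr::bind_cols(tibble::tibble(chrom = chrom, pos = pos), out)
}

toy_cohort <- function(n, ages = seq(20, 74, length.out = n),
                       sexes = rep(c("male", "female"), length.out = n)) {
  tibble::tibble(sample_id = paste0("S", seq_len(n)), age = ages, sex = sexes,
                 smoking = "non_smoker")
}

# counts tibble from a matrix of means (Poisson noise), for network tests
toy_counts <- function(mu, gene_ids = rownames(mu),
                       samples = paste0("S", seq_len(ncol(mu)))) {
  k <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
  out <- tibble::as_tibble(as.data.frame(k))
  names(out) <- samples
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), out)
}

true_dmp_ids <- function(sim) {
  with(sim$truth$cpg[sim$truth$cpg$is_dmp, ], paste0(chrom, ":", pos))
}
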