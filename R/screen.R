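# Connectivity-map style screening: per-condition percentile transform of
# modZ scores, outer-tertile up/down calls, reversal counting against the
# aging DEG signature, and per-drug best-condition selection with the
# strict more-than-half candidate rule.

#' Percentile transform of a modZ vector
#'
#' `percentile = 100 * (rank - 0.5) / G` with average ranks for ties, rank
#' ascending in modZ, applied within one condition across its gene universe.
#' The transform depends only on ranks, so it is invariant under any
#' strictly monotone transform of the scores.
#'
#' @param modz Numeric vector of per-gene scores for one condition (>= 2).
#' @return Percentiles in `[0, 100]`; an all-equal vector maps to all 50
#'   with a warning.
#' @export
percentile_transform <- function(modz) {
  if (length(modz) < 2) abort_fmt("need at least 2 genes for percentiles")
  if (length(unique(modz)) == 1) {
    rlang::warn("all modZ values equal; percentiles set to 50")
    return(rep(50, length(modz)))
  }
  100 * (rank(modz, ties.method = "average") - 0.5) / length(modz)
}

#' Tertile up/down/null call
#'
#' `up` when the percentile is at or above the upper tertile boundary,
#' `down` at or below the lower boundary, `null` otherwise (boundaries
#' inclusive).
#'
#' @param percentiles Numeric vector in `[0, 100]`.
#' @param lower_tertile,upper_tertile Boundaries (defaults 100/3 and 200/3).
#' @return Character vector of calls in `{"up", "down", "null"}`.
#' @export
tertile_call <- function(percentiles, lower_tertile = 100 / 3,
                         upper_tertile = 200 / 3) {
  stopifnot(lower_tertile > 0, lower_tertile < upper_tertile, upper_tertile < 100)
  case_when(percentiles >= upper_tertile ~ "up",
            percentiles <= lower_tertile ~ "down",
            TRUE ~ "null")
}

#' Count signature reversals in one condition
#'
#' A signature gene is reversed when its aging direction is up and the
#' condition calls it down, or vice versa; `null` calls never reverse.
#'
#' @param calls Named character vector of tertile calls (names = gene ids).
#' @param signature Named numeric vector of aging directions (+1/-1) for the
#'   DEG signature.
#' @return A list: `n_screenable` (signature genes present in the call
#'   universe) and `n_reversed`.
#' @export
count_reversals <- function(calls, signature) {
  shared <- intersect(names(signature), names(calls))
  if (length(shared) == 0) {
    rlang::warn("signature does not intersect the profile gene universe")
    return(list(n_screenable = 0L, n_reversed = 0L))
  }
  sig <- signature[shared]
  cl <- calls[shared]
  rev <- (sig > 0 & cl == "down") | (sig < 0 & cl == "up")
  list(n_screenable = length(shared), n_reversed = sum(rev))
}

#' Screen perturbagen profiles for aging-signature reversal
#'
#' Each condition's modZ vector is percentile-transformed over its gene
#' universe and tertile-called; reversals against the DEG signature are
#' counted. Per drug, the condition reversing the most DEGs is kept (ties:
#' larger summed distance of reversed genes from the 50th percentile, then
#' lexicographic condition label). A drug is a candidate when its best
#' condition reverses strictly more than half of the screenable DEGs.
#'
#' @param profiles Long profile tibble (`gene_id`, `drug`, `dose`, `time`,
#'   `modz`) as from [read_perturbation_profiles()].
#' @param signature Named numeric vector of aging directions (+1/-1), e.g.
#'   `sign(lfc_per_year)` of the validated DEG markers.
#' @param lower_tertile,upper_tertile Tertile boundaries.
#' @return Tibble (class `drug_screen`), one row per drug: `drug`,
#'   `best_dose`, `best_time`, `n_screenable`, `n_reversed`, `candidate`,
#'   ordered by `n_reversed` descending.
#' @export
screen_drugs <- function(profiles, signature, lower_tertile = 100 / 3,
                         upper_tertile = 200 / 3) {
  stopifnot(length(signature) > 0, !is.null(names(signature)))
  per_cond <- profiles %>%
    group_by(.data$drug, .data$dose, .data$time) %>%
    summarise(res = {
      pct <- percentile_transform(.data$modz)
      calls <- setNames(tertile_call(pct, lower_tertile, upper_tertile),
                        .data$gene_id)
      cr <- count_reversals(calls, signature)
      shared <- intersect(names(signature), .data$gene_id)
      pct_named <- setNames(pct, .data$gene_id)[shared]
      rev_mask <- (signature[shared] > 0 & calls[shared] == "down") |
        (signature[shared] < 0 & calls[shared] == "up")
      list(tibble(n_screenable = cr$n_screenable, n_reversed = cr$n_reversed,
                  tie_mass = sum(abs(pct_named[rev_mask] - 50))))
    }, .groups = "drop") %>%
    tidyr::unnest("res")
  best <- per_cond %>%
    mutate(cond_label = paste(.data$dose, .data$time, sep = "|")) %>%
    group_by(.data$drug) %>%
    arrange(desc(.data$n_reversed), desc(.data$tie_mass), .data$cond_label,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    mutate(candidate = .data$n_reversed > .data$n_screenable / 2) %>%
    select("drug", best_dose = "dose", best_time = "time", "n_screenable",
           "n_reversed", "candidate") %>%
    arrange(desc(.data$n_reversed), .data$drug)
  new_result(best, "drug_screen")
}
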