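# Readers and writers for the pipeline's on-disk artifacts. All tables are
# plain TSV; genomic coordinates are 0-based half-open (BED convention) both
# on disk and in memory. Readers are strict: malformed values fail with the
# offending row named, so data issues surface at the boundary.

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read a methylation beta-value matrix
#'
#' The file is a TSV whose first two columns are `chrom` and `pos` (CpG
#' position) followed by one numeric column per sample holding beta values in
#' `[0, 1]`. Rows are returned sorted by position within chromosome.
#'
#' @param path Path to the TSV file.
#' @param annotation_mode Coordinate convention of the `pos` column:
#'   `"0-based"` (default, stored as-is) or `"1-based"` (converted to 0-based
#'   on read). This is the only place 1-based input is accepted.
#' @return A tibble with columns `chrom`, `pos` and one column per sample.
#' @export
read_beta_matrix <- function(path, annotation_mode = c("0-based", "1-based")) {
  annotation_mode <- match.arg(annotation_mode)
  tbl <- read_tsv_quiet(path)
  if (!identical(names(tbl)[1:2], c("chrom", "pos"))) {
    abort_fmt("beta matrix must start with columns 'chrom' and 'pos', got: %s",
              paste(head(names(tbl), 2), collapse = ", "))
  }
  if (annotation_mode == "1-based") tbl$pos <- tbl$pos - 1L
  samp <- sample_cols(tbl, c("chrom", "pos"))
  if (length(samp) == 0) abort_fmt("beta matrix has no sample columns")
  m <- tbl_to_matrix(tbl, c("chrom", "pos"))
  bad <- which(is.na(m) | m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_fmt("beta value outside [0,1] (or missing) at file row %d, sample '%s'",
              bad[1, 1], samp[bad[1, 2]])
  }
  if (anyDuplicated(tbl[, c("chrom", "pos")])) {
    dup <- tbl[duplicated(tbl[, c("chrom", "pos")]), ]
    abort_fmt("duplicate CpG position: %s:%d", dup$chrom[1], dup$pos[1])
  }
  dplyr::arrange(tbl, .data$chrom, .data$pos)
}

#' Write a methylation beta-value matrix
#'
#' @param beta Tibble as returned by [read_beta_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  readr::write_tsv(beta, path, progress = FALSE)
  invisible(path)
}

#' Read an expression count matrix
#'
#' TSV with a `gene_id` column followed by one non-negative integer column per
#' sample.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `gene_id` and one column per sample.
#' @export
read_counts_matrix <- function(path) {
  tbl <- read_tsv_quiet(path)
  if (names(tbl)[1] != "gene_id") abort_fmt("counts matrix must start with 'gene_id'")
  if (anyDuplicated(tbl$gene_id)) abort_fmt("duplicate gene_id in counts matrix")
  m <- tbl_to_matrix(tbl, "gene_id")
  if (any(is.na(m) | m < 0 | m != round(m))) {
    bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
    abort_fmt("counts must be non-negative integers; offending gene '%s'",
              tbl$gene_id[bad[1, 1]])
  }
  tbl
}

#' @rdname read_counts_matrix
#' @param counts Tibble as returned by [read_counts_matrix()].
#' @param path Output TSV path.
#' @export
write_counts_matrix <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read a cohort table
#'
#' TSV with columns `sample_id`, `age` (years), `sex` (`male`/`female`) and
#' optionally `smoking` (`smoker`/`non_smoker`/`unknown`).
#'
#' @param path Path to the TSV file.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  tbl <- read_tsv_quiet(path)
  if (!"smoking" %in% names(tbl)) tbl$smoking <- "unknown"
  validate_cohort(tbl)
  tbl
}

#' @rdname read_cohort
#' @param cohort Cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Read a gene annotation table (BED6+2)
#'
#' Columns: `chrom`, `start`, `end` (0-based half-open gene body), `gene_id`,
#' `score` (ignored, kept for BED compatibility), `strand`, `tss` (0-based),
#' `is_tf` (0/1 or TRUE/FALSE).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `body_start`,
#'   `body_end`, `strand`, `is_tf`.
#' @export
read_gene_annotation <- function(path) {
  tbl <- read_tsv_quiet(path,
    col_names = c("chrom", "start", "end", "gene_id", "score", "strand", "tss", "is_tf"))
  if (is.character(tbl$start)) abort_fmt("annotation file must not have a header row")
  if (any(tbl$start >= tbl$end)) abort_fmt("annotation requires body_start < body_end")
  if (anyDuplicated(tbl$gene_id)) abort_fmt("duplicate gene_id in annotation")
  if (!all(tbl$strand %in% c("+", "-"))) abort_fmt("strand must be '+' or '-'")
  tibble(
    gene_id = tbl$gene_id, chrom = tbl$chrom, tss = as.integer(tbl$tss),
    body_start = as.integer(tbl$start), body_end = as.integer(tbl$end),
    strand = tbl$strand, is_tf = as.logical(tbl$is_tf)
  )
}

#' @rdname read_gene_annotation
#' @param annotation Annotation tibble (internal schema).
#' @export
write_gene_annotation <- function(annotation, path) {
  out <- tibble(
    chrom = annotation$chrom, start = annotation$body_start,
    end = annotation$body_end, gene_id = annotation$gene_id, score = 0L,
    strand = annotation$strand, tss = annotation$tss,
    is_tf = as.integer(annotation$is_tf)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

normalize_sign <- function(x) {
  lut <- c("-1" = -1, "+1" = 1, "1" = 1, "activates" = 1, "inhibits" = -1)
  out <- unname(lut[as.character(x)])
  if (any(is.na(out))) {
    abort_fmt("unknown edge sign token: '%s'", as.character(x)[is.na(out)][1])
  }
  as.numeric(out)
}

#' Read a GRN edge list
#'
#' Accepts either a headerless TSV (`source`, `target`, optional `sign`) or a
#' SIF file (`source relation target`, relation in `activates`/`inhibits`).
#' Sign tokens `-1`/`+1`/`activates`/`inhibits` are normalised to integers
#' `-1`/`+1` at parse time. Parallel duplicate edges are collapsed keeping the
#' first occurrence, with a warning; self-loops are retained here (they are
#' removed during network reconstruction).
#'
#' @param path Path to the edge file.
#' @param dialect `"tsv"` or `"sif"`.
#' @return A tibble with columns `source`, `target`, `sign` (`NA` if the file
#'   carries no signs).
#' @export
read_grn_edges <- function(path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, if (dialect == "tsv") "\t" else "[[:space:]]+")
  n_field <- lengths(parts)
  if (dialect == "sif") {
    if (any(n_field < 3)) abort_fmt("SIF lines need 'source relation target'")
    edges <- purrr::map_dfr(parts, function(p) {
      tibble(source = p[1], target = p[3:length(p)], sign = normalize_sign(p[2]))
    })
  } else {
    if (any(!n_field %in% c(2, 3))) abort_fmt("edge TSV must have 2 or 3 columns")
    edges <- tibble(
      source = purrr::map_chr(parts, 1),
      target = purrr::map_chr(parts, 2),
      sign = if (all(n_field == 3)) normalize_sign(purrr::map_chr(parts, 3)) else NA_real_
    )
  }
  dup <- duplicated(edges[, c("source", "target")])
  if (any(dup)) {
    rlang::warn(sprintf("%d duplicate edge(s) collapsed (first occurrence kept)", sum(dup)))
    edges <- edges[!dup, ]
  }
  edges
}

#' @rdname read_grn_edges
#' @param edges Edge tibble with `source`, `target`, `sign`.
#' @export
write_grn_edges <- function(edges, path) {
  out <- edges[, c("source", "target")]
  if (!all(is.na(edges$sign))) out$sign <- sprintf("%+d", as.integer(edges$sign))
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read perturbation expression profiles (GCT-like TSV)
#'
#' A `gene_id` column followed by one column per perturbation condition, each
#' named `drug|dose|time` and holding moderated Z (modZ) differential
#' expression scores.
#'
#' @param path Path to the TSV file.
#' @return A long tibble with columns `gene_id`, `drug`, `dose`, `time`,
#'   `modz`; every condition covers the same gene universe.
#' @export
read_perturbation_profiles <- function(path) {
  tbl <- read_tsv_quiet(path)
  if (names(tbl)[1] != "gene_id") abort_fmt("perturbation file must start with 'gene_id'")
  cond <- sample_cols(tbl, "gene_id")
  meta <- strsplit(cond, "|", fixed = TRUE)
  bad <- which(lengths(meta) != 3)
  if (length(bad) > 0) {
    abort_fmt("condition label '%s' is not of the form drug|dose|time", cond[bad[1]])
  }
  long <- tidyr::pivot_longer(tbl, -"gene_id", names_to = "condition", values_to = "modz")
  long <- tidyr::separate(long, "condition", into = c("drug", "dose", "time"), sep = "\\|")
  if (any(is.na(long$modz))) abort_fmt("missing modZ value in perturbation file")
  long[, c("gene_id", "drug", "dose", "time", "modz")]
}

#' @rdname read_perturbation_profiles
#' @param profiles Long profile tibble (`gene_id`, `drug`, `dose`, `time`, `modz`).
#' @export
write_perturbation_profiles <- function(profiles, path) {
  wide <- profiles %>%
    mutate(condition = paste(.data$drug, .data$dose, .data$time, sep = "|")) %>%
    select("gene_id", "condition", "modz") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "modz")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
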