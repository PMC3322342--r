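#' Filter configuration
#'
#' @param alpha FDR significance threshold (strict `p_adj < alpha`);
#'   default 0.01, the 1% FDR cutoff used throughout the analysis.
#' @param intensity_threshold baseline-intensity gate on the linear scale
#'   (strict `mean log2 intensity > log2(threshold)`); default 64, i.e.
#'   log2(intensity) > 6.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(alpha = 0.01, intensity_threshold = 64) {
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (alpha >= 1)
    stop("'alpha' must be < 1", call. = FALSE)
  assert_scalar_number(intensity_threshold, "intensity_threshold",
                       lower = 0, strict_lower = TRUE)
  structure(list(alpha = alpha, intensity_threshold = intensity_threshold),
            class = "filter_config")
}

check_de_columns <- function(de, cols, what = "DE table") {
  missing <- setdiff(cols, names(de))
  if (length(missing) > 0L)
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(de)
}

#' Select significantly enriched genes in one direction
#'
#' @param de DE table with `gene_id`, `M`, `p_adj` columns.
#' @param alpha FDR threshold; inclusion requires `p_adj < alpha`
#'   (strict).
#' @param direction `"positive"` (M > 0) or `"negative"` (M < 0).
#' @return Character vector of gene ids.
#' @export
select_enriched <- function(de, alpha = 0.01,
                            direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  check_de_columns(de, c("gene_id", "M", "p_adj"))
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       strict_lower = TRUE)
  keep <- de$p_adj < alpha &
    (if (direction == "positive") de$M > 0 else de$M < 0)
  de$gene_id[keep]
}

#' Baseline-intensity gate
#'
#' Genes whose mean log2 intensity in the named group strictly exceeds
#' `log2(threshold)` (default: intensity > 64, i.e. log2 intensity > 6).
#'
#' @param de DE table with a `mean_<which_group>` log2-intensity column.
#' @param which_group group/tissue label (e.g. `"germarium"`).
#' @param threshold linear-scale intensity threshold; default 64.
#' @return Character vector of gene ids passing the gate.
#' @export
mean_intensity_pass <- function(de, which_group, threshold = 64) {
  check_de_columns(de, "gene_id")
  col <- paste0("mean_", which_group)
  if (!col %in% names(de)) {
    available <- sub("^mean_", "", grep("^mean_", names(de), value = TRUE))
    stop(sprintf("unknown group '%s'; groups with intensity columns: %s",
                 which_group,
                 if (length(available)) paste(available, collapse = ", ")
                 else "(none)"), call. = FALSE)
  }
  assert_scalar_number(threshold, "threshold", lower = 0,
                       strict_lower = TRUE)
  de$gene_id[de[[col]] > log2(threshold)]
}

#' Rank genes by a score
#'
#' Rank 1 is the most extreme value in the requested order; ties receive
#' the average of the tied rank positions.
#'
#' @param values named numeric vector (names = gene ids).
#' @param order `"descending"` (largest value gets rank 1) or
#'   `"ascending"`.
#' @return Named numeric vector of ranks.
#' @export
rank_by <- function(values, order = c("descending", "ascending")) {
  order <- match.arg(order)
  if (any(!is.finite(values))) {
    bad <- names(values)[which(!is.finite(values))[1L]] %||% "(unnamed)"
    stop(sprintf("non-finite value for gene %s", bad), call. = FALSE)
  }
  r <- if (order == "descending") rank(-values, ties.method = "average")
       else rank(values, ties.method = "average")
  names(r) <- names(values)
  r
}

# Assemble a ranked gene list: order by rank sum (ascending), break ties
# lexicographically by gene_id, and attach provenance.
ranked_gene_list <- function(gene_ids, component_ranks, extra_cols,
                             filter_name, config) {
  rank_sum <- Reduce(`+`, component_ranks)
  ord <- order(rank_sum, gene_ids)
  entries <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  for (nm in names(component_ranks))
    entries[[paste0("rank_", nm)]] <- component_ranks[[nm]]
  entries$rank_sum <- rank_sum
  for (nm in names(extra_cols)) entries[[nm]] <- extra_cols[[nm]]
  entries <- entries[ord, , drop = FALSE]
  entries$final_position <- seq_len(nrow(entries))
  rownames(entries) <- NULL
  structure(entries,
            class = c("ranked_gene_list", "data.frame"),
            filter = filter_name,
            config = unclass(config))
}

de_named <- function(de, col) {
  stats::setNames(de[[col]], de$gene_id)
}

shared_universe <- function(...) {
  tables <- list(...)
  for (de in tables) check_de_columns(de, c("gene_id", "M", "p_adj"))
  universe <- Reduce(intersect, lapply(tables, `[[`, "gene_id"))
  if (length(universe) == 0L)
    stop("the DE tables share no genes; cannot intersect datasets",
         call. = FALSE)
  universe
}

#' Genes enriched in both female and male GSCs ("shared GSC" filter)
#'
#' Inclusion requires significance and positive direction in both
#' stem-cell comparisons (female GSC vs Kc; Os+ bgcn- vs bgcn-) plus the
#' baseline-intensity gate in both tissues of the two-color comparison.
#' Included genes are ranked by M (descending) separately in the two
#' stem-cell datasets and ordered by the sum of those ranks.
#'
#' @param de_female_gsc DE table of the female GSC vs Kc comparison
#'   (positive M = GSC-enriched).
#' @param de_male_gsc DE table of the Os+ bgcn- vs bgcn- comparison
#'   (positive M = Os+ bgcn- -enriched).
#' @param de_tissue DE table of the germarium vs testis-apex comparison
#'   (positive M = germarium-enriched) with `mean_germarium` and
#'   `mean_testis_apex` intensity columns.
#' @param config a [filter_config()].
#' @return A `ranked_gene_list` data.frame: `gene_id`, component ranks,
#'   `rank_sum`, contributing M / adjusted-p columns, `final_position`.
#' @export
filter_shared_gsc <- function(de_female_gsc, de_male_gsc, de_tissue,
                              config = filter_config()) {
  universe <- shared_universe(de_female_gsc, de_male_gsc, de_tissue)
  check_de_columns(de_tissue, c("mean_germarium", "mean_testis_apex"),
                   "tissue DE table")
  included <- Reduce(intersect, list(
    select_enriched(de_female_gsc, config$alpha, "positive"),
    select_enriched(de_male_gsc, config$alpha, "positive"),
    mean_intensity_pass(de_tissue, "germarium", config$intensity_threshold),
    mean_intensity_pass(de_tissue, "testis_apex", config$intensity_threshold),
    universe))
  included <- sort(included)
  m_f <- de_named(de_female_gsc, "M")[included]
  m_m <- de_named(de_male_gsc, "M")[included]
  ranks <- list(female_gsc = rank_by(m_f, "descending"),
                male_gsc = rank_by(m_m, "descending"))
  extras <- list(
    M_female_gsc = unname(m_f),
    p_adj_female_gsc = unname(de_named(de_female_gsc, "p_adj")[included]),
    M_male_gsc = unname(m_m),
    p_adj_male_gsc = unname(de_named(de_male_gsc, "p_adj")[included]),
    M_tissue = unname(de_named(de_tissue, "M")[included]))
  ranked_gene_list(included, ranks, extras, "shared_gsc", config)
}

#' Genes enriched in the germarium but not in female GSCs
#'
#' Inclusion: significantly germarium-enriched in the tissue comparison,
#' minus genes significantly GSC-enriched in the female GSC vs Kc
#' comparison. Ordered by germarium-direction M, descending.
#'
#' @inheritParams filter_shared_gsc
#' @return A `ranked_gene_list` data.frame.
#' @export
filter_germarium_not_gsc <- function(de_tissue, de_female_gsc,
                                     config = filter_config()) {
  universe <- shared_universe(de_tissue, de_female_gsc)
  included <- setdiff(
    select_enriched(de_tissue, config$alpha, "positive"),
    select_enriched(de_female_gsc, config$alpha, "positive"))
  included <- sort(intersect(included, universe))
  m_t <- de_named(de_tissue, "M")[included]
  ranks <- list(tissue = rank_by(m_t, "descending"))
  extras <- list(
    M_tissue = unname(m_t),
    p_adj_tissue = unname(de_named(de_tissue, "p_adj")[included]),
    M_female_gsc = unname(de_named(de_female_gsc, "M")[included]),
    p_adj_female_gsc = unname(de_named(de_female_gsc, "p_adj")[included]))
  ranked_gene_list(included, ranks, extras, "germarium_not_gsc", config)
}

#' Genes enriched in the testis apex but not in male GSCs/gonialblasts
#'
#' Inclusion: significantly testis-enriched in the tissue comparison,
#' minus genes significantly enriched in the Os+ bgcn- vs bgcn-
#' comparison. Included genes are ranked by absolute tissue M
#' (descending) and by M in the stem-cell comparison ascending (so
#' bgcn- -enriched, i.e. later-differentiating, genes come first); the
#' final order is the ascending sum of the two ranks.
#'
#' @inheritParams filter_shared_gsc
#' @return A `ranked_gene_list` data.frame.
#' @export
filter_testis_not_gsc <- function(de_tissue, de_male_gsc,
                                  config = filter_config()) {
  universe <- shared_universe(de_tissue, de_male_gsc)
  included <- setdiff(
    select_enriched(de_tissue, config$alpha, "negative"),
    select_enriched(de_male_gsc, config$alpha, "positive"))
  included <- sort(intersect(included, universe))
  m_t <- de_named(de_tissue, "M")[included]
  m_m <- de_named(de_male_gsc, "M")[included]
  ranks <- list(tissue_abs_m = rank_by(abs(m_t), "descending"),
                male_gsc = rank_by(m_m, "ascending"))
  extras <- list(
    M_tissue = unname(m_t),
    p_adj_tissue = unname(de_named(de_tissue, "p_adj")[included]),
    M_male_gsc = unname(m_m),
    p_adj_male_gsc = unname(de_named(de_male_gsc, "p_adj")[included]))
  ranked_gene_list(included, ranks, extras, "testis_not_gsc", config)
}
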