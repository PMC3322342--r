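#' Full-pipeline configuration
#'
#' Bundles all stage configurations. The defaults reproduce the design
#' shape of the study: four two-color replicate arrays comparing germarium
#' to testis apex with two dye flips, plus two three-vs-three
#' single-channel experiments, a 1% FDR cutoff and a 64-intensity
#' baseline gate.
#'
#' @param atlas an [atlas_config()].
#' @param mixtures named list of [mixture_design()]s with elements
#'   `germarium`, `testis_apex`, `female_gsc`, `kc`, `os_bgcn`, `bgcn`.
#' @param two_color list: `n_reps`, `n_flips`, `noise_log2_sd`,
#'   `dye_bias_coeffs` (ascending polynomial in A).
#' @param single_channel list: `n_per_group`, `noise_log2_sd`.
#' @param loess list: `span`, `iterations` for [loess_normalize()].
#' @param filters a [filter_config()].
#' @param enrichment list: `n_terms`, `term_size_range`, `purity`.
#' @param seed root seed; every stage derives its own stream from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(atlas = atlas_config(),
                       mixtures = default_mixtures(),
                       two_color = list(n_reps = 4, n_flips = 2,
                                        noise_log2_sd = 0.35,
                                        dye_bias_coeffs = c(3.02, -0.46, 0.02)),
                       single_channel = list(n_per_group = 3,
                                             noise_log2_sd = 0.15),
                       loess = list(span = 0.3, iterations = 3),
                       filters = filter_config(),
                       enrichment = list(n_terms = 200,
                                         term_size_range = c(10, 100),
                                         purity = 0.9),
                       seed = 1) {
  if (!inherits(atlas, "atlas_config"))
    stop("'atlas' must be an atlas_config", call. = FALSE)
  needed <- c("germarium", "testis_apex", "female_gsc", "kc",
              "os_bgcn", "bgcn")
  missing <- setdiff(needed, names(mixtures))
  if (length(missing) > 0L)
    stop(sprintf("'mixtures' is missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!inherits(filters, "filter_config"))
    stop("'filters' must be a filter_config", call. = FALSE)
  assert_count(seed, "seed")
  structure(
    list(atlas = atlas, mixtures = mixtures, two_color = two_color,
         single_channel = single_channel, loess = loess, filters = filters,
         enrichment = enrichment, seed = as.integer(seed)),
    class = "run_config")
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Write a table as TSV with stable numeric formatting
#'
#' Numeric columns are serialized as decimal text with 12 significant
#' digits so that repeated runs produce byte-identical files and content
#' hashes are portable. First column must be `gene_id` with unique values
#' (enforced on read).
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 12, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV table with schema validation
#'
#' @param path input path (TSV with a header; first column `gene_id`).
#' @param required character vector of column names that must be present.
#' @return data.frame.
#' @export
read_table <- function(path, required = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) == 0L || names(df)[1L] != "gene_id")
    stop(sprintf("'%s': first column must be gene_id", path), call. = FALSE)
  if (anyDuplicated(df$gene_id)) {
    dup <- df$gene_id[duplicated(df$gene_id)][1L]
    stop(sprintf("'%s': duplicate gene_id '%s'", path, dup), call. = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("'%s' is missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Precision/recall of a ranked list against a planted truth set
#'
#' @param list a `ranked_gene_list` (or a character vector of gene ids in
#'   ranked order).
#' @param truth nonempty character vector: the planted truth gene set.
#' @return list: `precision` (1.0 with `degenerate = TRUE` for an empty
#'   list), `recall`, `precision_at_k` for k in 10/25/50/list size
#'   (restricted to k <= list size), `list_size`, `truth_size`,
#'   `degenerate`.
#' @export
evaluate_recovery <- function(list, truth) {
  if (length(truth) == 0L)
    stop("'truth' must be a nonempty gene set", call. = FALSE)
  ids <- if (is.data.frame(list)) list$gene_id else as.character(list)
  n <- length(ids)
  hit <- ids %in% truth
  degenerate <- n == 0L
  precision <- if (degenerate) 1.0 else mean(hit)
  recall <- sum(hit) / length(truth)
  ks <- unique(pmin(c(10L, 25L, 50L, n), n))
  ks <- ks[ks > 0L]
  p_at_k <- stats::setNames(
    vapply(ks, function(k) mean(hit[seq_len(k)]), 0),
    as.character(ks))
  list(precision = precision, recall = recall, precision_at_k = p_at_k,
       list_size = n, truth_size = length(truth), degenerate = degenerate)
}

ranked_list_output <- function(rl, truth_class_map = NULL) {
  out <- as.data.frame(rl)
  if (!is.null(truth_class_map))
    out$truth_class <- unname(truth_class_map[out$gene_id])
  out
}

#' Run the full pipeline: simulate, normalize, test, integrate, enrich
#'
#' Executes every stage in order on synthetic data with planted ground
#' truth, writes all intermediate and final tables as TSV under `outdir`,
#' evaluates recovery of each filter list against its planted truth class,
#' and writes a JSON manifest containing the configuration, seed, and an
#' MD5 content hash of every output file. Fully deterministic for a fixed
#' seed. Stage progress is logged to standard error.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed).
#' @return The manifest, invisibly (list with `files`, `seed`,
#'   `recovery`, `concordance`, `n_significant`).
#' @export
run_all <- function(config = run_config(), outdir) {
  if (!inherits(config, "run_config"))
    stop("'config' must be a run_config", call. = FALSE)
  if (missing(outdir) || !is.character(outdir) || length(outdir) != 1L)
    stop("'outdir' must be a single directory path", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write_table(df, p)
    paths[[name]] <<- p
    p
  }

  # --- simulate -----------------------------------------------------------
  log_stage("simulate", "building atlas (%d genes, seed %d)",
            config$atlas$n_genes, seed)
  acfg <- config$atlas
  acfg$seed <- stage_seed(seed, "atlas")
  atlas <- build_atlas(acfg)
  truth <- truth_sets(atlas)
  truth_map <- stats::setNames(atlas$truth_class, atlas$gene_ids)
  atlas_df <- data.frame(gene_id = atlas$gene_ids,
                         atlas$true_expression,
                         truth_class = atlas$truth_class,
                         stringsAsFactors = FALSE, check.names = FALSE)
  emit(atlas_df, "atlas.tsv")

  tc <- config$two_color
  arrays <- simulate_two_color(
    atlas, config$mixtures$germarium, config$mixtures$testis_apex,
    n_reps = tc$n_reps, n_flips = tc$n_flips,
    noise_log2_sd = tc$noise_log2_sd,
    dye_bias_coeffs = tc$dye_bias_coeffs,
    seed = stage_seed(seed, "two_color"))
  log_stage("simulate", "%d two-color arrays (%d dye-flipped)",
            tc$n_reps, tc$n_flips)
  arrays_df <- data.frame(gene_id = atlas$gene_ids, stringsAsFactors = FALSE)
  for (a in arrays) {
    arrays_df[[sprintf("ch1_rep%d", a$replicate_id)]] <- a$intensity_ch1
    arrays_df[[sprintf("ch2_rep%d", a$replicate_id)]] <- a$intensity_ch2
  }
  emit(arrays_df, "two_color_raw.tsv")

  sc <- config$single_channel
  e2 <- simulate_single_channel(
    atlas, list(female_gsc = config$mixtures$female_gsc,
                kc = config$mixtures$kc),
    n_per_group = sc$n_per_group, noise_log2_sd = sc$noise_log2_sd,
    experiment_tag = "female_gsc_vs_kc",
    seed = stage_seed(seed, "female_gsc"))
  e3 <- simulate_single_channel(
    atlas, list(os_bgcn = config$mixtures$os_bgcn,
                bgcn = config$mixtures$bgcn),
    n_per_group = sc$n_per_group, noise_log2_sd = sc$noise_log2_sd,
    experiment_tag = "os_bgcn_vs_bgcn",
    seed = stage_seed(seed, "os_bgcn"))
  emit(data.frame(gene_id = atlas$gene_ids, e2$matrix,
                  check.names = FALSE), "female_gsc_vs_kc_raw.tsv")
  emit(data.frame(gene_id = atlas$gene_ids, e3$matrix,
                  check.names = FALSE), "os_bgcn_vs_bgcn_raw.tsv")

  # --- normalize ----------------------------------------------------------
  ma_raw <- ma_table(arrays)
  ma <- loess_normalize(ma_raw, span = config$loess$span,
                        iterations = config$loess$iterations)
  log_stage("normalize", "loess-normalized %d replicates (span %g)",
            ncol(ma$M), config$loess$span)
  ma_df <- data.frame(gene_id = ma$gene_ids, check.names = FALSE)
  for (j in seq_len(ncol(ma$M))) {
    ma_df[[paste0("M_", colnames(ma$M)[j])]] <- ma$M[, j]
    ma_df[[paste0("A_", colnames(ma$A)[j])]] <- ma$A[, j]
  }
  emit(ma_df, "ma_normalized.tsv")

  conc_g <- replicate_concordance(ma$log2_germarium)
  conc_t <- replicate_concordance(ma$log2_testis)
  log_stage("normalize",
            "replicate concordance: germarium R=%.3f (%.3f-%.3f), testis R=%.3f (%.3f-%.3f)",
            conc_g$mean, conc_g$min, conc_g$max,
            conc_t$mean, conc_t$min, conc_t$max)
  conc_df <- data.frame(
    tissue = c("germarium", "testis_apex"),
    mean_r = c(conc_g$mean, conc_t$mean),
    min_r = c(conc_g$min, conc_t$min),
    max_r = c(conc_g$max, conc_t$max))
  p <- file.path(outdir, "replicate_concordance.tsv")
  write_table(conc_df, p)
  paths[["replicate_concordance.tsv"]] <- p

  # --- differential expression -------------------------------------------
  de_e1 <- de_two_color(ma)
  de_e2 <- de_two_group(e2, positive_group = "female_gsc")
  de_e3 <- de_two_group(e3, positive_group = "os_bgcn")
  n_sig <- c(tissue = sum(de_e1$p_adj < config$filters$alpha),
             female_gsc = sum(de_e2$p_adj < config$filters$alpha),
             male_gsc = sum(de_e3$p_adj < config$filters$alpha))
  log_stage("de", "significant genes at FDR<%g: tissue %d, female GSC %d, male GSC %d",
            config$filters$alpha, n_sig[1L], n_sig[2L], n_sig[3L])
  emit(de_e1, "de_germarium_vs_testis.tsv")
  emit(de_e2, "de_female_gsc_vs_kc.tsv")
  emit(de_e3, "de_os_bgcn_vs_bgcn.tsv")

  # --- integrate ----------------------------------------------------------
  lists <- list(
    shared_gsc = filter_shared_gsc(de_e2, de_e3, de_e1, config$filters),
    germarium_not_gsc = filter_germarium_not_gsc(de_e1, de_e2,
                                                 config$filters),
    testis_not_gsc = filter_testis_not_gsc(de_e1, de_e3, config$filters))
  for (nm in names(lists)) {
    log_stage("integrate", "filter %s: %d genes", nm, nrow(lists[[nm]]))
    emit(ranked_list_output(lists[[nm]], truth_map),
         sprintf("filter_%s.tsv", nm))
  }

  # --- enrich -------------------------------------------------------------
  en <- config$enrichment
  planted <- c(shared_gsc = "planted_shared_gsc",
               germarium_not_gsc = "planted_germarium_not_gsc",
               testis_not_gsc = "planted_testis_not_gsc")
  planted <- planted[lengths(truth[names(planted)]) > 0L]
  ann <- simulate_annotations(
    atlas, n_terms = en$n_terms, planted_terms = planted,
    term_size_range = en$term_size_range, purity = en$purity,
    seed = stage_seed(seed, "annotations"))
  enrich_tables <- list()
  for (nm in names(lists)) {
    query <- lists[[nm]]$gene_id
    if (length(query) == 0L) {
      log_stage("enrich", "filter %s list empty; skipping enrichment", nm)
      next
    }
    tab <- overrepresentation(query, ann, alpha = config$filters$alpha)
    enrich_tables[[nm]] <- tab
    log_stage("enrich", "filter %s: top term %s (p_adj=%.3g)",
              nm, tab$term_id[1L], tab$p_adj[1L])
    tab_out <- cbind(gene_set = nm, tab)
    p <- file.path(outdir, sprintf("enrichment_%s.tsv", nm))
    write_table(tab_out, p)
    paths[[sprintf("enrichment_%s.tsv", nm)]] <- p
  }

  # --- evaluate -----------------------------------------------------------
  recovery <- lapply(names(lists), function(nm) {
    if (length(truth[[nm]]) == 0L) {
      log_stage("evaluate",
                "filter %s: truth class absent from atlas; list size %d",
                nm, nrow(lists[[nm]]))
      return(list(precision = NA_real_, recall = NA_real_,
                  precision_at_k = numeric(0),
                  list_size = nrow(lists[[nm]]), truth_size = 0L,
                  degenerate = TRUE))
    }
    r <- evaluate_recovery(lists[[nm]], truth[[nm]])
    log_stage("evaluate", "filter %s: precision %.3f, recall %.3f (list %d, truth %d)",
              nm, r$precision, r$recall, r$list_size, r$truth_size)
    r
  })
  names(recovery) <- names(lists)
  recovery_df <- data.frame(
    filter = names(lists),
    precision = vapply(recovery, `[[`, 0, "precision"),
    recall = vapply(recovery, `[[`, 0, "recall"),
    list_size = vapply(recovery, `[[`, 0L, "list_size"),
    truth_size = vapply(recovery, `[[`, 0L, "truth_size"),
    degenerate = vapply(recovery, `[[`, NA, "degenerate"))
  p <- file.path(outdir, "recovery.tsv")
  write_table(recovery_df, p)
  paths[["recovery.tsv"]] <- p

  # --- manifest -----------------------------------------------------------
  hashes <- tools::md5sum(unlist(paths))
  manifest <- list(
    package = "gscatlas",
    seed = seed,
    config = serialize_config(config),
    files = stats::setNames(as.list(unname(hashes)), names(paths)),
    concordance = list(germarium = conc_g$mean, testis_apex = conc_t$mean),
    n_significant = as.list(n_sig),
    enrichment = lapply(enrich_tables, function(tab)
      list(top_term = tab$term_id[1L], top_p_adj = tab$p_adj[1L])),
    recovery = lapply(recovery, function(r)
      list(precision = r$precision, recall = r$recall,
           list_size = r$list_size, truth_size = r$truth_size))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_stage("done", "manifest written to %s", manifest_path)
  invisible(manifest)
}

# Configuration as plain lists for JSON serialization.
serialize_config <- function(config) {
  mix <- lapply(config$mixtures, function(m)
    list(sample_name = m$sample_name, weights = as.list(m$weights)))
  list(
    atlas = list(
      n_genes = config$atlas$n_genes,
      class_proportions = as.list(config$atlas$class_proportions),
      baseline_log2_mean = config$atlas$baseline_log2_mean,
      baseline_log2_sd = config$atlas$baseline_log2_sd,
      effect_log2fc = config$atlas$effect_log2fc),
    mixtures = mix,
    two_color = config$two_color,
    single_channel = config$single_channel,
    loess = config$loess,
    filters = unclass(config$filters),
    enrichment = config$enrichment,
    seed = config$seed)
}
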