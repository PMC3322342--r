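#' Construct an annotation map
#'
#' @param terms named list mapping term ids to character vectors of
#'   annotated gene ids; every term must be nonempty and every annotated
#'   gene must belong to the background.
#' @param background character vector: the gene universe (all genes on the
#'   array).
#' @return An object of class `annotation_map`.
#' @export
annotation_map <- function(terms, background) {
  if (!is.list(terms) || length(terms) == 0L || is.null(names(terms)) ||
      any(names(terms) == ""))
    stop("'terms' must be a nonempty named list of gene id vectors",
         call. = FALSE)
  if (anyDuplicated(names(terms)))
    stop("'terms' has duplicated term ids", call. = FALSE)
  if (anyDuplicated(background))
    stop("'background' has duplicated gene ids", call. = FALSE)
  terms <- lapply(terms, unique)
  empty <- names(terms)[lengths(terms) == 0L]
  if (length(empty) > 0L)
    stop(sprintf("term(s) with no genes: %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  outside <- unique(unlist(terms, use.names = FALSE))
  outside <- setdiff(outside, background)
  if (length(outside) > 0L)
    stop(sprintf("annotated gene(s) outside the background: %s",
                 paste(utils::head(outside, 5L), collapse = ", ")),
         call. = FALSE)
  structure(list(terms = terms, background = background),
            class = "annotation_map")
}

#' Hypergeometric term over-representation analysis
#'
#' For each term, computes the one-sided hypergeometric upper-tail
#' probability of observing at least the query/term overlap,
#' `P(X >= count)` with `X ~ Hypergeometric(background_size,
#' population_hits, query_size)`, then applies Benjamini-Hochberg
#' adjustment across all tested terms. A term is flagged significant when
#' its adjusted p is strictly below `alpha`.
#'
#' @param query character vector of gene ids (must be a subset of the
#'   annotation background).
#' @param annotations an [annotation_map()].
#' @param alpha significance threshold on the adjusted p (default 0.01).
#' @return data.frame sorted by p: `term_id`, `count`, `population_hits`,
#'   `query_size`, `background_size`, `p`, `p_adj`, `significant`.
#' @export
overrepresentation <- function(query, annotations, alpha = 0.01) {
  if (!inherits(annotations, "annotation_map"))
    stop("'annotations' must be an annotation_map", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, annotations$background)
  if (length(outside) > 0L)
    stop(sprintf("query gene(s) outside the background: %s",
                 paste(utils::head(outside, 5L), collapse = ", ")),
         call. = FALSE)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       strict_lower = TRUE)
  n_bg <- length(annotations$background)
  n_q <- length(query)
  rows <- lapply(names(annotations$terms), function(tid) {
    genes <- annotations$terms[[tid]]
    hits <- length(genes)
    count <- length(intersect(query, genes))
    p <- stats::phyper(count - 1L, hits, n_bg - hits, n_q,
                       lower.tail = FALSE)
    data.frame(term_id = tid, count = count, population_hits = hits,
               query_size = n_q, background_size = n_bg, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate term annotations with planted class-specific terms
#'
#' Generates random background terms (uniform gene draws, sizes uniform in
#' `term_size_range`) plus one planted term per requested truth class whose
#' genes are preferentially (`purity`) drawn from that class. Planted terms
#' give the enrichment stage a known positive control.
#'
#' @param atlas a [build_atlas()] result.
#' @param n_terms number of random terms.
#' @param planted_terms named character vector mapping truth classes to the
#'   term ids to plant (e.g. `c(shared_gsc = "planted_shared_gsc")`); may
#'   be empty.
#' @param term_size_range length-2 integer vector of random-term sizes.
#' @param purity fraction of each planted term drawn from its truth class.
#' @param seed integer seed.
#' @return An [annotation_map()] over all atlas genes.
#' @export
simulate_annotations <- function(atlas, n_terms = 200,
                                 planted_terms = c(
                                   shared_gsc = "planted_shared_gsc",
                                   germarium_not_gsc = "planted_germarium_not_gsc",
                                   testis_not_gsc = "planted_testis_not_gsc"),
                                 term_size_range = c(10, 100),
                                 purity = 0.9, seed = 1) {
  assert_count(n_terms, "n_terms", lower = 1L)
  assert_scalar_number(purity, "purity", lower = 0, upper = 1,
                       strict_lower = TRUE)
  assert_count(seed, "seed")
  if (length(term_size_range) != 2L || any(term_size_range < 1L) ||
      term_size_range[1L] > term_size_range[2L])
    stop("'term_size_range' must be two increasing positive integers",
         call. = FALSE)
  background <- atlas$gene_ids
  if (max(term_size_range) > length(background))
    stop("term sizes must not exceed the number of atlas genes",
         call. = FALSE)
  truth <- truth_sets(atlas)
  if (length(planted_terms) > 0L) {
    unknown <- setdiff(names(planted_terms), TRUTH_CLASSES)
    if (length(unknown) > 0L)
      stop(sprintf("unknown truth class(es) in planted_terms: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    absent <- names(planted_terms)[lengths(truth[names(planted_terms)]) == 0L]
    if (length(absent) > 0L)
      stop(sprintf("planted class(es) absent from the atlas: %s",
                   paste(absent, collapse = ", ")), call. = FALSE)
  }
  terms <- with_seed(seed, {
    out <- list()
    sizes <- sample(seq(term_size_range[1L], term_size_range[2L]),
                    n_terms, replace = TRUE)
    for (i in seq_len(n_terms))
      out[[sprintf("term%04d", i)]] <- sample(background, sizes[i])
    for (cls in names(planted_terms)) {
      class_genes <- truth[[cls]]
      m <- min(length(class_genes), 50L)
      n_in <- max(1L, round(purity * m))
      n_out <- m - n_in
      genes <- sample(class_genes, n_in)
      if (n_out > 0L)
        genes <- c(genes, sample(setdiff(background, class_genes), n_out))
      out[[planted_terms[[cls]]]] <- genes
    }
    out
  })
  annotation_map(terms, background)
}

#' Read term annotations from a file
#'
#' Accepts either a two-column TSV (`term_id`, `gene_id`; one pair per
#' line, with a header) or GMT-style lines (`term<TAB>description<TAB>
#' gene1<TAB>gene2...`).
#'
#' @param path file path.
#' @param background gene universe for the resulting [annotation_map()].
#' @param format `"tsv"` or `"gmt"`.
#' @return An [annotation_map()].
#' @export
read_annotations <- function(path, background, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("term_id", "gene_id") %in% names(tab)))
      stop("annotation TSV must have columns term_id and gene_id",
           call. = FALSE)
    terms <- split(tab$gene_id, tab$term_id)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    terms <- stats::setNames(
      lapply(parts, function(x) x[-(1:2)]),
      vapply(parts, `[[`, "", 1L))
  }
  annotation_map(terms, background)
}
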