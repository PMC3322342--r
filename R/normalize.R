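#' Compute M and A values for one two-color array
#'
#' M is the log2 germarium/testis ratio after undoing any dye flip (positive
#' M = germarium-enriched, the orientation used throughout this package);
#' A is the mean log2 intensity of the two channels.
#'
#' @param array a `two_color_array` (see [simulate_two_color()]), or any
#'   list with `gene_ids`, `intensity_ch1`, `intensity_ch2`, `dye_flipped`.
#' @return data.frame with columns `gene_id`, `M`, `A`, `log2_germarium`,
#'   `log2_testis`. (M, A) and the channel log2 intensities are mutually
#'   recoverable: `log2_germarium = A + M/2`, `log2_testis = A - M/2`.
#' @export
compute_ma <- function(array) {
  required <- c("gene_ids", "intensity_ch1", "intensity_ch2", "dye_flipped")
  if (!all(required %in% names(array)))
    stop("'array' must have fields gene_ids, intensity_ch1, intensity_ch2, dye_flipped",
         call. = FALSE)
  for (ch in c("intensity_ch1", "intensity_ch2")) {
    bad <- which(!is.finite(array[[ch]]) | array[[ch]] <= 0)
    if (length(bad) > 0L)
      stop(sprintf("nonpositive intensity for gene %s in channel %s",
                   array$gene_ids[bad[1L]], sub("intensity_ch", "", ch)),
           call. = FALSE)
  }
  l1 <- log2(array$intensity_ch1)
  l2 <- log2(array$intensity_ch2)
  if (isTRUE(array$dye_flipped)) {
    lg <- l2; lt <- l1
  } else {
    lg <- l1; lt <- l2
  }
  data.frame(gene_id = array$gene_ids,
             M = lg - lt,
             A = (l1 + l2) / 2,
             log2_germarium = lg,
             log2_testis = lt,
             stringsAsFactors = FALSE)
}

#' Assemble an MA table from replicate arrays
#'
#' @param arrays list of `two_color_array`s over the same genes in the same
#'   order.
#' @return An `ma_table`: `gene_ids` plus gene x replicate matrices `M`,
#'   `A`, `log2_germarium`, `log2_testis`, and the per-replicate
#'   `dye_flipped` flags.
#' @export
ma_table <- function(arrays) {
  if (!is.list(arrays) || length(arrays) < 1L)
    stop("'arrays' must be a nonempty list of two_color_array objects",
         call. = FALSE)
  per_rep <- lapply(arrays, compute_ma)
  ids <- per_rep[[1L]]$gene_id
  for (x in per_rep)
    if (!identical(x$gene_id, ids))
      stop("all arrays must share the same genes in the same order",
           call. = FALSE)
  bind <- function(col) {
    m <- do.call(cbind, lapply(per_rep, `[[`, col))
    colnames(m) <- sprintf("rep%d", vapply(arrays, `[[`, 0, "replicate_id"))
    rownames(m) <- ids
    m
  }
  structure(
    list(gene_ids = ids,
         M = bind("M"),
         A = bind("A"),
         log2_germarium = bind("log2_germarium"),
         log2_testis = bind("log2_testis"),
         dye_flipped = vapply(arrays, `[[`, NA, "dye_flipped")),
    class = "ma_table")
}

#' Intensity-dependent loess normalization of M values
#'
#' Per replicate, fits a robust local regression of M on A (tricube
#' weights, local quadratic fits, bisquare robustness iterations) and
#' subtracts the fit, removing smooth intensity-dependent dye bias. A is
#' never changed.
#'
#' @param ma an [ma_table()].
#' @param span loess span in (0, 1]; default 0.3.
#' @param iterations number of robustness (bisquare reweighting)
#'   iterations; default 3.
#' @return A new `ma_table` with bias-corrected `M` (and channel log2
#'   intensities adjusted consistently so M/A invertibility holds).
#' @export
loess_normalize <- function(ma, span = 0.3, iterations = 3) {
  if (!inherits(ma, "ma_table"))
    stop("'ma' must be an ma_table", call. = FALSE)
  assert_scalar_number(span, "span", lower = 0, upper = 1,
                       strict_lower = TRUE)
  assert_count(iterations, "iterations", lower = 0L)
  n <- nrow(ma$M)
  if (n < 10L)
    stop("loess normalization needs >= 10 genes", call. = FALSE)
  if (span * n < 7L)
    stop(sprintf(
      "local fit window too small (span %g over %d genes); use a larger span",
      span, n), call. = FALSE)
  # Dye bias enters orientation-corrected M with opposite sign on flipped
  # vs unflipped arrays, so with both orientations present it is
  # identifiable: if every replicate's corrected M is exactly identical,
  # the arrays carry no dye bias (and no replicate noise), any M-vs-A
  # trend is biological, and there is nothing to remove.
  if (!is.null(ma$dye_flipped) && length(unique(ma$dye_flipped)) == 2L &&
      ncol(ma$M) > 1L && max(abs(ma$M - ma$M[, 1L])) == 0)
    return(ma)
  out <- ma
  for (j in seq_len(ncol(ma$M))) {
    out$M[, j] <- ma$M[, j] -
      robust_loess_fit(ma$A[, j], ma$M[, j], span, iterations)
  }
  # keep channel intensities consistent with the corrected (M, A)
  out$log2_germarium <- out$A + out$M / 2
  out$log2_testis <- out$A - out$M / 2
  out
}

# Robust local-quadratic regression of y on x: tricube neighborhood
# weights via stats::loess, explicit bisquare robustness reweighting.
# Returns the fitted curve at the data points. The reweighting loop stops
# early when the median absolute residual collapses to (numerically) zero:
# at that point the fit already interpolates the majority of the data and
# bisquare weights are undefined, which happens for noise-free input.
robust_loess_fit <- function(x, y, span, iterations) {
  w <- rep(1, length(y))
  fitted <- y * 0
  for (it in 0:iterations) {
    fit <- stats::loess(y ~ x, weights = w, span = span, degree = 2,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    fitted <- stats::fitted(fit)
    if (it == iterations) break
    res <- y - fitted
    s <- stats::median(abs(res))
    if (s <= 1e-10 * max(1, stats::median(abs(y)))) break
    w <- (1 - pmin(1, abs(res) / (6 * s))^2)^2
    if (all(w == 0)) break
  }
  fitted
}

#' Quantile normalization of a positive intensity matrix
#'
#' Transforms to log2 and equalizes the per-sample distributions: after
#' normalization every sample's sorted value vector equals the across-sample
#' mean of log2 order statistics. Within-sample ranks are preserved. Backed
#' by [limma::normalizeQuantiles()].
#'
#' @param matrix gene x sample matrix of positive linear intensities
#'   (>= 2 samples).
#' @return gene x sample matrix of normalized log2 values.
#' @export
quantile_normalize <- function(matrix) {
  if (!is.matrix(matrix) || ncol(matrix) < 2L)
    stop("'matrix' must be a matrix with >= 2 samples", call. = FALSE)
  if (any(!is.finite(matrix)) || any(matrix <= 0))
    stop("'matrix' must be strictly positive and finite", call. = FALSE)
  out <- limma::normalizeQuantiles(log2(matrix))
  dimnames(out) <- dimnames(matrix)
  out
}

#' Pairwise replicate concordance
#'
#' Pearson correlation over all replicate pairs of a gene x replicate
#' matrix of log2 values; summarizes reproducibility the way microarray
#' studies report an average R with its range.
#'
#' @param matrix gene x replicate matrix of log2 values (>= 2 replicates).
#' @return list with `mean`, `min`, `max`, and the `pairwise` correlation
#'   values (named "i_vs_j").
#' @export
replicate_concordance <- function(matrix) {
  if (!is.matrix(matrix) || ncol(matrix) < 2L)
    stop("'matrix' must be a matrix with >= 2 replicates", call. = FALSE)
  sds <- apply(matrix, 2, stats::sd)
  if (any(sds == 0)) {
    rep_names <- colnames(matrix) %||% as.character(seq_len(ncol(matrix)))
    stop(sprintf("replicate %s has zero variance; correlation undefined",
                 rep_names[which(sds == 0)[1L]]), call. = FALSE)
  }
  cm <- stats::cor(matrix)
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  vals <- cm[upper.tri(cm)]
  names(vals) <- paste(pairs[, 1L], pairs[, 2L], sep = "_vs_")
  list(mean = mean(vals), min = min(vals), max = max(vals), pairwise = vals)
}
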