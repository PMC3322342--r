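#' Gene-wise effect and variance estimates
#'
#' For a one-sample design (a matrix of orientation-corrected M values,
#' `groups = NULL`) the effect is the mean M across replicates, `s2` the
#' sample variance, and `df = n - 1`. For a two-group design (a log2
#' expression matrix plus group labels) the effect is mean(group1) -
#' mean(group2), `s2` the pooled within-group variance, and
#' `df = n1 + n2 - 2`; per-group mean log2 intensities are recorded for
#' downstream intensity gating.
#'
#' @param x gene x sample numeric matrix (M values or log2 intensities).
#' @param groups `NULL`, or a vector of two distinct labels, one per
#'   column of `x`. The first label encountered is group 1 (positive
#'   effect = higher in group 1).
#' @param gene_ids gene identifiers; defaults to `rownames(x)`.
#' @return data.frame with columns `gene_id`, `effect`, `s2`, `df`, and
#'   `mean_<label>` per group (one-sample designs get no group means).
#'   Attribute `n_eff` carries the effective sample size for the t
#'   denominator: n for one-sample, `1/(1/n1 + 1/n2)` for two groups.
#' @export
genewise_stats <- function(x, groups = NULL, gene_ids = rownames(x)) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix", call. = FALSE)
  if (is.null(gene_ids))
    gene_ids <- sprintf("g%05d", seq_len(nrow(x)))
  if (is.null(groups)) {
    if (ncol(x) < 2L)
      stop("one-sample design needs >= 2 replicates", call. = FALSE)
    out <- data.frame(gene_id = gene_ids,
                      effect = rowMeans(x),
                      s2 = row_vars(x),
                      df = ncol(x) - 1L,
                      stringsAsFactors = FALSE)
    attr(out, "n_eff") <- ncol(x)
  } else {
    if (length(groups) != ncol(x))
      stop("'groups' must have one label per sample", call. = FALSE)
    labs <- if (is.factor(groups)) levels(droplevels(groups))
            else unique(groups)
    if (length(labs) != 2L)
      stop("'groups' must contain exactly two distinct labels", call. = FALSE)
    n1 <- sum(groups == labs[1L]); n2 <- sum(groups == labs[2L])
    if (n1 < 2L || n2 < 2L)
      stop(sprintf("each group needs >= 2 samples (got %s=%d, %s=%d)",
                   labs[1L], n1, labs[2L], n2), call. = FALSE)
    x1 <- x[, groups == labs[1L], drop = FALSE]
    x2 <- x[, groups == labs[2L], drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    s2 <- ((n1 - 1L) * row_vars(x1) + (n2 - 1L) * row_vars(x2)) /
      (n1 + n2 - 2L)
    out <- data.frame(gene_id = gene_ids,
                      effect = m1 - m2,
                      s2 = s2,
                      df = n1 + n2 - 2L,
                      stringsAsFactors = FALSE)
    out[[paste0("mean_", labs[1L])]] <- m1
    out[[paste0("mean_", labs[2L])]] <- m2
    attr(out, "n_eff") <- 1 / (1 / n1 + 1 / n2)
    attr(out, "group_labels") <- labs
  }
  rownames(out) <- NULL
  out
}

# Invert the trigamma function by Newton iteration (solve trigamma(x) = y).
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, 0)
}

#' Estimate the variance prior by moment matching on log s2
#'
#' Fits the empirical-Bayes hierarchy in which each gene's true variance is
#' scaled-inverse-chi-square distributed (prior df `d0`, prior variance
#' `s0_2`) and the observed `s2` is a chi-square-based sample variance.
#' Matching the mean and variance of `log(s2)` against the theoretical
#' digamma/trigamma moments yields `d0` and `s0_2`. When the empirical
#' variance of `log(s2)` does not exceed the pure sampling contribution
#' `trigamma(df/2)`, there is no evidence of variance dispersion and `d0`
#' is reported infinite with `s0_2 = mean(s2)`.
#'
#' @param stats a [genewise_stats()] data.frame (needs `s2` and `df`).
#' @return list with `d0` (positive, possibly `Inf`) and `s0_2`.
#' @export
estimate_prior <- function(stats) {
  if (!all(c("s2", "df") %in% names(stats)))
    stop("'stats' must have columns s2 and df", call. = FALSE)
  s2 <- stats$s2
  df <- stats$df
  if (all(s2 == 0))
    stop("all gene-wise variances are zero; prior is undefined (degenerate simulation)",
         call. = FALSE)
  pos <- s2 > 0
  if (sum(pos) < 20L)
    stop(sprintf("need >= 20 genes with s2 > 0 (got %d)", sum(pos)),
         call. = FALSE)
  z <- log(s2[pos])
  dfp <- rep_len(df, length(s2))[pos]
  evar <- stats::var(z) - mean(trigamma(dfp / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(z) - mean(digamma(dfp / 2) - log(dfp / 2)) +
                  digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- mean(s2[pos])
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Empirical-Bayes moderated t-statistic
#'
#' Shrinks each gene-wise variance toward the prior,
#' `s_tilde2 = (d0*s0_2 + df*s2) / (d0 + df)` (equal to `s0_2` when `d0`
#' is infinite, and to `s2` when `d0 = 0`), forms
#' `t_mod = effect / sqrt(s_tilde2 / n_eff)`, and computes a two-sided p
#' from the t distribution with `d0 + df` degrees of freedom (standard
#' normal in the infinite-d0 limit).
#'
#' @param stats a [genewise_stats()] data.frame.
#' @param prior an [estimate_prior()] result (a list with `d0 >= 0`,
#'   possibly `Inf`, and `s0_2 > 0`).
#' @param n_eff effective sample size; defaults to the `n_eff` attribute
#'   of `stats`.
#' @return data.frame with columns `gene_id`, `t_mod`, `p`.
#' @export
moderated_t <- function(stats, prior, n_eff = attr(stats, "n_eff")) {
  if (!all(c("effect", "s2", "df") %in% names(stats)))
    stop("'stats' must have columns effect, s2 and df", call. = FALSE)
  if (!is.list(prior) || is.null(prior$d0) || is.null(prior$s0_2))
    stop("'prior' must be a list with d0 and s0_2", call. = FALSE)
  if (is.na(prior$d0) || prior$d0 < 0)
    stop("'prior$d0' must be >= 0 (possibly Inf)", call. = FALSE)
  if (!is.finite(prior$s0_2) || prior$s0_2 <= 0)
    stop("'prior$s0_2' must be a positive finite number", call. = FALSE)
  if (is.null(n_eff))
    stop("'n_eff' must be supplied when 'stats' carries no n_eff attribute",
         call. = FALSE)
  assert_scalar_number(n_eff, "n_eff", lower = 0, strict_lower = TRUE)
  d0 <- prior$d0
  s_tilde2 <- if (is.infinite(d0)) {
    rep_len(prior$s0_2, nrow(stats))
  } else {
    (d0 * prior$s0_2 + stats$df * stats$s2) / (d0 + stats$df)
  }
  if (any(s_tilde2 <= 0))
    stop("nonpositive posterior variance; cannot form moderated t",
         call. = FALSE)
  t_mod <- stats$effect / sqrt(s_tilde2 / n_eff)
  df_total <- d0 + stats$df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(gene_id = stats$gene_id, t_mod = t_mod, p = p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()] with input
#' validation: monotone in the p ordering and capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p))
    stop("'p' must be numeric", call. = FALSE)
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("all p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

# Shared assembly of a DE results table. Handles the exact zero-noise limit:
# when every gene-wise variance is zero the data are noiseless replicates and
# p is 0 for any nonzero effect and 1 otherwise (no moderation possible).
make_de_table <- function(stats, a_mean, n_eff, prior = NULL) {
  if (all(stats$s2 == 0)) {
    t_mod <- sign(stats$effect) * ifelse(stats$effect == 0, 0, Inf)
    p <- as.numeric(stats$effect == 0)
    prior_used <- list(d0 = NA_real_, s0_2 = NA_real_, degenerate = TRUE)
  } else {
    if (is.null(prior)) prior <- estimate_prior(stats)
    tp <- moderated_t(stats, prior, n_eff)
    t_mod <- tp$t_mod
    p <- tp$p
    prior_used <- c(prior, degenerate = FALSE)
  }
  de <- data.frame(gene_id = stats$gene_id,
                   M = stats$effect,
                   A = a_mean,
                   t_mod = t_mod,
                   p = p,
                   p_adj = bh_adjust(p),
                   stringsAsFactors = FALSE)
  mean_cols <- grep("^mean_", names(stats), value = TRUE)
  for (cl in mean_cols) de[[cl]] <- stats[[cl]]
  attr(de, "prior") <- prior_used
  attr(de, "n_eff") <- n_eff
  de
}

#' Differential expression for the two-color tissue comparison
#'
#' Runs the moderated t-test on orientation-corrected, normalized M values
#' (one-sample design over replicates: positive M = germarium-enriched) and
#' records per-tissue mean log2 channel intensities for the downstream
#' baseline-intensity gate.
#'
#' @param ma a (normalized) [ma_table()].
#' @param group_names length-2 character vector naming the two tissues in
#'   (positive-M, negative-M) order; defaults to
#'   `c("germarium", "testis_apex")`.
#' @param prior optional [estimate_prior()] override.
#' @return A DE table: `gene_id`, `M`, `A`, `t_mod`, `p`, `p_adj`,
#'   `mean_<tissue>` log2 intensity columns. Attributes record the prior
#'   and the orientation convention.
#' @export
de_two_color <- function(ma, group_names = c("germarium", "testis_apex"),
                         prior = NULL) {
  if (!inherits(ma, "ma_table"))
    stop("'ma' must be an ma_table", call. = FALSE)
  if (length(group_names) != 2L)
    stop("'group_names' must have length 2", call. = FALSE)
  stats <- genewise_stats(ma$M, gene_ids = ma$gene_ids)
  stats[[paste0("mean_", group_names[1L])]] <- rowMeans(ma$log2_germarium)
  stats[[paste0("mean_", group_names[2L])]] <- rowMeans(ma$log2_testis)
  de <- make_de_table(stats, rowMeans(ma$A), n_eff = ncol(ma$M),
                      prior = prior)
  attr(de, "orientation") <- sprintf("positive M = %s-enriched",
                                     group_names[1L])
  de
}

#' Differential expression for a two-group single-channel experiment
#'
#' Quantile-normalizes the intensity matrix (log2 scale) and runs the
#' moderated t-test on the two-group design. Positive M means enrichment in
#' `positive_group`.
#'
#' @param scs a `single_channel_set` (see [simulate_single_channel()]), or
#'   a list with `matrix`, `group_labels`, `gene_ids`.
#' @param positive_group which group label gets the positive-M orientation;
#'   defaults to the first label.
#' @param prior optional [estimate_prior()] override.
#' @return A DE table as in [de_two_color()], with `mean_<group>` log2
#'   intensity columns.
#' @export
de_two_group <- function(scs, positive_group = NULL, prior = NULL) {
  required <- c("matrix", "group_labels", "gene_ids")
  if (!all(required %in% names(scs)))
    stop("'scs' must have fields matrix, group_labels and gene_ids",
         call. = FALSE)
  labs <- unique(scs$group_labels)
  if (length(labs) != 2L)
    stop("'scs' must contain exactly two groups", call. = FALSE)
  positive_group <- positive_group %||% labs[1L]
  if (!positive_group %in% labs)
    stop(sprintf("'positive_group' must be one of: %s",
                 paste(labs, collapse = ", ")), call. = FALSE)
  ord <- c(positive_group, setdiff(labs, positive_group))
  grp <- factor(scs$group_labels, levels = ord)
  # Quantile normalization removes distributional (technical) differences
  # between samples. When replicates within each group are exactly
  # identical there is no technical variation to remove, and equalizing
  # order statistics would instead distort the biological group contrast;
  # in that degenerate (noise-free) limit the raw log2 matrix is used.
  raw_log2 <- log2(scs$matrix)
  raw_stats <- genewise_stats(raw_log2, groups = grp,
                              gene_ids = scs$gene_ids)
  norm <- if (all(raw_stats$s2 == 0)) raw_log2
          else quantile_normalize(scs$matrix)
  stats <- genewise_stats(norm, groups = grp, gene_ids = scs$gene_ids)
  de <- make_de_table(stats, rowMeans(norm),
                      n_eff = attr(stats, "n_eff"), prior = prior)
  attr(de, "orientation") <- sprintf("positive M = %s-enriched", ord[1L])
  de
}
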