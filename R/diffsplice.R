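# Differential junction usage between SF3B1-mutant and wild-type groups.
# Deliberately a transparent reimplementation of the count-based test:
# median-of-ratios normalisation, per-junction method-of-moments NB
# dispersion, Wald test on the group contrast, BH correction.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over junctions (restricted
#' to junctions with strictly positive counts in every sample) of the ratio
#' of the sample's count to the junction's geometric mean, rescaled so the
#' factors have geometric mean 1 (which makes normalisation idempotent). If
#' no junction is positive in all samples, total-count ratios are used with
#' a warning.
#'
#' @param counts numeric matrix, junctions x samples.
#' @return positive numeric vector of length `ncol(counts)`.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L) return(stats::setNames(1, colnames(counts)))
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    warning("no junction with all-positive counts; falling back to total-count ratios")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
    return(sf)
  }
  sub <- counts[allpos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geo, 2, stats::median)
  # rescale to geometric mean 1 so normalisation is idempotent
  sf / exp(mean(log(sf)))
}

# Method-of-moments NB dispersion for one junction on normalised counts.
# Var(q) ~ mu * mean(1/sf) + alpha * mu^2; residuals taken around the group
# means so the group effect does not inflate alpha.
mom_dispersion <- function(q, groups, inv_sf_mean, min_disp = 1e-8) {
  n <- length(q)
  mu_g <- tapply(q, groups, mean)
  resid2 <- (q - mu_g[as.character(groups)])^2
  df <- n - length(mu_g)
  if (df <= 0) return(min_disp)
  s2 <- sum(resid2) / df
  mbar <- mean(q)
  if (mbar <= 0) return(min_disp)
  max(min_disp, (s2 - mbar * inv_sf_mean) / mbar^2)
}

#' Negative-binomial Wald test for one junction
#'
#' Counts are normalised by the size factors; the log2 fold change is
#' `log2((mean MUT + c) / (mean WT + c))` with pseudocount `c`, and the
#' p-value comes from a Wald test of the group contrast on the log scale,
#' with a per-junction method-of-moments dispersion (floored at `min_disp`)
#' propagated through the delta method. All-zero junctions are untestable
#' (`NA` statistics).
#'
#' @param counts numeric vector of raw counts for one junction.
#' @param groups factor-like vector, `"MUT"` / `"WT"`, same length.
#' @param sf size factors (same length); default all 1.
#' @param pseudocount fold-change pseudocount c (default 0.5).
#' @param min_disp dispersion floor (default 1e-8).
#' @return list with `log2_fold_change`, `p_value`, `untestable`.
#' @export
nb_test <- function(counts, groups, sf = rep(1, length(counts)),
                    pseudocount = 0.5, min_disp = 1e-8) {
  stopifnot(length(counts) == length(groups), length(sf) == length(counts))
  groups <- as.character(groups)
  if (!all(c("MUT", "WT") %in% groups)) stop("both groups must be non-empty")
  if (all(counts == 0))
    return(list(log2_fold_change = NA_real_, p_value = NA_real_, untestable = TRUE))
  q <- counts / sf
  m1 <- mean(q[groups == "MUT"]); n1 <- sum(groups == "MUT")
  m0 <- mean(q[groups == "WT"]);  n0 <- sum(groups == "WT")
  alpha <- mom_dispersion(q, groups, mean(1 / sf), min_disp)
  lfc <- log2((m1 + pseudocount) / (m0 + pseudocount))
  # Var(mean normalised count) per group under NB(mu, alpha)
  v1 <- (m1 * mean(1 / sf[groups == "MUT"]) + alpha * m1^2) / n1
  v0 <- (m0 * mean(1 / sf[groups == "WT"]) + alpha * m0^2) / n0
  se2 <- v1 / (m1 + pseudocount)^2 + v0 / (m0 + pseudocount)^2
  if (se2 <= 0)
    return(list(log2_fold_change = lfc, p_value = NA_real_, untestable = TRUE))
  w <- (log(m1 + pseudocount) - log(m0 + pseudocount)) / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(w))
  list(log2_fold_change = lfc, p_value = p, untestable = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment. `NA` entries (untestable junctions) are
#' excluded from the number of tests and returned as `NA`.
#'
#' @param p numeric vector of p-values in \[0,1\] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0,1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Differential junction usage between MUT and WT samples
#'
#' Runs [size_factors()], filters junctions whose total count across the
#' cohort is below `min_total`, applies [nb_test()] per junction and
#' [bh_adjust()], and flags the selection at the study thresholds
#' (BH-adjusted p <= 1e-5 and |log2 fold change| >= 1 by default).
#'
#' @param junctions junction table with count columns.
#' @param samples sample sheet (see [read_sample_sheet()]).
#' @param p_threshold BH-adjusted p-value threshold (default 1e-5).
#' @param lfc_threshold absolute log2 fold-change threshold (default 1).
#' @param min_total cohort-wide minimum total count to test (default 10).
#' @param pseudocount,min_disp passed to [nb_test()].
#' @return data.frame (one row per junction, input order) with `id`,
#'   `mean_count` (mean normalised), `log2_fold_change`, `p_value`,
#'   `p_adjusted`, `untestable`, `selected`.
#' @export
diff_junction_usage <- function(junctions, samples, p_threshold = 1e-5,
                                lfc_threshold = 1, min_total = 10,
                                pseudocount = 0.5, min_disp = 1e-8) {
  samples <- validate_sample_sheet(samples)
  m <- count_matrix(junctions)
  missing <- setdiff(samples$sample, colnames(m))
  if (length(missing))
    stop("junction table lacks counts for sample(s): ", paste(missing, collapse = ", "))
  m <- m[, samples$sample, drop = FALSE]
  sf <- size_factors(m)
  groups <- samples$group
  keep <- rowSums(m) >= min_total
  res <- data.frame(id = rownames(m),
                    mean_count = rowMeans(sweep(m, 2, sf, "/")),
                    log2_fold_change = NA_real_, p_value = NA_real_,
                    p_adjusted = NA_real_, untestable = TRUE,
                    selected = FALSE, stringsAsFactors = FALSE)
  for (j in which(keep)) {
    t <- nb_test(m[j, ], groups, sf, pseudocount, min_disp)
    res$log2_fold_change[j] <- t$log2_fold_change
    res$p_value[j] <- t$p_value
    res$untestable[j] <- t$untestable
  }
  res$p_adjusted <- bh_adjust(res$p_value)
  select_differential(res, p_threshold, lfc_threshold)
}

#' Apply the selection thresholds to a differential result table
#'
#' @param results data.frame from [diff_junction_usage()] (needs
#'   `p_adjusted` and `log2_fold_change`).
#' @param p_threshold,lfc_threshold selection thresholds
#'   (defaults 1e-5 and 1, as used for the tumour cohort).
#' @return `results` with the `selected` flag recomputed.
#' @export
select_differential <- function(results, p_threshold = 1e-5, lfc_threshold = 1) {
  results$selected <- !is.na(results$p_adjusted) &
    !is.na(results$log2_fold_change) &
    results$p_adjusted <= p_threshold &
    abs(results$log2_fold_change) >= lfc_threshold
  results
}
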