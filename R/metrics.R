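#' Indices of the top fraction of a vector
#'
#' Shared helper for the "top 1% / top 5%" quality measures: returns
#' the `max(1, round(frac * N))` indices with the largest values
#' (round-half-up; ties broken by ascending index, so the result is
#' deterministic).
#'
#' @param values finite numeric vector.
#' @param frac fraction in (0, 1].
#' @return integer index vector.
#' @export
top_fraction_set <- function(values, frac) {
  if (length(values) == 0L) stop("empty vector")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  stopifnot_finite(values, "values")
  n_top <- max(1L, as.integer(floor(frac * length(values) + 0.5)))
  order(-values, seq_along(values))[seq_len(n_top)]
}

#' Global mean squared error
#'
#' @param imp,obs imputed and observed vectors of equal length.
#' @return mean squared difference.
#' @export
mse_global <- function(imp, obs) {
  if (length(imp) != length(obs)) stop("length mismatch")
  mean((imp - obs)^2)
}

#' Mean squared error over the top 1% of a ranking
#'
#' [mse_global()] restricted to `top_fraction_set(ranking, frac)`.
#' With `ranking = obs` this is MSE1obs; with `ranking = imp`, MSE1imp;
#' with another method's imputed track as the ranking it yields the
#' cross-ranking variants (e.g. MSE at positions top-ranked by a
#' competing model).
#'
#' @param imp,obs imputed and observed vectors.
#' @param ranking vector whose top fraction selects the positions.
#' @param frac fraction (default 0.01).
#' @return scalar MSE over the selected positions.
#' @export
mse_top1 <- function(imp, obs, ranking, frac = 0.01) {
  if (length(imp) != length(obs) || length(ranking) != length(obs))
    stop("length mismatch")
  idx <- top_fraction_set(ranking, frac)
  mse_global(imp[idx], obs[idx])
}

#' Genome-wide Pearson correlation
#'
#' @param imp,obs imputed and observed vectors (both non-constant).
#' @return Pearson correlation coefficient.
#' @export
gw_corr <- function(imp, obs) {
  if (length(imp) != length(obs)) stop("length mismatch")
  if (stats::sd(imp) == 0 || stats::sd(obs) == 0)
    stop("undefined correlation: zero variance")
  cor(imp, obs)
}

#' Overlap between top-ranked position sets
#'
#' Fraction of the top `frac_a` positions of `rank_a` that fall inside
#' the top `frac_b` positions of `rank_b`. The three catch measures
#' are: Match1 = `overlap_catch(obs, imp, 0.01, 0.01)`, Catch1obs =
#' `overlap_catch(obs, imp, 0.01, 0.05)`, Catch1imp =
#' `overlap_catch(imp, obs, 0.01, 0.05)`.
#'
#' @param rank_a,rank_b ranking vectors of equal length.
#' @param frac_a,frac_b fractions in (0, 1].
#' @return fraction in \[0, 1\].
#' @export
overlap_catch <- function(rank_a, rank_b, frac_a, frac_b) {
  if (length(rank_a) != length(rank_b)) stop("length mismatch")
  ta <- top_fraction_set(rank_a, frac_a)
  tb <- top_fraction_set(rank_b, frac_b)
  length(intersect(ta, tb)) / length(ta)
}

#' Rank-based AUC for recovering a binary label set
#'
#' Area under the ROC curve computed by the Mann-Whitney identity with
#' midrank tie handling. AucObs1 uses labels = top 1% by observed and
#' scores = imputed; AucImp1 the reverse; CatchPeakObs uses called-peak
#' labels with imputed scores.
#'
#' @param labels binary (0/1 or logical) vector with both classes present.
#' @param scores numeric ranking scores.
#' @return AUC in \[0, 1\].
#' @export
auc_recovery <- function(labels, scores) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores)) stop("length mismatch")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("undefined AUC: labels contain a single class")
  r <- rank(scores)                      # midranks for ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

measure_names <- c("MSEglobal", "MSE1obs", "MSE1imp", "GWcorr", "Match1",
                   "Catch1obs", "Catch1imp", "AucObs1", "AucImp1", "CatchPeakObs")

#' Evaluate one imputed experiment against its observed track
#'
#' Assembles the ten quality measures on the transformed scale:
#' MSEglobal, MSE1obs, MSE1imp, GWcorr, Match1, Catch1obs, Catch1imp,
#' AucObs1, AucImp1 and (when peak labels are supplied and contain both
#' classes) CatchPeakObs. Extra named ranking vectors in `rankings`
#' yield cross-ranking MSE variants named `MSE1imp<name>`.
#'
#' @param imp,obs imputed and observed vectors on the same bin index.
#' @param peaks optional binary per-bin peak labels (see
#'   [peaks_to_labels()]); `CatchPeakObs` is `NA` when absent or
#'   single-class.
#' @param rankings optional named list of other methods' imputed tracks.
#' @return named numeric vector of measures.
#' @export
evaluate_experiment <- function(imp, obs, peaks = NULL, rankings = NULL) {
  out <- c(MSEglobal = mse_global(imp, obs),
           MSE1obs = mse_top1(imp, obs, obs),
           MSE1imp = mse_top1(imp, obs, imp),
           GWcorr = gw_corr(imp, obs),
           Match1 = overlap_catch(obs, imp, 0.01, 0.01),
           Catch1obs = overlap_catch(obs, imp, 0.01, 0.05),
           Catch1imp = overlap_catch(imp, obs, 0.01, 0.05),
           AucObs1 = auc_recovery(seq_along(obs) %in% top_fraction_set(obs, 0.01), imp),
           AucImp1 = auc_recovery(seq_along(imp) %in% top_fraction_set(imp, 0.01), obs))
  cpo <- NA_real_
  if (!is.null(peaks)) {
    pk <- as.logical(peaks)
    if (length(pk) != length(obs)) stop("peak labels must match the bin index")
    if (any(pk) && !all(pk)) cpo <- auc_recovery(pk, imp)
  }
  out <- c(out, CatchPeakObs = cpo)
  for (nm in names(rankings))
    out[paste0("MSE1imp", nm)] <- mse_top1(imp, obs, rankings[[nm]])
  out
}

#' Convert per-experiment peak calls to per-bin binary labels
#'
#' A bin is labeled 1 when it overlaps a called peak by at least 1 bp.
#'
#' @param peaks a `GRanges` of peak intervals (e.g. from
#'   `rtracklayer::import()` on a BED file).
#' @param bins the bin index `GRanges`.
#' @return integer 0/1 vector of length `length(bins)`.
#' @export
peaks_to_labels <- function(peaks, bins) {
  as.integer(GenomicRanges::countOverlaps(bins, peaks, ignore.strand = TRUE) > 0)
}

#' Cross-method comparison statistics
#'
#' For each quality measure present in both reports: the Pearson
#' correlation of the two methods' per-experiment values, and the mean
#' and standard deviation of `log(mA / mB)` (natural log) over
#' experiments where both values are strictly positive (others are
#' excluded from the log ratios but kept for the correlation, and
#' counted).
#'
#' @param report_a,report_b matrices or data.frames of per-experiment
#'   measures (rows = experiments, columns = measures, matching row
#'   names identify shared experiments).
#' @return data.frame with columns measure, corr, log_ratio_mean,
#'   log_ratio_sd, n, n_excluded.
#' @export
compare_methods <- function(report_a, report_b) {
  report_a <- as.matrix(report_a); report_b <- as.matrix(report_b)
  shared <- intersect(rownames(report_a), rownames(report_b))
  meas <- intersect(colnames(report_a), colnames(report_b))
  out <- data.frame(measure = character(), corr = double(),
                    log_ratio_mean = double(), log_ratio_sd = double(),
                    n = integer(), n_excluded = integer())
  for (m in meas) {
    va <- report_a[shared, m]; vb <- report_b[shared, m]
    keep <- is.finite(va) & is.finite(vb)
    if (sum(keep) < 3L) stop("fewer than 3 shared experiments for measure ", m)
    pos <- keep & va > 0 & vb > 0
    lr <- log(va[pos] / vb[pos])
    out[nrow(out) + 1L, ] <- list(m, cor(va[keep], vb[keep]), mean(lr),
                                  stats::sd(lr), sum(keep), sum(keep) - sum(pos))
  }
  out
}

#' Ternary projection of a three-method comparison
#'
#' Projects a non-negative triple onto the simplex:
#' `x' = x / (x + y + z)` and likewise for y, z, so equal values map to
#' the center (1/3, 1/3, 1/3) and axis-aligned points to the corners.
#'
#' @param x,y,z non-negative values, not all zero.
#' @return numeric vector `c(x', y', z')` summing to 1.
#' @export
ternary_project <- function(x, y, z) {
  if (any(c(x, y, z) < 0)) stop("coordinates must be non-negative")
  s <- x + y + z
  if (s <= 0) stop("all-zero input has no ternary projection")
  c(x, y, z) / s
}

#' Average two imputed tracks
#'
#' Element-wise mean; combining two complementary imputation methods
#' this way often lowers the global MSE below either alone.
#'
#' @param imp_a,imp_b vectors of equal length.
#' @return element-wise mean vector.
#' @export
average_tracks <- function(imp_a, imp_b) {
  if (length(imp_a) != length(imp_b)) stop("length mismatch")
  (imp_a + imp_b) / 2
}
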