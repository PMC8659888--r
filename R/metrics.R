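# Evaluation: Dice similarity coefficient, sensitivity, specificity,
# positive predictive value, volumetric overlap error and relative volume
# difference on binary masks, plus an exact two-sided Mann-Whitney U test
# for comparing small sets of cross-validation scores.

as_bin <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (!all(x %in% c(0, 1))) stop("mask must be binary")
  as.integer(x)
}

check_masks <- function(P, G) {
  if (length(P) != length(G)) stop("mask shapes differ")
  list(P = as_bin(P), G = as_bin(G))
}

#' Dice similarity coefficient
#'
#' `2 |P ∩ G| / (|P| + |G|)`, the standard overlap metric.  Two empty
#' masks agree perfectly and score 1.  Setting `printed_formula = TRUE`
#' drops the conventional factor 2 (for auditing against sources that
#' print the coefficient without it).
#'
#' @param P,G binary masks of equal shape (prediction, ground truth).
#' @param printed_formula use `|P ∩ G| / (|P| + |G|)` instead.
#' @return value in \[0, 1\] (or \[0, 0.5\] for the audit variant).
#' @export
dsc <- function(P, G, printed_formula = FALSE) {
  m <- check_masks(P, G)
  num <- sum(m$P & m$G)
  den <- sum(m$P) + sum(m$G)
  if (den == 0) return(1)
  if (printed_formula) num / den else 2 * num / den
}

#' Sensitivity (tumor fraction detected)
#'
#' `|P ∩ G| / |G|`.  Undefined (NA) for an empty ground truth.
#' @inheritParams dsc
#' @return value in \[0, 1\] or `NA`.
#' @export
sen <- function(P, G) {
  m <- check_masks(P, G)
  if (sum(m$G) == 0) return(NA_real_)
  sum(m$P & m$G) / sum(m$G)
}

#' Specificity (normal tissue correctly left unsegmented)
#'
#' True negatives over ground-truth negatives,
#' `|1 - (P ∪ G)| / |1 - G|`.  Undefined (NA) when the ground truth
#' covers every pixel.
#' @inheritParams dsc
#' @return value in \[0, 1\] or `NA`.
#' @export
spe <- function(P, G) {
  m <- check_masks(P, G)
  neg <- length(m$G) - sum(m$G)
  if (neg == 0) return(NA_real_)
  tn <- sum(!(m$P | m$G))
  tn / neg
}

#' Positive predictive value (precision)
#'
#' `|P ∩ G| / |P|`.  Undefined (NA) for an empty prediction.
#' @inheritParams dsc
#' @return value in \[0, 1\] or `NA`.
#' @export
ppv <- function(P, G) {
  m <- check_masks(P, G)
  if (sum(m$P) == 0) return(NA_real_)
  sum(m$P & m$G) / sum(m$P)
}

#' Volumetric overlap error
#'
#' `1 - |P ∩ G| / |P ∪ G]` (one minus the Jaccard index).  Two empty
#' masks score 0.
#' @inheritParams dsc
#' @return value in \[0, 1\].
#' @export
voe <- function(P, G) {
  m <- check_masks(P, G)
  un <- sum(m$P | m$G)
  if (un == 0) return(0)
  1 - sum(m$P & m$G) / un
}

#' Relative volume difference
#'
#' `(|P| - |G|) / |G|`, a signed volume-bias measure bounded below by -1.
#' Undefined (NA) for an empty ground truth.
#' @inheritParams dsc
#' @return value >= -1 or `NA`.
#' @export
rvd <- function(P, G) {
  m <- check_masks(P, G)
  if (sum(m$G) == 0) return(NA_real_)
  (sum(m$P) - sum(m$G)) / sum(m$G)
}

#' Exact two-sided Mann-Whitney U test
#'
#' Enumerates all `choose(n + m, n)` assignments of the pooled sample
#' into the two groups and counts those whose U statistic (computed from
#' mid-ranks, so ties are handled) deviates from its null mean by at
#' least as much as the observed one.  Intended for the small samples of
#' cross-validation scores (at most 12 per group).
#'
#' @param a,b numeric vectors (e.g. per-trial DSC values of two models).
#' @return exact two-sided p-value.
#' @export
mann_whitney_exact <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty input sample")
  if (length(a) > 12L || length(b) > 12L)
    stop("exact enumeration supports at most 12 values per group")
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  r2 <- as.integer(round(2 * rank(pooled)))  # doubled mid-ranks (integers)
  u_dev <- function(rsum2) {
    # rsum2 = doubled rank sum of group 1; U1 = rsum/1 - n1(n1+1)/2
    abs(rsum2 / 2 - n1 * (n1 + 1) / 2 - n1 * n2 / 2)
  }
  obs <- u_dev(sum(r2[seq_len(n1)]))
  # distribution of the doubled rank sum over all n1-subsets via subset-sum
  # dynamic programming: cnt[j+1, s+1] = #subsets of size j with sum s
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  cnt <- matrix(0, n1 + 1L, smax + 1L)
  cnt[1L, 1L] <- 1
  for (v in r2) {
    jmax <- n1
    for (j in jmax:1) {
      reach <- which(cnt[j, ] > 0)
      if (!length(reach)) next
      tgt <- reach + v
      ok <- tgt <= smax + 1L
      cnt[j + 1L, tgt[ok]] <- cnt[j + 1L, tgt[ok]] + cnt[j, reach[ok]]
    }
  }
  sums <- which(cnt[n1 + 1L, ] > 0) - 1L
  weights <- cnt[n1 + 1L, sums + 1L]
  extreme <- u_dev(sums) >= obs - 1e-9
  sum(weights[extreme]) / choose(n1 + n2, n1)
}

#' Evaluate predicted masks against ground truth
#'
#' Pairs mask files by name across two directories (PNG, values
#' thresholded at 0.5), computes the six overlap metrics per pair, and
#' aggregates.  Undefined values (e.g. sensitivity with an empty ground
#' truth) are excluded from the means and counted.
#'
#' @param pred_dir,gt_dir directories with identically named mask files.
#' @return a data frame of class `dcnet_metrics_report` with one row per
#'   pair and columns `file, dsc, sen, spe, ppv, voe, rvd`; means are in
#'   `attr(, "means")`, exclusion counts in `attr(, "n_missing")`.
#' @export
evaluate <- function(pred_dir, gt_dir) {
  pf <- sort(list.files(pred_dir, pattern = "\\.png$"))
  gf <- sort(list.files(gt_dir, pattern = "\\.png$"))
  orphan <- c(setdiff(pf, gf), setdiff(gf, pf))
  if (length(orphan))
    stop("unpaired mask files: ", paste(orphan, collapse = ", "))
  if (!length(pf)) stop("no mask files found")
  rows <- lapply(pf, function(f) {
    P <- read_mask(file.path(pred_dir, f))
    G <- read_mask(file.path(gt_dir, f))
    data.frame(file = f, dsc = dsc(P, G), sen = sen(P, G), spe = spe(P, G),
               ppv = ppv(P, G), voe = voe(P, G), rvd = rvd(P, G))
  })
  rep <- do.call(rbind, rows)
  metric_cols <- c("dsc", "sen", "spe", "ppv", "voe", "rvd")
  attr(rep, "means") <- vapply(rep[metric_cols],
                               function(x) mean(x, na.rm = TRUE), 0)
  attr(rep, "n_missing") <- vapply(rep[metric_cols],
                                   function(x) sum(is.na(x)), 0L)
  class(rep) <- c("dcnet_metrics_report", class(rep))
  rep
}

#' Read a binary mask from a PNG file
#'
#' @param path PNG path; grayscale values are thresholded at 0.5.
#' @return binary integer matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(img >= 0.5), nrow(img), ncol(img))
}

#' Compare two metric reports with the exact Mann-Whitney test
#'
#' @param r1,r2 reports from [evaluate()] (or data frames with the metric
#'   columns).
#' @return named vector of two-sided p-values per metric.
#' @export
compare_reports <- function(r1, r2) {
  metric_cols <- c("dsc", "sen", "spe", "ppv", "voe", "rvd")
  vapply(metric_cols, function(mc) {
    a <- r1[[mc]]; b <- r2[[mc]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) return(NA_real_)
    if (length(a) > 12L) a <- a[seq_len(12L)]
    if (length(b) > 12L) b <- b[seq_len(12L)]
    mann_whitney_exact(a, b)
  }, 0)
}
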