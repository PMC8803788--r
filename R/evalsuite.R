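#' A 7x7x7-voxel volume of interest
#'
#' @param center integer voxel triple (1-based indices).
#' @param organ `"liver"` or `"lung"`.
#' @return an object of class `voi`.
#' @export
voi <- function(center, organ = c("liver", "lung")) {
  organ <- match.arg(organ)
  structure(list(center = as.integer(round(center)), organ = organ,
                 extent = 7L), class = "voi")
}

voi_indices <- function(v, d) {
  half <- 3L
  lo <- v$center - half; hi <- v$center + half
  if (any(lo < 1L) || any(hi > d))
    stopf("VOI at (%s) extends outside the volume",
          paste(v$center, collapse = ", "))
  lapply(1:3, function(i) lo[i]:hi[i])
}

#' VOI statistics: SUV mean, noise SD and background variability
#'
#' For each VOI, the mean and the SD of its 343 voxels (population SD,
#' divide by n). Organ aggregates follow the standard reduced-dose
#' evaluation protocol: `liver_noise_sd` is the arithmetic mean of the
#' liver VOI SDs, and `background_variability` per organ is the sample SD
#' of the VOI means divided by their mean (a coefficient of variation).
#' Values are clipped at zero before quantification.
#'
#' @param volume a [pet_volume()] or 3-D array.
#' @param vois list of [voi()] objects.
#' @return list with `per_voi` (data frame: organ, mean, sd),
#'   `liver_suv_mean`, `lung_suv_mean`, `liver_noise_sd`,
#'   `background_variability` (named by organ).
#' @export
voi_stats <- function(volume, vois) {
  vals <- pmax(as_volume_values(volume), 0)
  d <- dim(vals)
  rows <- lapply(vois, function(v) {
    idx <- voi_indices(v, d)
    x <- vals[idx[[1]], idx[[2]], idx[[3]]]
    m <- mean(x)
    data.frame(organ = v$organ, mean = m,
               sd = sqrt(mean((x - m)^2)))  # population SD over 343 voxels
  })
  per_voi <- do.call(rbind, rows)
  agg <- function(organ) {
    sub <- per_voi[per_voi$organ == organ, ]
    if (nrow(sub) == 0L) return(list(mean = NA_real_, noise = NA_real_,
                                     bv = NA_real_))
    list(mean = mean(sub$mean), noise = mean(sub$sd),
         bv = if (nrow(sub) > 1L) sd(sub$mean) / mean(sub$mean) else NA_real_)
  }
  liv <- agg("liver"); lun <- agg("lung")
  list(per_voi = per_voi,
       liver_suv_mean = liv$mean, lung_suv_mean = lun$mean,
       liver_noise_sd = liv$noise,
       background_variability = c(liver = liv$bv, lung = lun$bv))
}

#' Adaptive-threshold lesion segmentation
#'
#' Within a fixed 7x7x7 bounding box, the threshold is
#' `min + 0.42 * (max - min)`; the mask comprises voxels with value >= the
#' threshold (boundary values included), so the arg-max voxel always
#' belongs to the mask and the lesion SUVmax equals the box maximum. A
#' constant box yields the whole box as mask with a warning (degenerate
#' lesion).
#'
#' @param volume a [pet_volume()] or 3-D array.
#' @param bbox_center integer voxel triple; the box must fit in the volume.
#' @param threshold_fraction adaptive threshold fraction (default 0.42).
#' @return an object of class `lesion_roi` with fields `bbox_center`,
#'   `mask` (7x7x7 logical), `suv_max`, `threshold` and `n_voxels`.
#' @export
segment_lesion <- function(volume, bbox_center, threshold_fraction = 0.42) {
  vals <- pmax(as_volume_values(volume), 0)
  v <- voi(bbox_center, "liver")   # reuse the 7x7x7 box geometry
  idx <- voi_indices(v, dim(vals))
  box <- vals[idx[[1]], idx[[2]], idx[[3]]]
  lo <- min(box); hi <- max(box)
  if (hi == lo)
    warnf("segment_lesion: constant 7x7x7 box at (%s); mask covers the whole box",
          paste(v$center, collapse = ", "))
  thr <- lo + threshold_fraction * (hi - lo)
  mask <- box >= thr
  structure(list(bbox_center = v$center, mask = mask, suv_max = hi,
                 threshold = thr, n_voxels = sum(mask)),
            class = "lesion_roi")
}

#' Apply reference-defined ROIs across image series
#'
#' Organ VOIs (defined on the reference series) are copied verbatim to each
#' series; lesion segmentation is re-run per series at the same bounding-box
#' centres because of its adaptive-threshold basis.
#'
#' @param series named list of [pet_volume()]s on the same voxel grid.
#' @param vois list of [voi()]s.
#' @param lesion_centers list of integer voxel triples.
#' @return list per series: `voi_stats` and `lesions` (list of
#'   `lesion_roi`).
#' @export
transfer_rois <- function(series, vois, lesion_centers) {
  dims <- lapply(series, function(s) dim(as_volume_values(s)))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stopf("image series are not on a common voxel grid")
  lapply(series, function(s) {
    list(voi_stats = voi_stats(s, vois),
         lesions = lapply(lesion_centers, function(ctr)
           segment_lesion(s, ctr)))
  })
}

#' Signed percentage difference against a reference
#'
#' `100 * (series - reference) / reference`. Not exactly antisymmetric in
#' its arguments (the denominator is always the reference).
#'
#' @param series,reference numeric vectors (reference must be nonzero).
#' @return numeric vector of signed percentages.
#' @export
percent_difference <- function(series, reference) {
  if (any(reference == 0)) stopf("reference value is zero")
  100 * (series - reference) / reference
}

#' Ordinary least-squares calibration slope
#'
#' Fits `y = a + b x` (free intercept by default; through-origin fit with
#' `through_origin = TRUE`) for scatter plots of series lesion SUVmax
#' against the reference; the identity line is the no-bias reference.
#'
#' @param x reference values (must have positive variance, n >= 3).
#' @param y series values.
#' @param through_origin logical; fit `y = b x`.
#' @return list with `gradient`, `intercept` and the underlying `lm` fit.
#' @export
scatter_slope <- function(x, y, through_origin = FALSE) {
  if (length(x) < 3L || length(x) != length(y))
    stopf("need n >= 3 paired values")
  if (sd(x) == 0) stopf("reference values have zero variance")
  fit <- if (through_origin) lm(y ~ x + 0) else lm(y ~ x)
  cf <- coef(fit)
  list(gradient = unname(if (through_origin) cf["x"] else cf["x"]),
       intercept = unname(if (through_origin) 0 else cf["(Intercept)"]),
       fit = fit)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `series - reference`; limits of agreement are the mean
#' difference +/- 1.96 sample SDs (n - 1 denominator).
#'
#' @param reference,series paired numeric vectors, n >= 2.
#' @return object of class `bland_altman`: `mean_difference`, `loa_low`,
#'   `loa_high`, `sd_difference`, and the paired means/differences for
#'   plotting.
#' @export
bland_altman <- function(reference, series) {
  if (length(reference) < 2L || length(reference) != length(series))
    stopf("need n >= 2 paired values")
  d <- series - reference
  md <- mean(d); s <- sd(d)
  structure(list(mean_difference = md, loa_low = md - 1.96 * s,
                 loa_high = md + 1.96 * s, sd_difference = s,
                 means = (series + reference) / 2, differences = d),
            class = "bland_altman")
}

#' @export
#' @method print bland_altman
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.4g, limits of agreement [%.4g, %.4g]\n",
              x$mean_difference, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences, xlab = "mean of pair",
                 ylab = "difference (series - reference)", ...)
  graphics::abline(h = c(x$loa_low, x$mean_difference, x$loa_high),
                   lty = c(2, 1, 2))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; absolute differences are ranked with
#' mid-ranks for ties. For effective n <= `exact_max` the two-sided p value
#' is computed exactly by full enumeration of all 2^n sign assignments;
#' beyond that a normal approximation with tie-corrected variance and
#' continuity correction is used. If all differences are zero the test is
#' undefined and a condition of class `petdle_degenerate_test` is
#' signalled.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max largest effective n for the exact branch (default 12).
#' @return list with `statistic` (V, the positive-rank sum), `p.value`,
#'   `n_effective` and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 12L) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop(structure(class = c("petdle_degenerate_test", "error", "condition"),
                   list(message = "all paired differences are zero; the signed-rank test is undefined",
                        call = sys.call())))
  r <- rank(abs(d))            # mid-ranks under ties
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of V over all 2^n equally likely sign patterns
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    stats <- as.vector(signs %*% r)
    p <- 2 * min(mean(stats <= V), mean(stats >= V))
    p <- min(1, p)
    method <- "exact (enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- 0.5 * sign(V - mu)
    z <- (V - mu - cc) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation, tie-corrected, continuity-corrected"
  }
  list(statistic = V, p.value = p, n_effective = n, method = method)
}

#' Quadratic weighted kappa for ordinal agreement
#'
#' `kappa = 1 - sum(w * O) / sum(w * E)` with quadratic disagreement
#' weights `w_ij = (i - j)^2 / (k - 1)^2`, observed table `O` and expected
#' table `E` from the outer product of the marginals scaled to n. If both
#' raters use a single identical category the statistic is undefined and a
#' condition of class `petdle_degenerate_test` is signalled.
#'
#' @param scores_a,scores_b integer score vectors on `0:(n_categories-1)`.
#' @param n_categories number of ordinal categories.
#' @return object of class `kappa_result` with `kappa`, `weighting`
#'   (`"quadratic"`) and `categories`.
#' @export
quadratic_weighted_kappa <- function(scores_a, scores_b, n_categories) {
  if (length(scores_a) != length(scores_b))
    stopf("score vectors must have equal length")
  k <- as.integer(n_categories)
  if (any(c(scores_a, scores_b) < 0) || any(c(scores_a, scores_b) > k - 1L))
    stopf("scores outside category range 0..%d", k - 1L)
  lev <- 0:(k - 1L)
  O <- table(factor(scores_a, levels = lev), factor(scores_b, levels = lev))
  n <- length(scores_a)
  E <- outer(rowSums(O), colSums(O)) / n
  w <- outer(lev, lev, function(i, j) (i - j)^2 / (k - 1)^2)
  denom <- sum(w * E)
  if (denom == 0)
    stop(structure(class = c("petdle_degenerate_test", "error", "condition"),
                   list(message = "kappa undefined: a single category observed for both raters",
                        call = sys.call())))
  structure(list(kappa = 1 - sum(w * O) / denom, weighting = "quadratic",
                 categories = k), class = "kappa_result")
}

#' @export
#' @method print kappa_result
print.kappa_result <- function(x, ...) {
  cat(sprintf("quadratic weighted kappa = %.3f (%d categories)\n",
              x$kappa, x$categories))
  invisible(x)
}

# competition ranking: tied values share a rank, the following number is
# skipped (1, 1, 3, ...)
check_competition_ranks <- function(r) {
  s <- sort(as.integer(r))
  expected <- integer(length(s))
  i <- 1L
  while (i <= length(s)) {
    run <- sum(s == s[i])
    expected[i:(i + run - 1L)] <- i
    i <- i + run
  }
  all(s == expected)
}

#' Aggregate a reader score table
#'
#' Likert scores (0-5) and preference ranks (competition ranking: tied
#' series share a rank and the next number is skipped) per (case, series,
#' metric, reader) are aggregated per (series, metric): mean and sample SD
#' of scores pooled over readers and cases, mean rank, and the percentage
#' of scores >= 3.
#'
#' @param table data frame with columns `case`, `series`, `metric`,
#'   `reader`, `score`, `rank`.
#' @param series_order optional character vector fixing the output series
#'   ordering.
#' @return data frame with one row per (series, metric).
#' @export
aggregate_reader_tables <- function(table, series_order = NULL) {
  need <- c("case", "series", "metric", "reader", "score", "rank")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (any(!table$score %in% 0:5))
    stopf("scores must be integers in 0..5")
  # every (case, metric, reader) must score every series, and ranks must
  # follow competition ranking within each such group
  grp <- interaction(table$case, table$metric, table$reader, drop = TRUE)
  n_series <- length(unique(table$series))
  bad <- names(which(tapply(table$series, grp, function(s)
    length(unique(s)) != n_series)))
  if (length(bad))
    stopf("missing cells for (case, metric, reader): %s",
          paste(bad, collapse = "; "))
  for (g in levels(grp)) {
    r <- table$rank[grp == g]
    if (!check_competition_ranks(r))
      stopf("rank vector (%s) for group %s violates competition ranking",
            paste(sort(r), collapse = ", "), g)
  }
  series_order <- series_order %||% unique(table$series)
  out <- do.call(rbind, lapply(series_order, function(se) {
    do.call(rbind, lapply(unique(table$metric), function(me) {
      sub <- table[table$series == se & table$metric == me, ]
      data.frame(series = se, metric = me,
                 mean_score = mean(sub$score),
                 sd_score = sd(sub$score),
                 mean_rank = mean(sub$rank),
                 pct_ge3 = 100 * mean(sub$score >= 3))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Read a reader score table from CSV
#'
#' @param path CSV with columns case, series, metric, reader, score, rank.
#' @return data frame validated by [aggregate_reader_tables()]'s rules.
#' @export
read_reader_scores <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
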