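#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are taken as `device - reference` (prototype minus gold
#' standard), so a positive bias means the prototype overestimates. Limits of
#' agreement use the conventional 1.96 multiplier on the sample SD (n - 1) of
#' the differences; their midpoint equals the bias exactly.
#'
#' @param device,reference Paired numeric vectors of equal length >= 2.
#' @return List with `n`, `bias`, `sd_diff`, `loa_lower`, `loa_upper`.
#' @export
bland_altman <- function(device, reference) {
  if (length(device) != length(reference))
    stop("paired vectors must have equal length", call. = FALSE)
  ok <- stats::complete.cases(device, reference)
  d <- device[ok] - reference[ok]
  if (length(d) < 2L)
    stop("need at least 2 complete pairs", call. = FALSE)
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  list(n = length(d), bias = bias, sd_diff = sd_diff,
       loa_lower = bias - 1.96 * sd_diff,
       loa_upper = bias + 1.96 * sd_diff)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] with the method-comparison guard rails:
#' at least 3 pairs and nonzero variance in both members.
#'
#' @param x,y Paired numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  stats::cor(x[ok], y[ok])
}

#' ICC(2,1): two-way random effects, absolute agreement, single measures
#'
#' From the two-way ANOVA decomposition of an `n x k` matrix (subjects x
#' raters/systems) with mean squares `MSR` (rows), `MSC` (columns) and `MSE`
#' (residual):
#' `ICC = (MSR - MSE) / (MSR + (k - 1) MSE + (k / n) (MSC - MSE))`.
#' Systematic differences between the systems count against agreement, which
#' is the property that distinguishes this coefficient from a consistency
#' ICC or a Pearson correlation.
#'
#' @param matrix Complete numeric matrix, `n >= 2` subjects x `k >= 2`
#'   raters.
#' @return The intraclass correlation coefficient.
#' @export
icc_2_1 <- function(matrix) {
  m <- as.matrix(matrix)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters",
                             call. = FALSE)
  if (anyNA(m)) stop("ICC requires a complete matrix", call. = FALSE)
  grand <- mean(m)
  if (sum((m - grand)^2) == 0)
    stop("degenerate data: zero total variance", call. = FALSE)
  rowm <- rowMeans(m); colm <- colMeans(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- sum((m - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Coefficient of variation across task repetitions
#'
#' Per subject, `100 * SD / mean` over the repetition values (sample SD);
#' the reported CV is the arithmetic mean across subjects. Subjects with a
#' zero mean are excluded (counted in the `"n_excluded"` attribute).
#'
#' @param per_repetition Numeric matrix, subjects x repetitions.
#' @return Mean CV in percent, with attribute `"n_excluded"`.
#' @export
cv_percent <- function(per_repetition) {
  m <- as.matrix(per_repetition)
  if (ncol(m) < 2L) stop("need at least 2 repetitions", call. = FALSE)
  mu <- rowMeans(m)
  keep <- mu != 0
  if (!any(keep)) stop("all subject means are zero", call. = FALSE)
  if (any(!keep))
    warning(sum(!keep), " subject(s) with zero mean excluded from CV",
            call. = FALSE)
  cv <- 100 * apply(m[keep, , drop = FALSE], 1L, stats::sd) / abs(mu[keep])
  out <- mean(cv)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Intra-device ICC across repetitions
#'
#' [icc_2_1()] applied with the task repetitions as the rater dimension:
#' consistency of a single system across the five repetitions.
#'
#' @param per_repetition Numeric matrix, subjects x repetitions.
#' @return The intraclass correlation coefficient.
#' @export
intra_device_icc <- function(per_repetition) icc_2_1(per_repetition)

#' Bland-Altman plot coordinates
#'
#' Per-pair `(mean, difference)` points plus the bias and limits-of-agreement
#' reference lines, as a plain table consumable by any plotting layer.
#'
#' @inheritParams bland_altman
#' @return List with `points` (data frame `mean`, `difference`) and the
#'   `bias`, `loa_lower`, `loa_upper` line levels.
#' @export
bland_altman_plot_data <- function(device, reference) {
  ba <- bland_altman(device, reference)
  ok <- stats::complete.cases(device, reference)
  list(points = data.frame(mean = (device[ok] + reference[ok]) / 2,
                           difference = device[ok] - reference[ok]),
       bias = ba$bias, loa_lower = ba$loa_lower, loa_upper = ba$loa_upper)
}

#' Build the full agreement table from paired measurements
#'
#' One row per target (muscle or axis) x limb, mirroring the layout of a
#' device-validation report: Bland-Altman bias and 95% LOA, Pearson r,
#' between-device ICC(2,1) on the subjects x {device, reference} matrix, the
#' intra-device ICC of each system across repetitions, and each system's CV.
#' Participants are pooled within each limb separately. Targets with fewer
#' than 3 complete pairs are skipped with a warning. Values are not rounded
#' here; rounding belongs to report rendering.
#'
#' @param measures Data frame in tidy long form with columns `participant`,
#'   `side`, `target`, `system` (`"device"`/`"reference"`), `repetition`
#'   (0 = the headline per-participant value, 1..k = per-repetition values),
#'   `value`.
#' @return Data frame with one row per `target` x `side` and columns `n`,
#'   `bias`, `sd_diff`, `loa_lower`, `loa_upper`, `pearson_r`, `icc_between`,
#'   `icc_intra_device`, `icc_intra_reference`, `cv_device_pct`,
#'   `cv_reference_pct`.
#' @export
build_agreement_table <- function(measures) {
  need <- c("participant", "side", "target", "system", "repetition", "value")
  if (!all(need %in% names(measures)))
    stop("`measures` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  combos <- unique(measures[c("target", "side")])
  combos <- combos[order(combos$target, combos$side), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    tg <- combos$target[i]; sd_ <- combos$side[i]
    sub <- measures[measures$target == tg & measures$side == sd_, ]
    head_ <- sub[sub$repetition == 0L, ]
    wide <- merge(
      head_[head_$system == "device", c("participant", "value")],
      head_[head_$system == "reference", c("participant", "value")],
      by = "participant", suffixes = c("_device", "_reference"))
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
    if (nrow(wide) < 3L) {
      warning(sprintf("target %s/%s skipped: fewer than 3 complete pairs",
                      tg, sd_), call. = FALSE)
      next
    }
    ba <- bland_altman(wide$value_device, wide$value_reference)
    reps <- function(sys) {
      r <- sub[sub$system == sys & sub$repetition > 0L, ]
      stats::reshape(r[c("participant", "repetition", "value")],
                     idvar = "participant", timevar = "repetition",
                     direction = "wide")[, -1L, drop = FALSE]
    }
    rd <- as.matrix(reps("device")); rr <- as.matrix(reps("reference"))
    rows[[length(rows) + 1L]] <- data.frame(
      target = tg, side = sd_, n = ba$n,
      bias = ba$bias, sd_diff = ba$sd_diff,
      loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
      pearson_r = pearson_r(wide$value_device, wide$value_reference),
      icc_between = icc_2_1(cbind(wide$value_device, wide$value_reference)),
      icc_intra_device = intra_device_icc(rd),
      icc_intra_reference = intra_device_icc(rr),
      cv_device_pct = as.numeric(cv_percent(rd)),
      cv_reference_pct = as.numeric(cv_percent(rr)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
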