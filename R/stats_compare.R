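# Success-rate accounting, paired method comparison, confidence ellipses
# and metric-vs-ventriculomegaly correlation.

#' Tract generation success rate
#'
#' @param generated number of successfully generated tract instances.
#' @param attempted number attempted (> 0).
#' @return percentage, rounded half-up to 1 decimal (96.3 for 647/672).
#' @export
success_rate <- function(generated, attempted) {
  if (attempted <= 0) stop("attempted count must be positive")
  if (generated < 0 || generated > attempted) {
    stop("generated must lie in [0, attempted]")
  }
  round_half_up(100 * generated / attempted, 1L)
}

# round half away from zero at `digits` decimals (R's round() is banker's)
round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Paired comparison of two methods' per-subject metrics
#'
#' Computes the Pearson correlation (with its two-sided p-value), the mean
#' difference a - b, and the two-sided paired t-test p-value. Pairs with
#' either value missing are dropped (pairwise deletion); the number of
#' complete pairs is reported. In the study's sign convention a negative
#' mean difference means method B exceeds method A, so when `a` is the
#' standard-atlas method and `b` the pseudo-atlas method, negative values
#' mean the pseudo-atlas metrics are higher.
#'
#' @param a,b aligned numeric vectors (one entry per subject; NA = missing).
#' @param tract,metric optional row tags.
#' @return one-row data.frame: tract, metric, n, r, r_p, mean_diff, t_p,
#'   insufficient (TRUE when < 3 complete pairs; statistics then NA).
#' @export
compare_methods <- function(a, b, tract = "", metric = "") {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  out <- data.frame(tract = tract, metric = metric, n = n, r = NA_real_,
                    r_p = NA_real_, mean_diff = NA_real_, t_p = NA_real_,
                    insufficient = n < 3L, stringsAsFactors = FALSE)
  if (n < 3L) return(out)
  x <- a[ok]; y <- b[ok]
  out$mean_diff <- mean(x - y)
  if (stats::sd(x) > 0 && stats::sd(y) > 0) {
    ct <- stats::cor.test(x, y, method = "pearson")
    out$r <- unname(ct$estimate)
    out$r_p <- ct$p.value
  }
  if (stats::sd(x - y) > 0) {
    tt <- stats::t.test(x, y, paired = TRUE)
    out$t_p <- tt$p.value
  } else {
    out$t_p <- if (out$mean_diff == 0) 1 else 0
  }
  out
}

#' Method-comparison table across tracts and metrics
#'
#' Builds the paired-comparison table (one row per tract x metric in
#' {FA, MD}) from two long-format metric tables as produced by the
#' pipeline (columns subject, tract, FA, MD).
#'
#' @param tab_a,tab_b data.frames with columns `subject`, `tract`, `FA`,
#'   `MD` (bilaterally averaged where applicable).
#' @return data.frame of [compare_methods()] rows.
#' @export
comparison_table <- function(tab_a, tab_b) {
  tracts <- sort(unique(tab_a$tract))
  rows <- list()
  for (tr in tracts) {
    sa <- tab_a[tab_a$tract == tr, ]
    sb <- tab_b[tab_b$tract == tr, ]
    subjects <- sort(union(sa$subject, sb$subject))
    for (met in c("FA", "MD")) {
      va <- sa[[met]][match(subjects, sa$subject)]
      vb <- sb[[met]][match(subjects, sb$subject)]
      rows[[length(rows) + 1L]] <- compare_methods(va, vb, tract = tr,
                                                   metric = met)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Confidence ellipse of a bivariate sample
#'
#' Fits a bivariate normal (sample mean and covariance); the ellipse at
#' `level` is the chi-square(2 df) quantile contour: semi-axes are
#' sqrt(qchisq(level, 2) * eigenvalues of the covariance), oriented along
#' the covariance eigenvectors.
#'
#' @param x,y numeric vectors (>= 3 complete pairs).
#' @param level confidence level in (0, 1), default 0.95.
#' @return object of class `ellipse_summary`: center, covariance,
#'   semi_axes, angle_deg, level, degenerate flag.
#' @export
confidence_ellipse <- function(x, y, level = 0.95) {
  stopifnot(level > 0, level < 1)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("confidence ellipse requires >= 3 pairs")
  S <- stats::cov(cbind(x, y))
  e <- eigen(S, symmetric = TRUE)
  degenerate <- e$values[2] <= .Machine$double.eps * max(1, e$values[1])
  k <- stats::qchisq(level, df = 2)
  semi <- sqrt(pmax(k * e$values, 0))
  ang <- atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
  structure(list(center = c(mean(x), mean(y)), covariance = S,
                 semi_axes = semi, angle_deg = ang, level = level,
                 degenerate = degenerate),
            class = "ellipse_summary")
}

#' @export
print.ellipse_summary <- function(x, ...) {
  cat(sprintf(
    "%.0f%% ellipse: center (%.3g, %.3g), semi-axes %.3g / %.3g, %.1f deg%s\n",
    100 * x$level, x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
    x$angle_deg, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Linear association between a diffusion metric and the Evans' index
#'
#' Ordinary least-squares slope plus Pearson correlation with its
#' two-sided p-value; missing pairs are dropped.
#'
#' @param metric per-subject metric values.
#' @param ei per-subject Evans' indices.
#' @return list with `slope`, `intercept`, `r`, `p`, `n`, and `constant`
#'   (TRUE when the EI vector is constant, leaving the fit undefined).
#' @export
metric_vs_ei <- function(metric, ei) {
  stopifnot(length(metric) == length(ei))
  ok <- !is.na(metric) & !is.na(ei)
  x <- ei[ok]; y <- metric[ok]
  if (length(x) < 3L || stats::sd(x) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                p = NA_real_, n = length(x),
                constant = length(x) >= 3L && stats::sd(x) == 0))
  }
  fit <- stats::lm(y ~ x)
  ct <- if (stats::sd(y) > 0) stats::cor.test(x, y) else NULL
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
       p = if (is.null(ct)) NA_real_ else ct$p.value,
       n = length(x), constant = FALSE)
}
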