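# Method-comparison statistics over per-image count vectors: Pearson
# correlation, intraclass correlation (two-way model, single
# measurement), Cronbach's alpha, percent-difference Bland-Altman limits
# of agreement, and the paired t-test; plus a full pairwise report.

check_pair <- function(x, y, min_n = 3) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < min_n) {
    abort(sprintf("need at least %d pairs, got %d", min_n, length(x)))
  }
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  invisible(NULL)
}

#' Pearson correlation between two count vectors
#'
#' Product-moment correlation with its square and the two-tailed
#' significance, via [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return A one-row tibble: `r`, `r_squared`, `p_value`, `n`.
#' @examples
#' pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))
#' @export
pearson <- function(x, y) {
  check_pair(x, y)
  if (var(x) == 0 || var(y) == 0) {
    abort("`x` and `y` must both have nonzero variance")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
         p_value = ct$p.value, n = length(x))
}

# Two-way ANOVA mean squares of a subjects x raters matrix, the variance
# decomposition every ICC variant is built from.
anova_mean_squares <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  grand <- mean(mat)
  row_means <- rowMeans(mat)
  col_means <- colMeans(mat)
  msr <- k * sum((row_means - grand)^2) / (n - 1)          # subjects
  msc <- n * sum((col_means - grand)^2) / (k - 1)          # raters
  sse <- sum((mat - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))                          # residual
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Intraclass correlation coefficient
#'
#' Two-way model, single-measurement ICC from the subjects x raters
#' ANOVA mean squares, in both the absolute-agreement form (ICC(A,1),
#' sensitive to systematic rater offsets; the default) and the
#' consistency form (ICC(C,1)). The 95% confidence interval uses the
#' standard F-based formulas (McGraw & Wong): exact for the consistency
#' form, Satterthwaite-approximated degrees of freedom for absolute
#' agreement. The p-value tests ICC = 0 via `F = MSR/MSE`.
#'
#' @param data A data frame with one row per subject (image).
#' @param raters Columns holding the raters/methods (character vector of
#'   names; default: all numeric columns).
#' @param type `"agreement"` (ICC(A,1)) or `"consistency"` (ICC(C,1)).
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble: `icc`, `conf_low`, `conf_high`, `p_value`,
#'   `type`, `n_subjects`, `n_raters`.
#' @examples
#' tab <- tibble::tibble(r1 = c(9, 7, 8, 10, 6, 9),
#'                       r2 = c(8, 6, 9, 10, 5, 9),
#'                       r3 = c(9, 8, 8, 11, 6, 10))
#' icc(tab)
#' @export
icc <- function(data, raters = NULL, type = c("agreement", "consistency"),
                conf_level = 0.95) {
  type <- match.arg(type)
  mat <- rater_matrix(data, raters)
  n <- nrow(mat)
  k <- ncol(mat)
  if (k < 2) abort("need at least 2 raters")
  if (n < 5) abort("need at least 5 subjects")
  ms <- anova_mean_squares(mat)
  if (ms$msr == 0 && ms$mse == 0 && ms$msc == 0) {
    abort("degenerate variance decomposition: all counts identical")
  }
  alpha <- 1 - conf_level
  if (type == "consistency") {
    est <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    f <- ms$msr / ms$mse
    fl <- f / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    est <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (ms$msr - fl * ms$mse) /
      (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    hi <- n * (fu * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
  }
  p <- stats::pf(ms$msr / ms$mse, n - 1, (n - 1) * (k - 1),
                 lower.tail = FALSE)
  tibble(icc = est, conf_low = lo, conf_high = hi, p_value = p,
         type = type, n_subjects = n, n_raters = k)
}

rater_matrix <- function(data, raters = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(raters)) {
    raters <- names(data)[vapply(data, is.numeric, TRUE)]
  }
  if (!all(raters %in% names(data))) {
    abort("some `raters` columns are missing from `data`")
  }
  mat <- as.matrix(data[raters])
  if (anyNA(mat)) abort("missing values are not supported")
  mat
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient over the rater columns:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sums))`.
#'
#' @inheritParams icc
#' @return A single numeric value.
#' @export
cronbach_alpha <- function(data, raters = NULL) {
  mat <- rater_matrix(data, raters)
  k <- ncol(mat)
  if (k < 2) abort("need at least 2 raters")
  total_var <- var(rowSums(mat))
  if (total_var == 0) abort("zero variance of rater sums")
  k / (k - 1) * (1 - sum(apply(mat, 2, var)) / total_var)
}

#' Percent-difference Bland-Altman agreement
#'
#' For each pair the percent difference `d_i = 100 (x_i - y_i) /
#' ((x_i + y_i)/2)` is computed; the bias is `mean(d)` and the 95% limits
#' of agreement are `bias +/- 1.96 sd(d)`. The percent scale makes the
#' limits comparable across images whose counts span a wide range. Pairs
#' whose mean is zero have no defined percent difference; they are
#' excluded with a warning.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return A list of class `"bland_altman"`: `bias`, `loa_lower`,
#'   `loa_upper` (percent), `frac_within` (fraction of pairs inside the
#'   limits), `n_pairs`, and a tibble `pairs` with per-pair `mean`,
#'   `percent_diff`. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' ba <- bland_altman_percent(c(100, 120, 90, 150), c(104, 117, 95, 149))
#' glance(ba)
#' @export
bland_altman_percent <- function(x, y) {
  check_pair(x, y)
  pm <- (x + y) / 2
  zero <- pm == 0
  if (any(zero)) {
    warn(sprintf(
      "%d pair(s) with zero mean excluded from percent differences",
      sum(zero)))
    x <- x[!zero]
    y <- y[!zero]
    pm <- pm[!zero]
  }
  if (length(x) < 3) abort("fewer than 3 usable pairs")
  d <- 100 * (x - y) / pm
  bias <- mean(d)
  s <- sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  structure(list(
    bias = bias, loa_lower = loa[1], loa_upper = loa[2],
    frac_within = mean(d >= loa[1] & d <= loa[2]),
    n_pairs = length(d),
    pairs = tibble(mean = pm, percent_diff = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> bias %.2f%%, 95%% LoA [%.2f%%, %.2f%%], %d pairs (%.0f%% within)\n",
    x$bias, x$loa_lower, x$loa_upper, x$n_pairs, 100 * x$frac_within))
  invisible(x)
}

#' @rdname bland_altman_percent
#' @param x,object A `bland_altman` object.
#' @param ... Unused.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @rdname bland_altman_percent
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, loa_lower = x$loa_lower, loa_upper = x$loa_upper,
         frac_within = x$frac_within, n_pairs = x$n_pairs)
}

#' @rdname bland_altman_percent
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$mean, .data$percent_diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower,
                                       object$loa_upper),
                        linetype = 2) +
    ggplot2::labs(x = "Mean of the two methods",
                  y = "Percent difference (%)",
                  title = sprintf("Bias %.1f%%, 95%% LoA [%.1f%%, %.1f%%]",
                                  object$bias, object$loa_lower,
                                  object$loa_upper)) +
    ggplot2::theme_minimal()
}

#' Paired t-test on two count vectors
#'
#' Standard paired t on the differences `x - y`, with the 95% confidence
#' interval of the mean difference. If the differences have zero variance
#' but a nonzero mean the t statistic is infinite and is reported as
#' such (with p = 0).
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @param conf_level Confidence level.
#' @return A one-row tibble: `mean_diff`, `t`, `df`, `p_value`,
#'   `conf_low`, `conf_high`.
#' @export
paired_t <- function(x, y, conf_level = 0.95) {
  check_pair(x, y)
  d <- x - y
  n <- length(d)
  if (sd(d) == 0) {
    md <- mean(d)
    if (md == 0) {
      return(tibble(mean_diff = 0, t = 0, df = n - 1, p_value = 1,
                    conf_low = 0, conf_high = 0))
    }
    return(tibble(mean_diff = md, t = sign(md) * Inf, df = n - 1,
                  p_value = 0, conf_low = md, conf_high = md))
  }
  tt <- t.test(x, y, paired = TRUE, conf.level = conf_level)
  tibble(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         conf_low = tt$conf.int[1], conf_high = tt$conf.int[2])
}

format_p <- function(p) {
  ifelse(p < 1e-15, "<1e-15", format(p, digits = 4))
}

#' Full method-agreement report
#'
#' Computes, for every pair of method columns (including a derived
#' `mean_manual` column, the unweighted mean of the operator columns,
#' treated as the gold standard), the whole statistics battery: Pearson r
#' and r-squared, ICC (absolute agreement and consistency, single
#' measurement, with 95% CI), Cronbach's alpha, the paired t-test, and
#' percent-difference Bland-Altman bias and limits of agreement. A
#' one-way repeated-measures ANOVA p-value across the operator columns is
#' included as an inter-operator homogeneity check, as is the ICC over
#' all methods jointly.
#'
#' @param data A data frame with an image-id column and one numeric count
#'   column per method.
#' @param automated Name of the automated-count column.
#' @param operators Character vector of manual-rater column names
#'   (default: every numeric column except `automated`).
#' @param id Name of the image-id column (default: first non-numeric
#'   column, if any).
#' @return An object of class `"agreement_report"`: `pairwise` (tibble of
#'   per-pair statistics), `overall_icc` (all raters jointly),
#'   `operator_anova_p`, `bland_altman` (the gold-standard-vs-automated
#'   [bland_altman_percent()] object), `n_images`, `methods`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' tab <- tibble::tibble(
#'   image_id = paste0("im", 1:8),
#'   operator1 = c(120, 80, 200, 150, 90, 110, 60, 170),
#'   operator2 = c(118, 85, 190, 155, 92, 108, 63, 165),
#'   operator3 = c(125, 78, 205, 148, 88, 115, 58, 172),
#'   automated = c(122, 82, 195, 152, 91, 112, 61, 168))
#' rep <- agreement_report(tab)
#' glance(rep)
#' @export
agreement_report <- function(data, automated = "automated",
                             operators = NULL, id = NULL) {
  stopifnot(is.data.frame(data))
  if (!automated %in% names(data)) {
    abort(paste0("no `", automated, "` column in `data`"))
  }
  num_cols <- names(data)[vapply(data, is.numeric, TRUE)]
  if (is.null(operators)) operators <- setdiff(num_cols, automated)
  if (length(operators) < 1) abort("no operator columns found")
  if (is.null(id)) {
    non_num <- setdiff(names(data), num_cols)
    id <- if (length(non_num)) non_num[1] else NA_character_
  }
  n <- nrow(data)
  if (n < 3) abort("need at least 3 images")

  methods <- data[c(operators, automated)]
  if (length(operators) >= 2) {
    methods$mean_manual <- rowMeans(data[operators])
  }

  pair_stats <- function(m1, m2) {
    x <- methods[[m1]]
    y <- methods[[m2]]
    pe <- pearson(x, y)
    two <- tibble(a = x, b = y)
    ia <- icc(two, type = "agreement")
    ic <- icc(two, type = "consistency")
    al <- cronbach_alpha(two)
    tt <- paired_t(x, y)
    ba <- suppressWarnings(bland_altman_percent(x, y))
    tibble(method_1 = m1, method_2 = m2,
           pearson_r = pe$r, r_squared = pe$r_squared,
           pearson_p = pe$p_value,
           icc_agreement = ia$icc, icc_conf_low = ia$conf_low,
           icc_conf_high = ia$conf_high,
           icc_consistency = ic$icc,
           cronbach_alpha = al,
           mean_diff = tt$mean_diff, t = tt$t, t_p = tt$p_value,
           diff_conf_low = tt$conf_low, diff_conf_high = tt$conf_high,
           ba_bias = ba$bias, ba_loa_lower = ba$loa_lower,
           ba_loa_upper = ba$loa_upper, ba_frac_within = ba$frac_within)
  }
  combos <- utils::combn(names(methods), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(combos, function(p) pair_stats(p[1], p[2]))

  overall <- if (length(operators) >= 1)
    icc(methods[c(operators, automated)], type = "agreement") else NULL

  anova_p <- NA_real_
  if (length(operators) >= 2) {
    long <- tidyr::pivot_longer(
      dplyr::mutate(data[operators], .image = seq_len(n)),
      -".image", names_to = "operator", values_to = "count")
    fit <- aov(count ~ operator + Error(factor(.image)), data = long)
    s <- summary(fit)
    within <- s[["Error: Within"]][[1]]
    anova_p <- within["operator", "Pr(>F)"]
  }

  gold <- if ("mean_manual" %in% names(methods)) "mean_manual"
          else operators[1]
  ba_main <- suppressWarnings(
    bland_altman_percent(methods[[automated]], methods[[gold]]))

  structure(list(pairwise = pairwise, overall_icc = overall,
                 operator_anova_p = anova_p, bland_altman = ba_main,
                 n_images = n, automated = automated,
                 operators = operators, gold = gold,
                 icc_note = paste(
                   "ICC: two-way model, single measurement;",
                   "absolute agreement reported alongside consistency.",
                   "Bland-Altman percent differences use the pairwise",
                   "mean as denominator.")),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d images; automated = `%s`, gold = `%s`\n",
              x$n_images, x$automated, x$gold))
  cat("#", x$icc_note, "\n")
  row <- dplyr::filter(x$pairwise,
                       (.data$method_1 == x$automated &
                          .data$method_2 == x$gold) |
                         (.data$method_1 == x$gold &
                            .data$method_2 == x$automated))
  if (nrow(row)) {
    cat(sprintf(
      "automated vs %s: r = %.3f (R2 = %.3f), ICC = %.3f [%.3f, %.3f], alpha = %.3f\n",
      x$gold, row$pearson_r, row$r_squared, row$icc_agreement,
      row$icc_conf_low, row$icc_conf_high, row$cronbach_alpha))
    cat(sprintf(
      "  paired t p = %s; Bland-Altman bias %.2f%%, LoA [%.2f%%, %.2f%%]\n",
      format_p(row$t_p), row$ba_bias, row$ba_loa_lower, row$ba_loa_upper))
  }
  if (!is.na(x$operator_anova_p)) {
    cat(sprintf("inter-operator RM-ANOVA p = %s\n",
                format_p(x$operator_anova_p)))
  }
  invisible(x)
}

#' @rdname agreement_report
#' @param x,object An `agreement_report`.
#' @param ... Unused.
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) x$pairwise

#' @rdname agreement_report
#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  row <- dplyr::filter(x$pairwise,
                       (.data$method_1 == x$automated &
                          .data$method_2 == x$gold) |
                         (.data$method_1 == x$gold &
                            .data$method_2 == x$automated))
  tibble(n_images = x$n_images,
         pearson_r = row$pearson_r, r_squared = row$r_squared,
         icc = row$icc_agreement, icc_conf_low = row$icc_conf_low,
         icc_conf_high = row$icc_conf_high,
         cronbach_alpha = row$cronbach_alpha,
         mean_diff = row$mean_diff, t_p = row$t_p,
         ba_bias = row$ba_bias, ba_loa_lower = row$ba_loa_lower,
         ba_loa_upper = row$ba_loa_upper,
         overall_icc = if (is.null(x$overall_icc)) NA_real_
                       else x$overall_icc$icc,
         operator_anova_p = x$operator_anova_p)
}

#' @rdname agreement_report
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  autoplot(object$bland_altman) +
    ggplot2::labs(subtitle = sprintf("%s vs %s (n = %d)",
                                     object$automated, object$gold,
                                     object$n_images))
}

#' Serialize an agreement report to JSON
#'
#' @param report An [agreement_report()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  out <- list(
    note = report$icc_note,
    n_images = report$n_images,
    automated = report$automated,
    operators = report$operators,
    gold_standard = report$gold,
    pairwise = report$pairwise,
    overall_icc = report$overall_icc,
    operator_anova_p = report$operator_anova_p,
    bland_altman = glance(report$bland_altman)
  )
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
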