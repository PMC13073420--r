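ff_measures <- c(caput = "ff_caput", corpus = "ff_corpus",
                 cauda = "ff_cauda", whole = "ff_whole",
                 delta_ff = "delta_ff")

#' Assign subjects to the study's age bands
#'
#' Bands are half-open on the right -- `[20, 30)`, `[30, 40)`, `[40, 50)` --
#' except the oldest, `[50, 70]`, which includes 70. A subject aged exactly
#' 30 therefore falls in the 30-40 band. Ages outside `[20, 70]` are
#' rejected.
#'
#' @param age Age(s) in years.
#' @return Character vector of band labels
#'   (`"20-30"`, `"30-40"`, `"40-50"`, `"50-70"`).
#' @examples
#' assign_age_band(c(20, 30, 49.9, 70))
#' @export
assign_age_band <- function(age) {
  if (any(is.na(age))) stop("age must not be missing")
  if (any(age < 20 | age > 70))
    stop("age out of cohort range: subjects must be 20-70 years, got ",
         paste(utils::head(age[age < 20 | age > 70], 5L), collapse = ", "))
  as.character(cut(age, breaks = c(20, 30, 40, 50, 70),
                   labels = c("20-30", "30-40", "40-50", "50-70"),
                   right = FALSE, include.lowest = TRUE))
}

#' Group key for one subject
#'
#' Deterministic mapping of a subject to their analysis group: age band,
#' exposure, and (for exposed subjects only) the drinking-status stratum.
#'
#' @param age Age in years, in `[20, 70]`.
#' @param exposure `"control"` or `"alcohol"`.
#' @param abstinence Stratum label for alcohol subjects
#'   (`"current"`, `"<1y"`, `"1-2y"`); ignored for controls.
#' @return A list with elements `age_band`, `exposure`,
#'   `abstinence_stratum` (`NA` for controls).
#' @export
assign_group <- function(age, exposure, abstinence = "none") {
  exposure <- match.arg(exposure, c("control", "alcohol"))
  list(age_band = assign_age_band(age), exposure = exposure,
       abstinence_stratum = if (exposure == "alcohol") abstinence
                            else NA_character_)
}

#' Per-group summary statistics of pancreatic fat measures
#'
#' For every (age band, exposure) group -- plus the pooled 20-50 aggregate
#' of the three younger bands -- computes the number of subjects and, for
#' each measure (caput, corpus, cauda, whole-pancreas fat fraction and the
#' regional range `delta_ff`), the mean, sample standard deviation
#' (`n - 1` denominator) and coefficient of variation `sd / mean`.
#'
#' @param profiles A subject-profile data frame (see [subject_profile()])
#'   with `age` and `exposure` populated.
#' @return A long-format data frame with columns `age_band`, `exposure`,
#'   `n`, `measure`, `mean`, `sd`, `cv`. Groups with fewer than 2 subjects
#'   are dropped with a warning.
#' @export
summarize_groups <- function(profiles) {
  stopifnot(all(c("age", "exposure", ff_measures) %in% names(profiles)))
  profiles$age_band <- assign_age_band(profiles$age)
  agg <- profiles[profiles$age_band %in% c("20-30", "30-40", "40-50"), ]
  agg$age_band <- "20-50"
  all_p <- rbind(profiles, agg)
  all_p$age_band <- factor(all_p$age_band,
                           levels = c("20-30", "30-40", "40-50", "20-50",
                                      "50-70"))
  out <- do.call(rbind, lapply(
    split(all_p, list(all_p$age_band, all_p$exposure), drop = TRUE),
    function(g) {
      if (nrow(g) < 2L) {
        warning("group ", g$age_band[1L], "/", g$exposure[1L],
                " has fewer than 2 subjects; excluded from summaries")
        return(NULL)
      }
      do.call(rbind, lapply(names(ff_measures), function(m) {
        v <- g[[ff_measures[[m]]]]
        data.frame(age_band = as.character(g$age_band[1L]),
                   exposure = g$exposure[1L], n = nrow(g), measure = m,
                   mean = mean(v), sd = stats::sd(v),
                   cv = if (mean(v) > 0) stats::sd(v) / mean(v) else NA_real_)
      }))
    }))
  rownames(out) <- NULL
  out[order(out$age_band, out$exposure, match(out$measure,
                                              names(ff_measures))), ]
}

comparison_result <- function(test_name, statistic, p_value, groups = NULL,
                              ...) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, groups = groups, ...),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  if (!is.null(x$groups))
    cat("  groups:", paste(x$groups, collapse = " vs "), "\n")
  invisible(x)
}

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition, computed through a
#' linear-model fit. All values equal across every group yields F = 0,
#' p = 1 rather than an error.
#'
#' @param values Numeric response.
#' @param groups Group labels, same length as `values`; at least two groups
#'   with n >= 2 each.
#' @return A `comparison_result` with the F statistic, p-value and degrees
#'   of freedom (`df`).
#' @examples
#' anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
anova_oneway <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 values")
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  if (stats::var(values) == 0)
    return(comparison_result("one-way ANOVA", statistic = 0, p_value = 1,
                             df = c(df1, df2)))
  tab <- stats::anova(stats::lm(values ~ groups))
  comparison_result("one-way ANOVA",
                    statistic = tab[["F value"]][1L],
                    p_value = tab[["Pr(>F)"]][1L],
                    df = c(df1, df2))
}

#' Asymptotic test for equality of two coefficients of variation
#'
#' Miller's asymptotic z-test (the "u test") comparing the coefficients of
#' variation of two independent normal samples:
#' \deqn{u = \frac{cv_1 - cv_2}{\sqrt{\bar c^2 (0.5 + \bar c^2)
#'   \left(\tfrac{1}{n_1 - 1} + \tfrac{1}{n_2 - 1}\right)}},}
#' where \eqn{\bar c} is the pooled CV, the degrees-of-freedom-weighted mean
#' \eqn{((n_1 - 1) cv_1 + (n_2 - 1) cv_2) / (n_1 + n_2 - 2)}. `u` is
#' referred to the standard normal, two-sided.
#'
#' @param cv1,cv2 Sample coefficients of variation (> 0).
#' @param n1,n2 Sample sizes (>= 2).
#' @return A `comparison_result` with the u statistic and p-value.
#' @examples
#' cv_u_test(0.342, 39, 0.238, 37)
#' @export
cv_u_test <- function(cv1, n1, cv2, n2) {
  if (n1 < 2 || n2 < 2) stop("both samples need n >= 2")
  if (cv1 <= 0 || cv2 <= 0) stop("coefficients of variation must be positive")
  cbar <- ((n1 - 1) * cv1 + (n2 - 1) * cv2) / (n1 + n2 - 2)
  v <- cbar^2 * (0.5 + cbar^2) * (1 / (n1 - 1) + 1 / (n2 - 1))
  u <- (cv1 - cv2) / sqrt(v)
  comparison_result("u test (CV equality, Miller)", statistic = u,
                    p_value = 2 * stats::pnorm(-abs(u)))
}

#' Bootstrap test for equality of two coefficients of variation
#'
#' Nonparametric alternative to [cv_u_test()] for raw data: resamples each
#' group with replacement and compares the observed CV difference with its
#' bootstrap null distribution (groups centered to a common CV under the
#' null via scaling).
#'
#' @param x1,x2 Raw samples (positive means required).
#' @param n_boot Number of bootstrap replicates.
#' @return A `comparison_result` with the observed CV difference and the
#'   bootstrap p-value.
#' @export
cv_bootstrap_test <- function(x1, x2, n_boot = 2000) {
  cv <- function(v) stats::sd(v) / mean(v)
  if (mean(x1) <= 0 || mean(x2) <= 0) stop("samples must have positive means")
  obs <- cv(x1) - cv(x2)
  # null: rescale both groups to the pooled CV, keeping their means
  pooled <- ((length(x1) - 1) * cv(x1) + (length(x2) - 1) * cv(x2)) /
    (length(x1) + length(x2) - 2)
  null1 <- mean(x1) + (x1 - mean(x1)) * pooled / cv(x1)
  null2 <- mean(x2) + (x2 - mean(x2)) * pooled / cv(x2)
  diffs <- vapply(seq_len(n_boot), function(i) {
    cv(sample(null1, replace = TRUE)) - cv(sample(null2, replace = TRUE))
  }, numeric(1))
  p <- (1 + sum(abs(diffs) >= abs(obs))) / (n_boot + 1)
  comparison_result("bootstrap CV equality test", statistic = obs,
                    p_value = p)
}

#' Intra-observer intraclass correlation coefficient
#'
#' Single-measure, absolute-agreement ICC from a two-way mixed-effects
#' model, i.e. ICC(A,1): subjects are random, the repeated reading occasions
#' are fixed. Computed from the two-way ANOVA mean squares
#' (rows = subjects, columns = occasions):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E)}.}
#'
#' @param ratings An `n x k` numeric matrix (or data frame): `n` subjects
#'   measured on `k >= 2` occasions by the same observer; `n >= 5`.
#' @return The ICC (a scalar in `[-1, 1]`).
#' @examples
#' set.seed(1)
#' truth <- rnorm(20, 6, 1.5)
#' icc_intraobserver(cbind(truth + rnorm(20, 0, 0.1),
#'                         truth + rnorm(20, 0, 0.1)))
#' @export
icc_intraobserver <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop("need at least 5 paired measurements")
  if (k < 2L) stop("need at least 2 measurement occasions")
  if (anyNA(ratings)) stop("ratings must be complete")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom == 0) return(1)  # all readings identical
  (msr - mse) / denom
}

#' Shapiro-Wilk normality check
#'
#' Wrapper around the Shapiro-Wilk test used to annotate group summaries
#' before parametric testing. The check gates nothing: parametric tests are
#' still run, the result is carried as an annotation.
#'
#' @param values Numeric sample, 3 <= n <= 5000, non-constant.
#' @return A `comparison_result` with the W statistic and p-value.
#' @export
check_normality <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n)
  if (stats::var(values) == 0)
    stop("degenerate sample: all values identical, normality undefined")
  sw <- stats::shapiro.test(values)
  comparison_result("Shapiro-Wilk", statistic = unname(sw$statistic),
                    p_value = sw$p.value)
}

#' Effect of drinking status on whole-pancreas fat fraction
#'
#' Summarizes alcohol-exposed subjects by drinking-status stratum (current
#' drinkers, abstainers < 1 year, abstainers 1-2 years, plus the pooled
#' "all abstainers" column), split by age 20-50 versus 50-70, and runs a
#' one-way ANOVA across the three base strata within each age split.
#'
#' @param profiles Subject profiles; only rows with `exposure == "alcohol"`
#'   are used.
#' @return A list with `summary` (data frame: `age_band`, `stratum`, `n`,
#'   `mean`, `sd` of whole-pancreas FF) and `tests` (named list of
#'   `comparison_result`, one per age split with >= 2 populated strata;
#'   splits with a single stratum yield a summary only).
#' @export
compare_abstinence <- function(profiles) {
  alc <- profiles[profiles$exposure == "alcohol", ]
  if (!nrow(alc)) stop("no alcohol-exposed subjects in `profiles`")
  alc$age_split <- ifelse(assign_age_band(alc$age) == "50-70",
                          "50-70", "20-50")
  strata <- c("current", "<1y", "1-2y")
  bad <- !alc$abstinence %in% strata
  if (any(bad))
    stop("alcohol subjects must carry an abstinence stratum of ",
         paste(strata, collapse = "/"))
  summary <- do.call(rbind, lapply(split(alc, alc$age_split), function(g) {
    one <- function(label, v) {
      if (!length(v)) {
        warning("empty stratum '", label, "' in age band ",
                g$age_split[1L], "; excluded")
        return(NULL)
      }
      data.frame(age_band = g$age_split[1L], stratum = label,
                 n = length(v), mean = mean(v), sd = stats::sd(v))
    }
    rbind(one("current", g$ff_whole[g$abstinence == "current"]),
          one("all abstainers", g$ff_whole[g$abstinence != "current"]),
          one("<1y", g$ff_whole[g$abstinence == "<1y"]),
          one("1-2y", g$ff_whole[g$abstinence == "1-2y"]))
  }))
  rownames(summary) <- NULL
  tests <- lapply(split(alc, alc$age_split), function(g) {
    present <- intersect(strata, unique(g$abstinence))
    keep <- g$abstinence %in% present
    if (length(present) < 2L) return(NULL)
    anova_oneway(g$ff_whole[keep], g$abstinence[keep])
  })
  list(summary = summary, tests = Filter(Negate(is.null), tests))
}

#' Render group summaries as publication-style tables
#'
#' `render_ff_table()` lays out mean +/- SD of the four fat-fraction
#' measures per group; `render_cv_table()` lays out their coefficients of
#' variation (3 decimals). Both return plain data frames suitable for
#' [write_table_delim()].
#'
#' @param summaries Output of [summarize_groups()].
#' @param digits Decimals for means and SDs.
#' @return A wide-format data frame, one row per (age band, exposure).
#' @export
render_ff_table <- function(summaries, digits = 2) {
  wide_by(summaries, function(r)
    sprintf(paste0("%.", digits, "f +/- %.", digits, "f"), r$mean, r$sd))
}

#' @rdname render_ff_table
#' @export
render_cv_table <- function(summaries, digits = 3) {
  wide_by(summaries, function(r) sprintf(paste0("%.", digits, "f"), r$cv),
          measures = c("caput", "corpus", "cauda", "whole"))
}

wide_by <- function(summaries, fmt,
                    measures = c("caput", "corpus", "cauda", "whole",
                                 "delta_ff")) {
  keys <- unique(summaries[c("age_band", "exposure", "n")])
  for (m in measures) {
    keys[[m]] <- vapply(seq_len(nrow(keys)), function(i) {
      r <- summaries[summaries$age_band == keys$age_band[i] &
                       summaries$exposure == keys$exposure[i] &
                       summaries$measure == m, ]
      if (!nrow(r)) NA_character_ else fmt(r[1L, ])
    }, character(1))
  }
  rownames(keys) <- NULL
  keys
}
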