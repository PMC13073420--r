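# Brute-force statistical oracles, independent of the package's code paths.

# OLS slope/intercept by explicit normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# one-way ANOVA F by explicit between/within sum-of-squares decomposition
anova_oracle <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ss_between / df1) / (ss_within / df2)
  c(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# scalar transcription of the two dual-echo product formulas
forward_oracle <- function(w, f, t2_star, tr = 80, te_ip = 2.46,
                           te_op = 1.23, flip = 50, t1w = 828, t1f = 382) {
  ss <- function(t1) {
    al <- flip * pi / 180
    e1 <- exp(-tr / t1)
    sin(al) * (1 - e1) / (1 - cos(al) * e1)
  }
  c(si_ip = (w * ss(t1w) + f * ss(t1f)) * exp(-te_ip / t2_star),
    si_op = abs(w * ss(t1w) - f * ss(t1f)) * exp(-te_op / t2_star))
}

default_params <- acquisition_params()
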