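# Independent oracles kept deliberately naive: explicit sums and manual
# order statistics, no calls into the code paths they check.

# OLS by the normal equations, explicit sums
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum((x - sx / n)^2)
  sxy <- sum((x - sx / n) * (y - sy / n))
  slope <- sxy / sxx
  list(slope = slope, intercept = sy / n - slope * sx / n)
}

# Pearson r and two-sided t-test p-value from first principles
pearson_oracle <- function(x, y) {
  n <- length(x)
  xm <- x - mean(x); ym <- y - mean(y)
  r <- sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# type-7 quantile by hand: linear interpolation of order statistics
quantile7_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[pmin(lo + 2, length(x))] - s[lo + 1])
}

# brute-force reimplementation of the error summary
summary_oracle <- function(pe) {
  n <- length(pe)
  ae <- abs(pe)
  med <- function(v) {
    s <- sort(v)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  svar <- function(v) sum((v - sum(v) / n)^2) / (n - 1)
  list(n = n,
       me = sum(pe) / n,
       sd = if (n > 1) sqrt(svar(pe)) else NA_real_,
       median_error = med(pe),
       mae = sum(ae) / n,
       sd_ae = if (n > 1) sqrt(svar(ae)) else NA_real_,
       median_ae = med(ae),
       iqr = if (n > 1) quantile7_oracle(pe, 0.75) - quantile7_oracle(pe, 0.25)
             else NA_real_,
       pct_within_05 = 100 * sum(ae <= 0.5) / n,
       pct_within_10 = 100 * sum(ae <= 1.0) / n,
       pct_within_15 = 100 * sum(ae <= 1.5) / n)
}

# keratometric index that makes the plain-Haigis corneal power coincide
# with the Haigis-L power at radius r_mm, for agreement fixtures
matching_kerat_index <- function(r_mm) {
  1 + corneal_power_haigis_l(r_mm) * r_mm / 1000
}

# SA8 at which the default regression predicts zero error
sa8_at_root <- function(model = pe_model()) -model$intercept / model$slope

# a tiny hand-checkable two-eye cohort built on the worked example
toy_cohort <- function() {
  data.frame(eye_id = c("toy_1", "toy_2"),
             axial_length_mm = c(28.43, 28.43),
             acd_mm = c(3.62, 3.62),
             mean_corneal_radius_mm = c(8.79, 8.79),
             sa8_um = c(3.69, 3.69),
             implanted_power_d = c(20, 22.365844),
             postop_se_d = c(1.418, 0),
             stringsAsFactors = FALSE)
}
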