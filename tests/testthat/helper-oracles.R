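# Closed-form oracles independent of the simulation code paths.

# Moments of K * C * IR / BW with independent lognormal C, IR, BW.
lognormal_product_moments <- function(conc, ir, bw, constants) {
  k <- constants$unit_factor * constants$ef * constants$ed * constants$csf /
    constants$at
  m <- log(k) + conc$meanlog + ir$meanlog - bw$meanlog
  s2 <- conc$sdlog^2 + ir$sdlog^2 + bw$sdlog^2
  mean <- exp(m + s2 / 2)
  list(meanlog = m, sdlog = sqrt(s2),
       mean = mean, sd = mean * sqrt(exp(s2) - 1))
}

# Spearman correlation implied by a bivariate normal with correlation rho.
spearman_from_pearson <- function(rho) (6 / pi) * asin(rho / 2)

# Pearson correlation of one input's log with the log-risk when all inputs
# are independent lognormals (sign = the input's exponent in the risk).
input_log_correlation <- function(sd_input, sds_all, sign = 1) {
  sign * sd_input / sqrt(sum(sds_all^2))
}
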