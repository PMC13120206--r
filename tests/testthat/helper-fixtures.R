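# small in-code fixtures shared across test files

# a valid sample table with deterministic, hand-checkable values
make_table <- function(n = 4, al = FALSE) {
  base <- c(As = 12, Cd = 0.4, Cr = 70, Cu = 30, Hg = 0.15,
            Mn = 1100, Ni = 35, Pb = 32, Zn = 110)
  df <- data.frame(site_id = sprintf("S%d", seq_len(n)))
  for (m in names(base)) df[[m]] <- base[[m]] * (1 + 0.1 * seq_len(n))
  if (al) df$Al <- 115000 + 1000 * seq_len(n)
  sample_table(df, require_al = al)
}

# Table 6 mean concentrations keyed by metal, used in risk tests
liuye_means <- function() {
  p <- default_liuye_profile()$metals
  stats::setNames(p$mean, p$metal)
}

# closed-form lognormal moment bridge (independent of fit_by_moments)
lnorm_pars <- function(mean, cv) {
  s2 <- log(1 + cv^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}
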