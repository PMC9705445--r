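# Independent oracle for the exact two-sided Mann-Whitney p-value:
# enumerate every assignment of the pooled values to the two groups and
# count assignments whose U statistic is at least as extreme (both tails of
# the symmetric no-ties null). Used only to check the package's test, never
# as the implementation.
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  nb <- length(b)
  ustat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- ustat(a, b)
  mu <- na * nb / 2
  combs <- utils::combn(length(pooled), na)
  us <- apply(combs, 2, function(idx) ustat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Closed-form Pearson chi-square for a 2x2 table.
chisq_closed_form <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- sum(m)
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Write a simulated cohort's closed-form outcomes to CSV in the documented
# supplementary-table schema and reload it through the package reader.
roundtrip_outcomes_csv <- function(sim) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(analytic_outcomes(sim), path, row.names = FALSE)
  load_supplementary_outcomes(path)
}
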