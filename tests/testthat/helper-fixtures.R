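# shared fixtures, built in code

defaultReg <- defaultRegistry()

# brute-force weighted sums over the default registry used as independent
# oracles against the pipeline implementations
oracleWeightedSum <- function(registry, weights_fun) {
  sp <- speciesTable(registry)
  sum(vapply(seq_len(nrow(sp)), function(i) {
    sp$mass_fraction[i] * weights_fun(sp$name[i], sp$length_nt[i])
  }, numeric(1)))
}

# logistic size-bias closed form, written out independently of the package
oracleLogistic <- function(L, l50, w, floor) {
  floor + (1 - floor) / (1 + exp((L - l50) / w))
}

# the isoleucine-starvation ground-truth folds at a given time, straight from
# the anchor definition F(t) = a^(t/80)
isoFold <- function(species, t) {
  anchors <- c(`23S` = 0.75, `16S` = 0.75, `5S` = 0.95, tRNA = 1.10,
               other = 1.00)
  anchors[[species]]^(t / 80)
}

noisySettings <- list(counting = "poisson", densitometry_cv = 0.05,
                      load_cv = 0.1)

# Welch statistics written out from the closed-form definitions (independent
# oracle for the t.test-backed implementation)
oracleWelch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p_value = p)
}
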