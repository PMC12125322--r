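# Shared fixtures, built in code.

# canonical epithelial / mesenchymal spot panels
epithelial_panel <- function(zeb1 = 0) {
  list(cdx2_intensity = 3, cdx2_pct = 90, frmd6_intensity = 0, frmd6_pct = 0,
       htr2b_intensity = 0, ker_intensity = 3, ker_pct = 90, zeb1_pct = zeb1)
}
mesenchymal_panel <- function() {
  list(cdx2_intensity = 0, cdx2_pct = 10, frmd6_intensity = 2,
       frmd6_pct = 70, htr2b_intensity = 2, ker_intensity = 1, ker_pct = 30,
       zeb1_pct = 15)
}

panels_df <- function(panels) {
  do.call(rbind, lapply(panels, as.data.frame))
}

# latent generator label -> reported label
latent_to_label <- function(latent) {
  c(CMS1L = "CMS1-like", CMS2L = "CMS2-like",
    CMS3L = "CMS3-like", CMS4L = "CMS4-like")[latent]
}

# tiny survival fixture with hand-checkable KM values
hand_km_data <- function() {
  data.frame(time = c(1, 2, 3, 4), event = c(TRUE, TRUE, FALSE, TRUE))
}

# brute-force Efron partial log-likelihood for a single covariate (used as
# an independent grid-search oracle against the Newton fit)
grid_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event]))) {
    risk <- which(time >= t)
    dead <- which(event & time == t)
    d <- length(dead)
    w <- exp(beta * x)
    s0 <- sum(w[risk]); s0d <- sum(w[dead])
    ll <- ll + sum(beta * x[dead])
    for (l in seq_len(d) - 1) ll <- ll - log(s0 - (l / d) * s0d)
  }
  ll
}
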