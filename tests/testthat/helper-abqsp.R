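# Shared fixtures: the two published coupling presets, the shipped
# calibrated surrogate (loaded once), and an independent brute-force
# effect-matrix oracle built from scalar arithmetic.

cp_final <- coupling_presets("final")
cp_calib <- coupling_presets("mci_calibration")
sp_cal <- surrogate_params()
rp_def <- receptor_params()

# independent scalar evaluation of the coupling equations, cell by cell
brute_effect_cell <- function(x, y, p) {
  g <- if (p$x0 > 0 && x <= p$x0) {
    1 + p$delta * x / p$x0 - y * p$alpha_star
  } else {
    1 + p$delta + (p$x0 - x) * p$alpha - y * p$alpha_star
  }
  a7 <- 1 - p$beta * (x + y)
  c(g = max(g, 0), a7 = max(a7, 0))
}

brute_effect_matrix <- function(p) {
  out <- NULL
  for (y in 0:16) for (x in 0:16) {
    out <- rbind(out, c(x = x, y = y, brute_effect_cell(x, y, p)))
  }
  as.data.frame(out)
}
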