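# Builds the packaged synthetic AR(1) noise model (20 sensors): spatially
# smooth lag-1 coefficients rescaled to spectral radius 0.95 and a spatially
# correlated innovation covariance. Synthetic stand-in for a model fitted to
# real ongoing recordings; regenerate with: Rscript data-raw/make_ar1_fixture.R
idx <- 1:20
k <- exp(-abs(outer(idx, idx, "-")) / 2)
a <- 0.95 * k / max(Mod(eigen(k, only.values = TRUE)$values))
sigma <- exp(-abs(outer(idx, idx, "-")) / 4)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(signif(a, 10), "inst/extdata/ar1_synthetic_coefficients.tsv",
            sep = "\t", row.names = FALSE, col.names = FALSE)
write.table(signif(sigma, 10), "inst/extdata/ar1_synthetic_innovation_cov.tsv",
            sep = "\t", row.names = FALSE, col.names = FALSE)
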