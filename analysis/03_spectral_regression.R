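#!/usr/bin/env Rscript
## The spectral spline regression. The published community table carries band
## summaries only (the raw per-wavelength spectra are not published), so the
## regression is demonstrated on synthetic communities: effect recovery at
## n = 500 and the size of the 5-df F test under a null community.

suppressMessages(library(fruitsignals))
dir.create("results", showWarnings = FALSE)

cmty <- generate_community(community_config(n_species = 500, seed = 8))
fit <- fit_spectral_model(cmty)
eff <- band_effects(fit)
print(fit)
print(eff)
write.csv(eff, "results/band_effects_synthetic.csv", row.names = FALSE)

cat(sprintf("\nInjected blue effect: %.3f per unit blue %%;",
            cmty$true_effects[["blue"]]))
cat(sprintf(" recovered blue band effect: %.4f (SE %.4f)\n",
            eff$cumulative_coefficient[eff$band == "blue"],
            eff$std_error[eff$band == "blue"]))
cat("The spline smooths the band-limited injection, so the recovered\n")
cat("coefficient sits at ~84% of the injected step height (see vignette).\n")

rej <- 0; n_null <- 200
for (i in seq_len(n_null)) {
  null_cm <- generate_community(community_config(n_species = 56,
                                                 blue_voc_effect = 0,
                                                 seed = 3000 + i))
  if (fit_spectral_model(null_cm)$f_p < 0.05) rej <- rej + 1
}
cat(sprintf("F-test size at nominal 0.05 over %d null communities: %.3f\n",
            n_null, rej / n_null))
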