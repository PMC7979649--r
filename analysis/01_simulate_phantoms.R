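#!/usr/bin/env Rscript
# Synthesize the digital phantoms every later stage consumes: the
# three-vessel hepatic phase-contrast phantom (sham-rat worked example:
# PV 29.9, infra-hepatic IVC 38.2, derived HA 11.9 ml/min, so supra-hepatic
# IVC carries 80.0 ml/min), with a smooth background phase error and
# 0.05 rad phase noise, and the 6 x 2 mm truncated-ellipsoid LV cine stack.
# Images go to results/images/ (NIfTI), ground truth to JSON.

suppressPackageStartupMessages(library(cavalflow))
dir.create("results/images", recursive = TRUE, showWarnings = FALSE)
seed <- 1L

specs <- hepatic_vessel_specs()  # PV 29.9 / infra 38.2 / HA 11.9 ml/min
phantom <- synthesize_pcmri(
  specs, pixel_spacing = 0.208, matrix_size = 64,
  background = c(0.10, 0.05, -0.05, 0.02, 0, 0.02), noise_sd = 0.05,
  liver_weight = 15, body_weight = 470, seed = seed)
write_pcmri(phantom, "results/images")

cat("Hepatic phantom ground truth (ml/min):\n")
cat(sprintf("  PV %.1f, infra IVC %.1f, supra IVC %.1f -> TLBF %.1f, HA %.1f (%.1f%% of TLBF)\n",
            phantom$truth$mean_flows[["pv"]],
            phantom$truth$mean_flows[["infra_ivc"]],
            phantom$truth$mean_flows[["supra_ivc"]],
            phantom$truth$tlbf, phantom$truth$ha_flow,
            phantom$truth$ha_fraction))

lv <- lv_phantom_spec(edv = 0.66, esv = 0.25, wall_volume = 0.857,
                      n_slices = 6, slice_thickness = 2, n_phases = 20,
                      heart_rate = 333, body_weight = 470)
cine <- synthesize_cine(lv)  # masks regenerate from the spec; not persisted
cat(sprintf("Cine phantom: EDV %.2f ml, ESV %.2f ml, EF %.1f%%, wall %.3f ml (6 x 2 mm slices)\n",
            cine$truth$edv, cine$truth$esv, cine$truth$ef,
            cine$truth$wall_volume))
jsonlite::write_json(cine$truth[c("edv", "esv", "sv", "ef", "wall_volume",
                                  "lv_mass", "heart_rate", "body_weight")],
                     "results/cine_ground_truth.json",
                     auto_unbox = TRUE, digits = NA)
cat("wrote results/images/ and results/cine_ground_truth.json\n")
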