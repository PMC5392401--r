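#!/usr/bin/env Rscript
# The full decentration study: 2 telescopes x optimized/nonoptimized x
# far/near x anterior-lens decentrations 0-1 mm in 0.2 mm steps.
#
# Emits the three study tables: optical (RMS wavefront error, waves) and
# visual (VSOTF) quality at the far target (table 1) and near target
# (table 2), and the retinal image decentration produced by lens
# decentration (table 3), plus a provenance file.

suppressMessages(library(itseye))
dir.create("results", showWarnings = FALSE)
cfg <- simulation_config()          # 64 x 64 pupil sampling

t0 <- Sys.time()
records <- run_sweep(cfg, verbose = TRUE)
cat(sprintf("sweep: %d cells in %.1f min\n", nrow(records),
            as.numeric(Sys.time() - t0, units = "mins")))

paths <- emit_tables(records, "results")
utils::write.csv(records, "results/sweep_records.csv", row.names = FALSE)

opts <- attr(records, "optimizer_results")
meta <- list(
  wavelength_nm = cfg$wavelength_nm,
  pupil_diameter_mm = cfg$pupil_diameter_mm,
  pupil_sampling = cfg$n_grid,
  rms_convention = paste(cfg$rms_remove, collapse = "+"),
  csf_params = cfg$csf_params,
  eye_constants = cfg$eye,
  its2_placement_offset_mm = build_its2()$placement_offset,
  assumption = "retina fixed at the cited axial length (23.95 mm); no best-focus shift",
  optimizer_results = lapply(opts, function(o)
    list(k = o$k, a2 = o$a2, a4 = o$a4, achieved_rms_waves = o$achieved_rms))
)
yaml::write_yaml(meta, "results/run_meta.yaml")
cat("written:", paste(c(paths, "results/sweep_records.csv",
                        "results/run_meta.yaml"), collapse = ", "), "\n")

# headline observations mirrored from the records
nonopt <- subset(records, !optimized & vergence == "far" & decentration == 0)
cat(sprintf("centred nonoptimized far RMS: ITS1 %.5f, ITS2 %.5f waves\n",
            nonopt$rms[nonopt$system == "ITS1"],
            nonopt$rms[nonopt$system == "ITS2"]))
d08 <- subset(records, !optimized & vergence == "far" & decentration == 0.8)
cat(sprintf("image displacement at 0.8 mm decentration: %.2f deg (ITS1), %.2f deg (ITS2) — parafoveal\n",
            d08$image_shift_deg[d08$system == "ITS1"],
            d08$image_shift_deg[d08$system == "ITS2"]))
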