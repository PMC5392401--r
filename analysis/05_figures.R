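#!/usr/bin/env Rscript
# Quality-versus-decentration figures from the sweep records written by
# analysis/04_decentration_sweep.R (run that first).

suppressMessages(library(itseye))
rec <- utils::read.csv("results/sweep_records.csv")
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

plot_metric <- function(metric, ylab, file) {
  grDevices::png(file.path("results/figures", file), width = 1400,
                 height = 700, res = 130)
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  for (vg in c("far", "near")) {
    sub <- rec[rec$vergence == vg, ]
    graphics::plot(NULL, xlim = c(0, 1), ylim = range(sub[[metric]]),
                   xlab = "anterior lens decentration (mm)", ylab = ylab,
                   main = paste(vg, "target"))
    i <- 1
    for (sn in c("ITS1", "ITS2")) for (op in c(TRUE, FALSE)) {
      s <- sub[sub$system == sn & sub$optimized == op, ]
      s <- s[order(s$decentration), ]
      graphics::lines(s$decentration, s[[metric]], col = i, lty = op + 1,
                      type = "b", pch = 19)
      i <- i + 1
    }
    graphics::legend("topleft", bty = "n", cex = 0.8, col = 1:4,
                     lty = c(2, 1, 2, 1), pch = 19,
                     legend = c("ITS1 optimized", "ITS1 nonoptimized",
                                "ITS2 optimized", "ITS2 nonoptimized"))
  }
  grDevices::dev.off()
}

plot_metric("rms", "RMS wavefront error (waves)", "rms_vs_decentration.png")
plot_metric("vsotf", "VSOTF", "vsotf_vs_decentration.png")
cat("written: results/figures/rms_vs_decentration.png, vsotf_vs_decentration.png\n")
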