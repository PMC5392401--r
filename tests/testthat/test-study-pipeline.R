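# A reduced sweep keeps the pipeline test inexpensive; sampling density
# only trades precision, not structure.
sweep_small <- function() fixture("sweep_small", function()
  run_sweep(config = simulation_config(n_grid = 24),
            decentrations = c(0, 0.2, 0.4),
            vergences = "far", opt_n_grid = 16))

test_that("the sweep enumerates the full factorial design", {
  rec <- sweep_small()
  expect_equal(nrow(rec), 2 * 2 * 1 * 3)
  expect_setequal(unique(rec$system), c("ITS1", "ITS2"))
  expect_true(all(rec$vsotf >= 0 & rec$vsotf <= 1 + 1e-9))
  expect_true(all(rec$decentration %in% c(0, 0.2, 0.4)))
  # centred cells show no image displacement
  expect_true(all(rec$image_shift_mm[rec$decentration == 0] == 0))
  # optimizer provenance rides along
  opts <- attr(rec, "optimizer_results")
  expect_named(opts, c("ITS1_far", "ITS2_far"))
  expect_true(all(vapply(opts, function(o) o$converged, logical(1))))
})

test_that("nonoptimized RMS grows with decentration and shift tracks it", {
  rec <- sweep_small()
  for (sn in c("ITS1", "ITS2")) {
    sub <- rec[rec$system == sn & !rec$optimized, ]
    sub <- sub[order(sub$decentration), ]
    expect_true(all(diff(sub$rms) > 0))
    # image shift approximately proportional to lens decentration
    dec <- sub$decentration[sub$decentration > 0]
    ratio <- sub$image_shift_mm[sub$decentration > 0] / dec
    expect_true(all(ratio > 0.9 & ratio < 1.2))
  }
})

test_that("table emission is complete, ordered and deterministic", {
  rec <- sweep_small()
  dir <- withr::local_tempdir()
  paths <- emit_tables(rec, dir)
  expect_true(all(file.exists(c(file.path(dir, "table1_far.csv"),
                                file.path(dir, "table3_decentration.csv")))))
  t1 <- utils::read.csv(file.path(dir, "table1_far.csv"))
  expect_equal(nrow(t1), 6)      # 2 systems x 3 decentrations
  expect_named(t1, c("system", "decentration", "rms_optimized",
                     "vsotf_optimized", "rms_nonoptimized",
                     "vsotf_nonoptimized"))
  t3 <- utils::read.csv(file.path(dir, "table3_decentration.csv"))
  expect_setequal(unique(t3$block), c("nonoptimized", "optimized"))
  # byte-identical rewrite
  before <- readLines(file.path(dir, "table1_far.csv"))
  emit_tables(rec, dir)
  expect_identical(readLines(file.path(dir, "table1_far.csv")), before)
  # incomplete sweeps are refused with the missing cells named
  expect_error(emit_tables(rec[-1, ], withr::local_tempdir()),
               "missing cells")
})
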