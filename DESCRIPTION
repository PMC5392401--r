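Package: itseye
Title: Simulation of Intraocular Telescopic Systems in a Schematic Eye
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact sequential skew-ray tracing of Galilean intraocular
    telescopic systems (ITS) implanted in an aphakic Liou-Brennan schematic
    eye. Provides thick-lens design from the effective-power formula,
    conic/aspheric surface tracing with coordinate-break lens decentration,
    wavefront maps and Zernike analysis, Fourier-optics image quality
    metrics (PSF, OTF, and the neural-CSF-weighted visual Strehl ratio
    VSOTF), asphericity optimization, and a decentration study pipeline
    that tabulates optical and visual quality against lens decentration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
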