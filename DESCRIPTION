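Package: qa4dct
Title: Automated Imaging Quality Assurance for 4DCT Motion Phantom Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of four-dimensional computed tomography (4DCT)
    imaging quality-assurance scans of a Catphan-style image-quality phantom
    moved on a programmable motion platform. Given a stationary reference CT
    and a set of respiratory-binned 4DCT volumes, the package localizes the
    phantom, measures sensitometry-plug dimensions by full width at half
    maximum (FWHM) profiling, recovers the motion amplitude from per-bin plug
    centroids, checks maximum- and minimum-intensity projections against the
    expected motion envelope, and computes a CT image-quality suite (geometric
    distortion, modulation transfer function from a bead, low-contrast
    detectability, HU constancy and consistency, uniformity, noise, and
    contrast-to-noise ratio), reporting deltas against the stationary baseline
    with configurable tolerances. A synthetic phantom and 4DCT simulator with
    partial-volume rendering, Gaussian blur, intra-bin motion blur, and seeded
    noise stands in for the physical phantom and motion rig so the whole
    pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
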