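Package: spherecloud
Title: Parametric Sphere-Cloud Stimuli for Visual Category Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Generation, manipulation and rendering of artificial category
    stimuli built from colored spheres in 3D space. Categories are derived
    from a base stimulus (the prototype) by per-parameter perturbation under
    uniform deviation ranges or Gaussian standard deviations, with polar
    position shifts and circular hue arithmetic. Includes morph continua
    between stimuli, category-exception construction, parametric deviation
    tables, deterministic raster rendering, trial schedulers for
    prototype-based, exemplar-based and continuum training protocols, a
    simulated observer for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    jpeg,
    withr,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
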