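Package: glassage
Title: Physical Ageing of Amorphous Glasses by Differential Scanning Calorimetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies physical ageing of amorphous (glassy) materials from
    differential scanning calorimetry (DSC) thermograms. Reads and segments
    heat-flow or specific-heat curves, fits solid/liquid heat-capacity
    reference lines, locates the glass transition, integrates total enthalpy,
    and determines fictive temperature by the enthalpy-intersection and
    equal-area constructions. Enthalpy relaxation from aged/unaged curve
    pairs is fitted to the Kohlrausch-Williams-Watts stretched exponential,
    with recovery parameters and fictive-temperature trajectories; kinetic
    fragility is obtained from the cooling/heating-rate dependence of the
    glass transition. A Tool-Narayanaswamy-Moynihan simulator generates
    self-consistent synthetic thermograms for arbitrary thermal programs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
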