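Package: shuntflow
Title: Hyperelastic Vessel Mechanics and Reduced-Order Pulsatile
    Hemodynamics for Modified Blalock-Taussig Shunts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constitutive modelling of vascular grafts and the aorta
    (five-parameter Mooney-Rivlin, three-parameter Yeoh, Ogden and
    Holzapfel-Gasser-Ogden hyperelastic models plus a linear-elastic
    reference), estimation of their constants from uniaxial tensile
    tests by bounded multi-start nonlinear least squares with
    identifiability diagnostics, and a reduced-order one-dimensional
    pulsatile flow solver for compliant vessel networks whose
    pressure-area laws derive from the assigned wall material. Includes
    a synthetic-data generator for expanded-PTFE graft tensile tests,
    idealized aorta-shunt-pulmonary-artery networks for the three
    classical shunt placements, and hemodynamic and wall-mechanics
    metrics (wall shear stress, TAWSS, von Mises wall stress, radial
    displacement, shunt flow) with structured scenario comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    lhs,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
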