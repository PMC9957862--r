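Package: mwablate
Title: Coupled Electromagnetic-Thermal Simulation of Microwave Tissue Ablation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale finite-element simulator of microwave ablation (MWA)
    probes in liver tissue. Solves the axisymmetric frequency-domain wave
    equation for a coaxial interstitial antenna (monopole, single-slot,
    dual-slot and sleeved single-slot concepts) weakly coupled to the
    transient bioheat equation, with sigmoidal temperature-dependent liver
    dielectric properties. Computes the port reflection coefficient (S11),
    the specific absorption rate field, the temperature field, and
    isocontour shape metrics (area, perimeter, circularity) of the ablation
    pattern over the course of treatment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Matrix, grDevices, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
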