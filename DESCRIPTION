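Package: plaquant
Title: Automated Quantification of Dental Plaque from Fluorescein UV Photographs
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments the dental area from photographs of fluorescein-dyed
    dentition taken under ultraviolet light, classifies every dental pixel
    into visible plaque, two risk levels of non-visible plaque, or
    non-plaque using green-minus-blue channel differences, and computes
    planimetric clinical indices (API index, area growth index, area time
    index) per image and relative to a patient's reference moment.
    Includes a synthetic scene generator with ground-truth masks and
    programmable temporal plaque growth, a batch experiment runner driven
    by a YAML configuration, and CSV/PNG/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
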