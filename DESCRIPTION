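Package: timeagree
Title: Validation of Time-Use Assessment Methods with Simultaneous-Activity Crediting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for validating recall-based time-use assessment methods
    (24-hour recall, image-assisted recall, enumerator image interpretation)
    against a direct-observation criterion. Implements timeslot crediting of
    coded activities with full credit for simultaneous activities, aggregation
    into ICATUS-2016 major divisions, population descriptives (medians,
    quartiles, non-participation, partaker medians), and an inter-method
    agreement suite: Bland-Altman bias and limits of agreement, threshold
    exceedance, Cronbach's alpha, weighted Cohen's kappa, the Wilcoxon
    signed-rank test (exact and approximate), and Bland-Altman plot-shape
    diagnostics. A synthetic-cohort generator with configurable recall-error
    models supports end-to-end testing and parameter-recovery studies without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
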