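Package: cerelearn
Title: Cerebellar Circuit Simulation and Trial-Over-Trial Learning Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generative simulation of a cerebellar Purkinje-cell / inferior-olive
    circuit during trial-over-trial motor learning, together with the statistics
    used to characterise complex-spike-linked plasticity in floccular recordings:
    tagging of consecutive-trial pairs and trios by complex-spike occurrence,
    trial-over-trial firing-rate differences, same-trial-facilitation tercile
    analysis, a complex-spike independence test, a model-ablation suite, and a
    spike-level synthetic-data layer with reciprocal-interval rate estimation,
    analysis-window scalars and complex-spike probability histograms. All
    user-facing functions take data frames and return tibbles; fitted result
    objects have tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
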