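Package: fogcast
Title: Forecasting Freezing-of-Gait Events from Stepping Force Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forecasting freezing-of-gait (FoG) episodes from
    vertical ground-reaction-force traces recorded while stepping in place.
    Simulates stepping cohorts with freeze episodes and ground-truth labels,
    labels traces by amplitude-envelope thresholding, transforms labeled
    traces into forecast-classification datasets via an input/gap/target/offset
    windowing scheme, trains a Gaussian naive Bayes, random forest and
    multilayer perceptron ensemble under leave-one-subject-out
    cross-validation, combines member votes by minority or majority rule, and
    runs streaming real-time prediction over a sliding buffer. Includes
    parameter sweeps over input and gap lengths with macro-averaged F1
    scoring, Spearman and Kruskal-Wallis summary statistics, and ggplot2
    visualisations of sweep surfaces and prediction timelines.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
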