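Package: sonotex
Title: Texture and Multi-Resolution CNN Classification of Hepatocellular
    Carcinoma in B-Mode Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates hepatocellular carcinoma (HCC) from the cirrhotic
    parenchyma (PAR) on which it evolved, inside B-mode ultrasound images.
    Provides polygon-annotation driven patch generation from VIA annotation
    files, a 47-feature conventional texture pipeline (second- and third-order
    gray-level co-occurrence statistics, autocorrelation, Hurst fractal index,
    edge statistics, Laws energy maps, Haar wavelet entropies, and local binary
    patterns), four feature-selection methods with their union, four classical
    classifiers, a multi-resolution convolutional network with atrous spatial
    pyramid pooling implemented natively, a shared evaluation layer with ROC
    analysis and sliding-window confidence maps, and a seeded speckle-phantom
    generator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    png,
    randomForest,
    Rcpp,
    rpart,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    EBImage,
    mgcv,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
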