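Package: memdrift
Title: Drift-Diffusion Attractor Dynamics for Continuous-Report Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modeling continuous-report (delayed-estimation) working
    memory as a drift-diffusion process on a circular feature space. Memories
    evolve under a flexible drift function built from von Mises derivative
    basis functions plus diffusive noise; the induced report distribution is
    obtained by Fokker-Planck discretization and matrix-exponential
    propagation, mixed with guess, swap, and decoding-noise components.
    Provides maximum-likelihood fitting with model variants and AIC/BIC/
    cross-validated comparison, bootstrap uncertainty, model-free circular
    statistics (entropy-based clustering, Hodges-Ajne and permuted Kuiper
    tests, response-peak detection, bias and precision profiles), a
    ground-truth synthetic task generator, normative error simulations, and a
    nonlinear perceptual-warp control model.
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
    lhs,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
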