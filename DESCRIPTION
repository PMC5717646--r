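Package: tcrkpr
Title: Kinetic Proofreading with Phosphatase Feedback in Early T-Cell
    Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a mass-action model of the first minutes of T-cell
    activation, in which T-cell receptor (TCR) complexes are phosphorylated
    sequentially on N sites and the phosphatase SHP-1, activated by singly
    phosphorylated complexes, provides negative feedback.  The package
    enumerates all positive steady states by reducing the steady-state
    equations to a single polynomial of degree N+1 in the active-phosphatase
    concentration, classifies their stability from the analytic Jacobian,
    integrates the kinetics with stiff solvers, and computes the
    dose-response surface log C_N = F(log L1, nu1) together with its
    small-ligand and intermediate-regime asymptotics, including the
    antagonist (self-ligand) extension.  Reproduces multistationarity,
    damped oscillations, non-monotone dose-response and the optimal
    dissociation rate predicted by the model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
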