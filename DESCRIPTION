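Package: spindlemix
Title: De-Mixing Muscle Mechanical State from Proprioceptive Afferent Firing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for estimating muscle mechanical
    state variables from populations of proprioceptive afferents. Generates
    ramp-hold-release muscle-tendon unit stretch protocols, simulates
    contractile and non-contractile passive forces and the firing of muscle
    spindle (group Ia, II) and Golgi tendon organ (group Ib) afferents driven
    by contractile force and yank (the force rate), processes spike trains
    into interpolated instantaneous firing rates, fits the afferent encoding
    gains by non-negative least squares and bounded nonlinear optimisation,
    and linearly de-mixes afferent firing back into estimates of force and
    yank and into self-generated versus externally imposed force components.
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
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
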