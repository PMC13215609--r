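Package: chronosim
Title: Simulation and Analysis of Image Speed and Memorability Effects on
    Perceived Duration
Version: 0.1.0
Authors@R:
    person("Chronosim", "Developers", email = "chronosim@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the "processing speed" of an image --
    the rate at which the softmax-output Shannon entropy of a recurrent
    convolutional network collapses across timesteps -- and its memorability
    jointly shape perceived duration and later recognition. Provides a
    desk-scale random-weight recurrent convolutional network and entropy
    tracing, power-law fitting of entropy collapse (E = A*T^B + C, with A the
    speed proxy), memorability/speed-stratified stimulus sampling with
    test/foil splits, generators for synthetic temporal-bisection and
    recognition experiments (logit choice models with subject random effects,
    an inverted-U quadratic alternative, lognormal reaction times), and the
    matching inference stack: log-RT outlier filtering, binomial mixed-effects
    fits with nested likelihood-ratio tests, binned psychometric surfaces,
    weighted quadratic (inverted-U) fits, recognition summaries,
    repeated-measures ANOVA and group contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    png,
    jpeg
Config/testthat/edition: 3
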