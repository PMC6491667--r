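Package: ssgrid
Title: State Space Grids for Coded Interaction Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build and analyse state space grids (SSGs) from synchronized
    streams of timed categorical events, such as coded team meeting
    interaction. Reads GridWare-style trajectory files and long-format
    tables, collapses event streams into cell visits, computes content
    measures (per-cell and per-region event counts, durations, time
    shares) and structure measures (cell range, transitions, dispersion,
    visit/duration/transition entropy), quantifies attractor strength via
    return times and the winnowing procedure, renders duration-scaled
    grid plots and cumulative trajectory frames, and simulates
    trajectories from semi-Markov models with configurable attractor
    structure. Includes a command-line interface for the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
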