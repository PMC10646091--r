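Package: mazemetrics
Title: Trajectory Metrics and Agent Simulation for Virtual Water-Maze Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies memory-guided spatial navigation in circular-arena
    (Morris water maze style) tasks from position and orientation time series.
    Computes per-trial behavioral metrics: a Monte-Carlo percent-rank memory
    score with a closed-form circle-intersection oracle, scatter of final
    locations, latency, path length and path error, surface coverage, average
    distance to the final location, initial angular velocity (idPhi) after
    quaternion-to-yaw conversion, unwrapping and zero-phase low-pass
    filtering, and a rotation-aligned, length-normalized dynamic-time-warping
    trajectory distance. Includes presence-probability and final-location
    grid maps, a synthetic navigator simulator reproducing the task geometry
    (6 blocks of 3 learning + 4 rotated probe trials in a 3.8 m arena), and a
    pipeline that aggregates trial metrics to participant and group-by-setup
    summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
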