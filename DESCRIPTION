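Package: descnet
Title: Signed Descending-Neuron Network Analysis for the Fly Brain Connectome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed, directed descending-neuron (DN) networks from
    connectome tables in the Codex CSV dialect, computes per-neuron connectivity
    and hop-reachability statistics, fits exponential and power-law models to
    degree distributions against shuffled-network nulls, performs signed Louvain
    consensus (co-clustering) community detection with cluster annotation, and
    provides trial-based calcium-imaging response statistics (delta-F-over-F
    normalisation, stimulus-triggered averages with confidence-interval masking)
    plus heuristic behaviour classification from treadmill velocities and 2D
    pose keypoints. A synthetic-data module generates planted-partition
    connectomes, trial-structured fluorescence recordings and kinematic series
    with known ground truth so that every stage of the pipeline can be
    exercised and verified without external downloads.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
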