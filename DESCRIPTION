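Package: prunebm
Title: Activity-Dependent Synaptic Pruning of Boltzmann Machines via Local
    Fisher Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study developmental synaptic pruning in stochastic
    binary encoder networks. Implements Bernoulli restricted and deep
    Boltzmann machines with prunable masked weights, contrastive-divergence
    and mean-field persistent-chain training, exact and sampled estimates of
    the Fisher information matrix (including a local variance estimate from
    pre-post spike coincidences and a mean-field heuristic that needs only
    the synaptic weight and mean firing rates), percentile-based pruning
    criteria with dead-unit removal, and generative/encoding evaluation
    (Kullback-Leibler divergence to the data distribution, log-probability
    matching, classifier-based encoding quality, and quality/diversity
    scores for generated patterns). A synthetic binary data generator
    (prototype mixtures, circular patches, receptive-field connectivity,
    toy digit glyphs) makes every experiment reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
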