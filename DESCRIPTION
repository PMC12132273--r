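Package: fondvae
Title: Iterative Spiking Variational Autoencoders via Natural-Gradient
    Free-Energy Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a family of iterative variational autoencoders in
    which posterior inference is carried out by recurrent membrane-potential
    dynamics rather than an amortized encoder network. The principal model is
    the iterative Poisson VAE (iP-VAE): latent spike counts are Poisson with
    rates exp(u), and natural gradient descent on variational free energy
    yields local update rules with feedforward drive, lateral competition
    through the dictionary Gram matrix, and divisive normalization in rate
    space. The package provides the free-energy terms and their gradients,
    the online (rolling-prior) and static-prior inference dynamics,
    dictionary learning by gradient accumulation across the unrolled
    inference trajectory, a locally competitive algorithm (LCA) baseline,
    synthetic sparse-dictionary data generators, natural-image patch
    whitening, MNIST IDX readers, drifting-grating stimuli, and evaluation
    metrics (reconstruction R-squared, latent sparsity, update-norm traces,
    convergence detection, the reconstruction-sparsity landscape, and
    dictionary recovery scoring).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
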