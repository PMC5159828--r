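Package: robustbmi
Title: Robust Neural Decoding for Brain-Machine Interfaces with
    Multiplicative Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building intracortical brain-machine interface (BMI)
    cursor decoders that stay usable when recording conditions change.
    Implements a multiplicative recurrent neural network (MRNN) decoder whose
    recurrent weights are re-parameterized by the incoming spike counts,
    trained with Hessian-free (Gauss-Newton conjugate gradient) optimization
    on multi-day corpora with spike-count data augmentation; a
    feedback-intention-trained Kalman filter (FIT-KF) baseline; mutual
    information electrode ranking and principal-angle subspace analyses; a
    synthetic multi-day corpus generator with cosine-tuned Poisson electrodes
    and drifting recording conditions; and a closed-loop cursor-task
    simulator with the standard center-out performance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
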