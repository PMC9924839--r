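Package: ecglvh
Title: Left Ventricular Hypertrophy Detection from 12-Lead ECG Voltage Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for rule-based and machine-learning
    detection of left ventricular hypertrophy (LVH) from resting 12-lead
    electrocardiograms. Implements automatic R-peak and S-valley extraction
    with a refractory-constrained local-maximum scan and T-wave misdetection
    correction, per-lead median amplitude features and R-anchored beat
    segmentation, seven published ECG voltage criteria (Cornell,
    Sokolow-Lyon, Peguero-Lo Presti, Framingham, Gubner, sum-of-12-leads,
    Lewis), an entropy decision tree with depth selection, a k-means++
    clustering classifier, and a 24-26-1 back-propagation neural network,
    together with one-way ANOVA F-statistic feature ranking and a
    sequential feature-elimination accuracy curve. A parametric 12-lead
    ECG generator with exact ground truth makes every stage testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
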