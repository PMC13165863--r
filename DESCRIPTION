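Package: dyadsense
Title: Multimodal Behavior Analytics for Dyadic Collaboration Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyzes time-synchronized multimodal event logs (speech
    transcripts, eye-gaze samples, controller and task events) from
    two-person collaborative sessions. Detects gaze fixations on regions
    of interest, segments transcripts into utterances and labels them
    with dialogue acts via a transparent rule cascade, classifies
    per-participant behavior states (Engaged, Struggling, Waiting) with
    an interpretable decision tree, drives a five-state feedback machine
    that emits scaffolding prompts after sustained interaction
    breakdowns, scores five dimensions of collaboration from the sensed
    features, and provides an effect-size, confidence-interval,
    false-discovery-rate, and post hoc power battery for small dyadic
    studies. A scripted session simulator renders ground-truth behavior
    scripts into raw multimodal logs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
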