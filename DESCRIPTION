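Package: nestcount
Title: Counting Pollinator Nest-Box Entries and Exits from Tracked Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes multi-object-tracking output of a top-view camera
    watching a bumblebee nest-box entrance. A rectangular virtual frame is
    placed over the entrance; boundary crossings of each tracked bee are
    grouped into episodes by an inter-crossing time threshold and classified
    by crossing-count parity into nest entries, exits, or turn-backs. Includes
    the naive counter that treats every crossing as a nest event, a synthetic
    trajectory simulator with ground truth and tracker failure modes (ID
    switches and merges, jitter, dropout), a confusion-matrix evaluation
    harness (accuracy, precision, recall, F1), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    purrr,
    rlang,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
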