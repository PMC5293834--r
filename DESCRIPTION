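Package: refnav
Title: Reference-Frame Based Spatial Navigation Simulator
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates goal-directed spatial navigation with Gaussian-tuned
    neural populations for head direction, allocentric and egocentric goal
    direction, and egocentric cue direction, a hippocampal cognitive map with
    winner-take-all place cells and landmark-graph route planning, a
    retrosplenial confidence system that arbitrates among allocentric,
    egocentric and route-centric strategies via softmax selection, and a
    differential-drive agent with wall-sliding collision handling. Ships three
    built-in experimental worlds (a blinking-light arena, a five-armed star
    maze, and a multi-region vista-space world) together with experiment
    runners, trial classification and a strategy-contribution metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
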