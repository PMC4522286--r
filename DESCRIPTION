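Package: ffm
Title: Finger Force Manipulandum Dexterity Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the four Finger Force Manipulandum (FFM) task protocols
    (isometric force tracking, sequential finger tapping, single-finger
    tapping at 1-3 Hz, and cued multi-finger tapping), reads and validates
    four-channel fingertip force recordings, and computes the dexterity
    component measures used to profile individual subjects against control
    norms: tracking error, release duration, tapping-rate slope, motor
    overflow, omission rate and unwanted extra-finger taps. A seedable
    generative model of control-like and paretic-like force traces, with
    exported ground-truth events, makes every analysis stage testable
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
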