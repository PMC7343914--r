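# extdata

No calibration curve is redistributed with the package. To run the
IntCal13 worked example (tests and the optional acceptance quantities),
place the published curve file here as `intcal13.14c` (the standard
comma-separated `.14c` layout: comment lines, then cal BP, 14C age BP,
sigma, ...).
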