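# report every failure rather than terminating after the default cap,
# so long-running calibration checks are always executed
options(testthat.progress.max_fails = Inf)
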