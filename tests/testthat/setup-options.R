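# The acceptance criteria below are allowed to be red (they assert the source
# design's printed pattern, which the stated simulation world does not
# reproduce); never let accumulated failures terminate the suite early.
options(testthat.progress.max_fails = 10000)
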