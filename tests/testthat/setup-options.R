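# Report every failure rather than aborting the run at testthat's default
# cap; the replication checks in test-acceptance.R are allowed to fail
# individually without silencing the rest of the suite.
options(testthat.progress.max_fails = Inf)
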