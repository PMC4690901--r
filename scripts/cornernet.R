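#!/usr/bin/env Rscript
# Thin CLI wrapper; all logic lives in the cornernet package.
suppressPackageStartupMessages(library(cornernet))
quit(status = cornernet_main(commandArgs(trailingOnly = TRUE)), save = "no")
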