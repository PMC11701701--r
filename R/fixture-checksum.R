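# md5 of inst/extdata/starch_activities.tsv, regenerated whenever the
# bundled table changes (tools::md5sum on the installed file).
fixture_md5 <- "5d0467347b03e654216d7516e0822bfd"
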