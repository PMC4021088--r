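# Shared fixtures, built once per test run.

# Host-like usage table: 71 coding sequences whose third-position GC bias
# reproduces a GC-rich monocot corpus (average GC ~55.7%).
host_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- build_usage_table(
        synthetic_cds_set(71, 300, gc3_bias = 0.8, seed = 20140101),
        source_label = "synthetic host corpus")
    }
    tab
  }
})
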