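# Geometry fixtures are deterministic but not free to build (the sheet
# placement runs a grid refinement), so build each once per test run.
cached_suite <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- fixture_suite()
    s
  }
})

cached_models <- local({
  m <- list()
  function(name) {
    if (is.null(m[[name]])) {
      m[[name]] <<- parse_structure(cached_suite()[[name]]$pdb)
    }
    m[[name]]
  }
})
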