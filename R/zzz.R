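.onLoad <- function(libname, pkgname) {
  # size-asserted load of the three packaged vocabularies; a modified
  # vocabulary file violating 116/120/54 fails here, not at first use
  .load_vocabularies(system.file("extdata", "vocab", package = pkgname,
                                 lib.loc = libname))
}
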