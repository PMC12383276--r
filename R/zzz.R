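.onLoad <- function(libname, pkgname) {
  ## the glm module's block samplers markedly improve mixing of the
  ## penalized spline coefficients in conditionally linear models
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  invisible()
}
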