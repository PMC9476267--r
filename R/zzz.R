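.onLoad <- function(libname, pkgname) {
  # Satterthwaite degrees of freedom for marginal means on Gaussian mixed
  # fits, at any sample size
  emmeans::emm_options(lmer.df = "satterthwaite", lmerTest.limit = 1e5,
                       pbkrtest.limit = 0)
  invisible()
}

utils::globalVariables(".")
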