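# Classed conditions so callers (and tests) can distinguish failure modes.
# Every error raised by the package carries class c("npmine_<kind>", "npmine_error").

np_stop <- function(class, msg, ...) {
  extra <- list(...)
  cond <- errorCondition(msg, class = c(class, "npmine_error"))
  for (nm in names(extra)) cond[[nm]] <- extra[[nm]]
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
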