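# Structured logging to stderr with per-stage timers. Quiet by default in
# non-interactive test runs; enable with options(pseudotract.verbose = TRUE).

pt_log <- function(...) {
  if (isTRUE(getOption("pseudotract.verbose", FALSE))) {
    message("[pseudotract ", format(Sys.time(), "%H:%M:%S"), "] ", ...)
  }
  invisible(NULL)
}

pt_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- force(expr)
  pt_log(name, " finished in ",
         sprintf("%.2f", proc.time()[["elapsed"]] - t0), " s")
  res
}
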