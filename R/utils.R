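# seed hygiene: run a block under a fixed seed, then restore the caller's
# RNG state so seeded helpers do not perturb a surrounding simulation
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# small deterministic config checksum (polynomial rolling hash over the
# deparsed object, mod 2^31-1); stamped into output headers for the
# reproducibility contract
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
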