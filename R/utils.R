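#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state so generators are pure functions of
# their seed and never disturb the caller's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# zero-padded identifier factory: id_seq("G", 12, width = 4) -> "G0001" ...
id_seq <- function(prefix, n, width = max(2L, nchar(as.character(n)))) {
  sprintf(paste0(prefix, "%0", width, "d"), seq_len(n))
}
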