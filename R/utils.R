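# Internal helpers shared across modules.

# Reverse complement of plain character vectors. Biostrings is used for file
# IO; this stays a one-liner so sequence logic is self-contained and cheap on
# short windows.
revcomp_chr <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Seeded evaluation without touching the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# One global seed fans out to per-stage child seeds by fixed offsets, so each
# generator is reproducible on its own.  Offsets are arbitrary but frozen.
child_seed <- function(seed, stage) {
  offsets <- c(
    diff_table = 101L, compendium = 211L, genome = 307L, ontology = 401L,
    pipeline = 503L
  )
  off <- offsets[[stage]]
  (as.integer(seed) * 7L + off) %% .Machine$integer.max
}

stop_rhe <- function(msg, class) {
  abort(msg, class = paste0("rhepipe_", class))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_rhe(sprintf("`%s` must be a single number in [%s, %s]",
                     name, format(lower), format(upper)), "bad_argument")
  }
  invisible(x)
}
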