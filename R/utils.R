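# Shared internals: seeded-RNG isolation and config hashing.

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream. All randomized operations in the package run through this, so
# results depend only on the seeds they are given.
.with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# MD5 of the canonical JSON serialization of a config list; embedded in every
# output artifact so reruns can be compared by hash.
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tf))
}
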