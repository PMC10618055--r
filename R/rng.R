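# Deterministic per-substep RNG streams.  One global seed derives one stream
# per stochastic substep (init / mobility / culture), so toggling one process
# off does not perturb the draws of the others (enables ablation tests).
# Streams are stored as saved .Random.seed vectors and swapped in per use.

stream_names <- c("init", "mobility", "culture")

derive_seed <- function(seed, k) {
  # distinct 32-bit-safe child seeds
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483629)
}

make_streams <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  for (k in seq_along(stream_names)) {
    set.seed(derive_seed(seed, k))
    e[[stream_names[k]]] <- get(".Random.seed", envir = globalenv())
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  e
}

with_stream <- function(streams, name, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", streams[[name]], envir = globalenv())
  on.exit({
    streams[[name]] <- get(".Random.seed", envir = globalenv())
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# serialisable snapshot of the stream state (for checkpoints)
streams_to_list <- function(streams) as.list(streams)

streams_from_list <- function(lst) {
  e <- new.env(parent = emptyenv())
  for (nm in names(lst)) e[[nm]] <- lst[[nm]]
  e
}
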