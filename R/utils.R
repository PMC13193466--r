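# small internal helpers shared across modules

geomean <- function(x) exp(mean(log(x)))

# run `expr` under a fixed RNG state without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_old) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# derive a per-stage seed from a global one, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 97 + offset) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
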