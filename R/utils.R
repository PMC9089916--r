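# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    expr
}

# Derive a distinct child seed from a base seed and a stream label,
# staying within 32-bit integer range.
childSeed <- function(seed, stream) {
    sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% 10000L +
        (as.integer(seed) %% 200000L) * 10007L
}

.assertSingleNumber <- function(x, nm, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
        stop(nm, " must be a single number in [", lo, ", ", hi, "]",
             call. = FALSE)
    invisible(x)
}
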