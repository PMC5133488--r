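# Internal RNG helpers: every stochastic operation takes an explicit seed and
# runs in a locally scoped RNG state, so a scan is reproducible end-to-end and
# independent of anything the caller did with .Random.seed.

withSeed <- function(seed, code) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(as.integer(seed))
    code
}

# Fold any number of integer keys into one 32-bit seed (multiplicative hash,
# kept strictly below 2^31 so set.seed() accepts it). Streams derived from
# (master, region, scheme) are deterministic and order-independent.
deriveSeed <- function(...) {
    keys <- as.double(c(...))
    s <- 104729
    for (k in keys) s <- (s * 69069 + abs(k) + 1) %% 2147483629
    as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

laspaMessage <- function(verbose, ...) {
    if (isTRUE(verbose)) message("[laspa] ", ...)
}
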