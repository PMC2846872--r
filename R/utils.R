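# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# user's stream.
withSeed <- function(seed, expr) {
    seed <- as.integer(seed)
    if (is.na(seed))
        stop("seed must be a finite integer")
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(seed)
    force(expr)
}

# column SDs with zero-variance guard (constant feature -> scale 1, so the
# standardized column is exactly 0 and contributes nothing to the kernel)
colScale <- function(x) {
    s <- apply(x, 2L, sd)
    s[!is.finite(s) | s == 0] <- 1
    s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
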