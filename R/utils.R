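# Internal helpers shared across modules.

# Evaluate expr under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards so that simulation functions never
# perturb global RNG state.
.withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) {
        old <- get(".Random.seed", envir = env, inherits = FALSE)
        on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
    } else {
        on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE))
                    rm(".Random.seed", envir = env), add = TRUE)
    }
    set.seed(seed)
    expr
}

# A single numeric column checked to be non-negative whole numbers.
.checkCounts <- function(x, what) {
    if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
        stop(what, " must be non-negative integers", call. = FALSE)
    invisible(as.numeric(x))
}
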