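# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so library calls never perturb user simulations.
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
    force(expr)
}

# sample() without the length-1 surprise
sampleVec <- function(x, size, replace = FALSE, prob = NULL) {
    x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# draw one integer uniformly from an inclusive range c(lo, hi)
drawCount <- function(range) {
    if (range[1] == range[2]) as.integer(range[1])
    else sample.int(range[2] - range[1] + 1L, 1L) + as.integer(range[1]) - 1L
}

stopifnot_range <- function(x, nm) {
    if (length(x) != 2 || x[1] > x[2])
        stop(nm, " must be an increasing pair", call. = FALSE)
}
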