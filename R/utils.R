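# Internal helpers shared across modules.

# Evaluate expr with a private RNG state: seeds, runs, then restores whatever
# stream the caller had, so package functions never clobber user RNG state.
withSeed <- function(seed, expr) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
        if (has_old) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    expr
}

# round half away from zero (R's round() rounds half to even)
roundHalfUp <- function(x) floor(x + 0.5)

# typed error for collinear / too-few point configurations
degenerateGeometryError <- function(msg) {
    stop(structure(class = c("degenerateGeometryError", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

asMatrixSamples <- function(samples) {
    if (methods::is(samples, "TabularDataset")) sampleValues(samples)
    else {
        m <- as.matrix(samples)
        storage.mode(m) <- "double"
        m
    }
}
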