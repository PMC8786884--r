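# Run code under a local RNG seed, restoring the caller's stream afterwards.
# seed = NULL runs the code on the ambient stream.
withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# Upper-triangle (i < j) index pairs of an n x n matrix; row-per-pair matrix
# with columns i, j, ordered so that (i, j) enumerates pairs with j ascending.
upperPairs <- function(n) {
    if (n < 2) return(cbind(i = integer(0), j = integer(0)))
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    cbind(i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]))
}
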